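# End-to-end orchestration: build -> restraints -> restrained SA with pruning
# -> representative selection -> desk-scale production sampling -> analysis ->
# report bundle, plus campaign planning that mirrors molecule x solvent x
# replica run matrices.
#
# "Solvent" is a metadata tag at desk scale: the stand-in sampler has no
# solvent model, so the tag only selects analysis conventions (e.g. the RDF
# normalization density) and labels outputs.

#' Plan a simulation campaign (molecule x solvent x replica)
#'
#' Cartesian-product enumeration with deterministic, unique seed assignment
#' and stable ordering (molecule-major, then solvent, then replica).
#'
#' @param molecules Character vector of molecule ids (must be unique).
#' @param solvents Solvent tags (default DMSO and water).
#' @param replicas_per_cell Replicas per molecule/solvent cell (default 4).
#' @param base_seed Seed of the first run.
#' @param duration_tag Free-text duration label stored on each run.
#' @return A `campaign_plan` data frame: molecule, solvent, replica, seed,
#'   duration_tag.
#' @export
plan_campaign <- function(molecules, solvents = c("DMSO", "water"),
                          replicas_per_cell = 4, base_seed = 1L,
                          duration_tag = "200ns") {
  if (length(molecules) == 0L || length(solvents) == 0L)
    stop("value error: molecules and solvents must be non-empty")
  if (anyDuplicated(molecules))
    stop("value error: duplicate molecule ids")
  if (replicas_per_cell < 1L) stop("value error: replicas must be >= 1")
  plan <- expand.grid(replica = seq_len(replicas_per_cell),
                      solvent = solvents, molecule = molecules,
                      stringsAsFactors = FALSE)[, 3:1]
  plan$seed <- base_seed + seq_len(nrow(plan)) - 1L
  plan$duration_tag <- duration_tag
  class(plan) <- c("campaign_plan", "data.frame")
  plan
}

.PIPELINE_SCHEMA_VERSION <- 1L

#' Pipeline configuration
#'
#' Aggregates every stage's parameters with protocol defaults: restraint force
#' constant 32 kcal mol^-1 A^-2, pruning ceiling 5 kcal/mol, 10 clusters,
#' RDF bin 0.1 Angstrom at the bulk water density. Unknown keys in any block
#' are rejected (fail-fast).
#'
#' @param sequence Foldamer sequence string.
#' @param seed Master seed; all stage seeds derive from it.
#' @param solvent Metadata tag (`"DMSO"` or `"water"`).
#' @param restraints List: `source` ("synthetic" or "file"), `path` (file
#'   source), `template`, `r_ref`, `sigma_log`, `max_distance`, `k`, `slack`.
#' @param annealing List: `steps_per_ps`, `n_replicas`.
#' @param pruning List: `penalty_ceiling`, `penalty_statistic`.
#' @param production List: `n_steps`, `stride`, `temperature`.
#' @param clustering List: `n_clusters`, `merge_threshold`.
#' @param rdf List: `bin_width`, `density` (NULL = water default),
#'   `reference_role`, `target_role`, `r_max`.
#' @param window_fraction Trailing fraction of production frames analysed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sequence, seed = 1L, solvent = "DMSO",
                            restraints = list(), annealing = list(),
                            pruning = list(), production = list(),
                            clustering = list(), rdf = list(),
                            window_fraction = 0.5) {
  merge_block <- function(defaults, given, block) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop(sprintf("config error: unknown key(s) in '%s': %s", block,
                   paste(bad, collapse = ", ")))
    defaults[names(given)] <- given
    defaults
  }
  cfg <- list(
    schema_version = .PIPELINE_SCHEMA_VERSION,
    sequence = sequence, seed = as.integer(seed), solvent = solvent,
    restraints = merge_block(
      list(source = "synthetic", path = NULL, template = "helix",
           r_ref = 2.5, sigma_log = 0.1, max_distance = 5,
           k = .DEFAULT_K_RESTRAINT, slack = 0), restraints, "restraints"),
    annealing = merge_block(
      list(steps_per_ps = 100, n_replicas = 100), annealing, "annealing"),
    pruning = merge_block(
      list(penalty_ceiling = .DEFAULT_PENALTY_CEILING,
           penalty_statistic = "min"), pruning, "pruning"),
    production = merge_block(
      list(n_steps = 20000, stride = 20, temperature = 300), production,
      "production"),
    clustering = merge_block(
      list(n_clusters = 10, merge_threshold = 1.0), clustering, "clustering"),
    rdf = merge_block(
      list(bin_width = 0.1, density = NULL, reference_role = "O",
           target_role = "SC_centroid", r_max = 12), rdf, "rdf"),
    window_fraction = window_fraction
  )
  if (is.null(cfg$rdf$density))
    cfg$rdf$density <- .WATER_DENSITY
  if (cfg$window_fraction <= 0 || cfg$window_fraction > 1)
    stop("config error: window_fraction must be in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the [pipeline_config()] structure; unknown keys
#'   are errors and a `schema_version` mismatch is rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- raw$schema_version
  if (!is.null(sv) && sv != .PIPELINE_SCHEMA_VERSION)
    stop(sprintf("config error: schema_version %s unsupported", sv))
  raw$schema_version <- NULL
  known <- c("sequence", "seed", "solvent", "restraints", "annealing",
             "pruning", "production", "clustering", "rdf", "window_fraction")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("config error: unknown top-level key(s): %s",
                 paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

# stable hash of the configuration (drives idempotence)
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full desk-scale pipeline
#'
#' Stages, in order: sequence parsing; restraint derivation (synthetic forward
#' model or a peak-table file); iterative restrained-SA refinement; selection
#' of the main-cluster medoid among replica finals as the representative;
#' constant-temperature production Monte Carlo from that representative (the
#' desk-scale stand-in for solvated MD, or an externally supplied trajectory
#' via `external_trajectory`); trajectory analysis (RMSD/ROG series, torsion
#' distribution, clustering with merging, RDF); summary and manifest.
#'
#' Re-running with an unchanged configuration is a no-op unless `force`.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param force Re-run even when a manifest with the same config hash exists.
#' @param external_trajectory Optional multi-model PDB or XYZ path analysed in
#'   place of the production stand-in.
#' @return A `pipeline_bundle` (invisible list of stage outputs and file
#'   paths).
#' @export
run_pipeline <- function(cfg, outdir, force = FALSE,
                         external_trajectory = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  hash <- .config_hash(cfg)
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    files <- file.path(outdir, names(old$files))
    if (identical(old$config_hash, unname(hash)) && all(file.exists(files)) &&
        all(unname(tools::md5sum(files)) == unlist(old$files))) {
      message("pipeline: manifest up to date, skipping (use force = TRUE)")
      return(invisible(structure(list(outdir = outdir, skipped = TRUE,
                                      manifest = old),
                                 class = "pipeline_bundle")))
    }
  }

  stage <- "parse"
  bundle <- try({
    topo <- parse_sequence(cfg$sequence)

    stage <- "restraints"
    rcfg <- cfg$restraints
    if (identical(rcfg$source, "file")) {
      peaks <- read_roesy_tsv(rcfg$path)
    } else {
      template <- build_conformation(topo,
                                     template_torsions(rcfg$template, topo),
                                     provenance = "restraint_template")
      peaks <- forward_roesy(template, r_ref = rcfg$r_ref,
                             max_distance = rcfg$max_distance,
                             sigma_log = rcfg$sigma_log, seed = cfg$seed)
    }
    dist <- peaks_to_distances(peaks)
    dist <- dist[dist$role_a != "calibration", , drop = FALSE]
    rset <- distances_to_restraints(dist, k = rcfg$k, slack = rcfg$slack)
    write_roesy_tsv(peaks, file.path(outdir, "peaks.tsv"))
    write_restraints_tsv(rset, file.path(outdir, "restraints_initial.tsv"))

    stage <- "refine"
    schedule <- default_sa_schedule(cfg$annealing$steps_per_ps)
    pcfg <- pruning_config(cfg$pruning$penalty_ceiling,
                           cfg$pruning$penalty_statistic)
    refinement <- refine(topo, rset, schedule, pcfg,
                         n_replicas = cfg$annealing$n_replicas,
                         base_seed = cfg$seed)
    write_restraints_tsv(refinement$set,
                         file.path(outdir, "restraints_final.tsv"))
    write_refinement_json(refinement, file.path(outdir, "refinement.json"))

    stage <- "representative"
    finals <- lapply(refinement$results, `[[`, "conformation")
    finals_traj <- trajectory(topo, finals)
    write_pdb(finals_traj, file.path(outdir, "replica_finals.pdb"))
    k_rep <- min(cfg$clustering$n_clusters, length(finals))
    sa_clusters <- cluster_frames(finals_traj, n_clusters = k_rep)
    rep_frame <- sa_clusters$representatives[1]
    representative <- frame_conformation(finals_traj, rep_frame)
    write_pdb(representative, file.path(outdir, "representative.pdb"))

    stage <- "production"
    if (!is.null(external_trajectory)) {
      prod_traj <- if (grepl("\\.xyz$", external_trajectory))
        read_xyz(external_trajectory, topo) else
          read_pdb(external_trajectory, topo)
    } else {
      prod_traj <- production_trajectory(
        topo, start = refinement$results[[rep_frame]]$torsions,
        n_steps = cfg$production$n_steps, stride = cfg$production$stride,
        temperature = cfg$production$temperature,
        seed = cfg$seed + 10000L)
    }
    write_xyz(prod_traj, file.path(outdir, "production.xyz"),
              comment = sprintf("production_%s", cfg$solvent))

    stage <- "analysis"
    prod_traj <- set_window(prod_traj, fraction = cfg$window_fraction)
    rmsd <- rmsd_series(prod_traj, representative)
    rog <- rog_series(prod_traj)
    tdist <- torsion_distribution(prod_traj)
    k_prod <- min(cfg$clustering$n_clusters,
                  prod_traj$window[2] - prod_traj$window[1] + 1L)
    clusters <- cluster_frames(prod_traj, n_clusters = k_prod)
    merged <- merge_similar_clusters(clusters,
                                     threshold = cfg$clustering$merge_threshold)
    ref_sel <- which(topo$atoms$role == cfg$rdf$reference_role)
    tgt_sel <- which(topo$atoms$role == cfg$rdf$target_role)
    rdf <- compute_rdf(prod_traj, ref_sel[1], tgt_sel,
                       bin_width = cfg$rdf$bin_width,
                       density = cfg$rdf$density, r_max = cfg$rdf$r_max)
    write_series_tsv(rmsd, file.path(outdir, "rmsd.tsv"), "rmsd_A")
    write_series_tsv(rog, file.path(outdir, "rog.tsv"), "rog_A")
    write.table(tdist$histogram, file.path(outdir, "torsion_histogram.tsv"),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    write.table(data.frame(r = rdf$r, g = rdf$g, counts = rdf$counts),
                file.path(outdir, "rdf.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    rep_prod <- frame_conformation(prod_traj, merged$representatives[1])
    write_pdb(rep_prod, file.path(outdir, "representative_production.pdb"))
    jsonlite::write_json(
      list(populations = merged$populations,
           representatives = merged$representatives,
           merge_log = merged$merge_log,
           sa_populations = sa_clusters$populations),
      file.path(outdir, "clusters.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)

    list(topology = topo, restraints = refinement$set,
         refinement = refinement, sa_clusters = sa_clusters,
         representative = representative, trajectory = prod_traj,
         rmsd = rmsd, rog = rog, torsions = tdist, clusters = merged,
         rdf = rdf, outdir = outdir, skipped = FALSE)
  }, silent = TRUE)
  if (inherits(bundle, "try-error"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 attr(bundle, "condition")$message))

  stage <- "summary"
  summary <- summarize_pipeline(bundle)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(config = unclass(cfg), config_hash = unname(hash),
                   files = as.list(setNames(
                     unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  bundle$summary <- summary
  class(bundle) <- "pipeline_bundle"
  invisible(bundle)
}

#' Constant-temperature production sampling (desk-scale stand-in)
#'
#' Unrestrained torsional Monte Carlo at a fixed temperature, recording one
#' frame every `stride` steps; stands in for solvated production MD so the
#' analysis stages always have input.
#'
#' @param topology A [foldamer_topology].
#' @param start Starting [torsion_state()] (default extended).
#' @param n_steps Total MC steps.
#' @param stride Steps between recorded frames.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @param weights [move_params()].
#' @return A [trajectory()].
#' @export
production_trajectory <- function(topology, start = NULL, n_steps = 20000,
                                  stride = 20, temperature = 300, seed = 1L,
                                  weights = move_params()) {
  if (is.null(start)) start <- extended_torsions(topology)
  v0 <- .torsion_vector(topology, start)
  par <- .energy_params(topology, restraint_set(), weights)
  zm <- topology$zmatrix
  sigma <- min(max(weights$sigma_hi * sqrt(temperature / weights$t_ref),
                   weights$sigma_lo), weights$sigma_hi)
  set.seed(as.integer(seed))
  res <- .production_cpp(zm[, 1:3, drop = FALSE] - 1L, zm[, "bond"],
                         zm[, "angle"], zm[, "toroff"],
                         as.integer(zm[, "link"]), v0, par, temperature,
                         as.integer(n_steps), as.integer(stride), sigma,
                         seq_len(2L * nrow(topology$residues)))
  trajectory(topology, res$frames,
             times = seq_len(dim(res$frames)[3]) * stride / 100)
}

#' Summary tables of a pipeline run
#'
#' (a) cluster population table, (b) the representative structure's
#' per-residue phi/psi in the layout of a dihedral table, (c) RMSD/ROG mean
#' and sd over the analysis window.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return List of data frames: `populations`, `representative_torsions`,
#'   `series_stats`.
#' @export
summarize_pipeline <- function(bundle) {
  if (is.null(bundle$clusters) || is.null(bundle$rmsd))
    stop("named error: bundle is missing analysis stage outputs")
  res <- bundle$topology$residues
  rep_conf <- frame_conformation(bundle$trajectory,
                                 bundle$clusters$representatives[1])
  tor <- measure_torsions(rep_conf)
  label <- paste0(res$code1,
                  ifelse(res$kind == "amide", "",
                         ifelse(res$kind == "tz4n", "4n", "4c")),
                  res$position_index)
  list(
    populations = data.frame(cluster = seq_along(bundle$clusters$populations),
                             population = bundle$clusters$populations),
    representative_torsions = data.frame(residue = label, phi = tor$phi,
                                         psi = tor$psi),
    series_stats = data.frame(
      series = c("rmsd", "rog"),
      mean = c(mean(bundle$rmsd), mean(bundle$rog)),
      sd = c(sd(bundle$rmsd), sd(bundle$rog)))
  )
}
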