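# Synthetic-data generators with known ground truth: template conformers,
# two-state trajectory mixtures with Gaussian torsional noise, forward-modelled
# ROESY peak tables (r^-6 with multiplicative log-normal noise), and ideal-gas
# point sets for RDF null tests.
#
# The template torsion values are package fixtures chosen for compact,
# clash-free geometry under this package's coarse-grained builder; they are
# NOT experimentally determined structures (none are deposited for this
# compound class).

# per-kind template torsions (phi, psi): period-2 patterns adapted to the
# alternating amide/triazole backbone
.TEMPLATES <- list(
  extended = list(amide = c(180, 180), tz4n = c(180, 180), tz4c = c(180, 180)),
  helix = list(amide = c(-60, -30), tz4n = c(-60, -150), tz4c = c(-100, -30))
)

#' Template torsion states
#'
#' `extended`: every phi/psi at 180 (zigzag reminiscent of a beta-strand).
#' `helix`: a compact helical pattern (amide (-60, -30); 4n (-60, -150);
#' 4c (-100, -30)), periodic over the alternating backbone. `twisted_s`: two
#' helical blocks of opposite handedness (sign-mirrored second half).
#'
#' @param name One of `"extended"`, `"helix"`, `"twisted_s"`.
#' @param topology A [foldamer_topology].
#' @return A [torsion_state()].
#' @export
template_torsions <- function(name, topology) {
  res <- topology$residues
  n <- nrow(res)
  base <- switch(name,
                 extended = .TEMPLATES$extended,
                 helix = .TEMPLATES$helix,
                 twisted_s = .TEMPLATES$helix,
                 stop(sprintf("value error: unknown template '%s'", name)))
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    v <- base[[res$kind[i]]]
    phi[i] <- v[1]; psi[i] <- v[2]
  }
  if (name == "twisted_s") {
    flip <- seq_len(n) > n / 2
    phi[flip] <- wrap_angle(-phi[flip])
    psi[flip] <- wrap_angle(-psi[flip])
  }
  torsion_state(res$position_index, phi, psi)
}

#' Generator specification for synthetic trajectories
#'
#' @param template Template name or a list of [torsion_state()] (one per
#'   mixture state).
#' @param noise_sd Torsional noise (degrees; i.i.d. Gaussian per torsion).
#'   The default 5.7 degrees yields a mean intra-state backbone RMSD of about
#'   0.3 Angstrom on the heptamer templates.
#' @param n_frames Number of frames.
#' @param populations State weights, summing to 1.
#' @param seed Integer seed.
#' @param sigma_log ROESY multiplicative log-normal noise (default 0.1).
#' @param max_noe_distance NOE forward-model cutoff (Angstrom, default 5).
#' @return A `generator_spec`.
#' @export
generator_spec <- function(template = "helix", noise_sd = 5.7, n_frames = 100,
                           populations = 1, seed = 1L, sigma_log = 0.1,
                           max_noe_distance = 5) {
  if (abs(sum(populations) - 1) > 1e-9)
    stop("value error: populations must sum to 1")
  if (noise_sd < 0) stop("value error: noise_sd must be >= 0")
  if (n_frames < 1L) stop("value error: n_frames must be >= 1")
  structure(list(template = template, noise_sd = noise_sd,
                 n_frames = n_frames, populations = populations, seed = seed,
                 sigma_log = sigma_log, max_noe_distance = max_noe_distance),
            class = "generator_spec")
}

#' Generate a synthetic trajectory with planted state structure
#'
#' Per frame: a state is chosen by the population weights, its template
#' torsions are perturbed with i.i.d. Gaussian noise, and coordinates are
#' built. Returns the trajectory plus the true state label per frame.
#' Deterministic given the seed.
#'
#' @param spec A [generator_spec()]. If `spec$template` is a character vector,
#'   one template per state; a single name with multiple populations uses the
#'   templates `helix`, `extended`, `twisted_s` in order.
#' @param topology A [foldamer_topology].
#' @return List: `trajectory`, `labels` (integer state per frame),
#'   `templates` (the torsion states used).
#' @export
generate_trajectory <- function(spec, topology) {
  n_states <- length(spec$populations)
  templates <- spec$template
  if (is.character(templates)) {
    if (length(templates) == 1L && n_states > 1L)
      templates <- c("helix", "extended", "twisted_s")[seq_len(n_states)]
    templates <- lapply(templates, template_torsions, topology = topology)
  }
  if (length(templates) != n_states)
    stop("value error: one template per mixture state required")
  set.seed(as.integer(spec$seed))
  labels <- sample.int(n_states, spec$n_frames, replace = TRUE,
                       prob = spec$populations)
  n <- nrow(topology$residues)
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    tt <- templates[[labels[f]]]
    ts <- torsion_state(tt$position_index,
                        wrap_angle(tt$phi + rnorm(n, 0, spec$noise_sd)),
                        wrap_angle(tt$psi + rnorm(n, 0, spec$noise_sd)))
    frames[[f]] <- build_conformation(topology, ts,
                                      sprintf("synthetic_frame_%d", f))
  }
  list(trajectory = trajectory(topology, frames), labels = labels,
       templates = templates)
}

# protons (and pseudo-protons) considered by the NOE forward model
.NOE_ROLES <- c("H_N", "H_A", "ring_H5", "SC_centroid")

#' Forward-model a ROESY peak table from a conformation
#'
#' Every proton/pseudo-proton pair (`H_N`, `H_A`, `ring_H5`, side-chain
#' centroid) within `max_distance` yields a peak with intensity
#' `I_ref * (r_ref / r)^6 * exp(eps)`, `eps ~ N(0, sigma_log^2)`, plus one
#' noise-free synthetic calibration peak at exactly `r_ref`. At
#' `sigma_log = 0` this is the exact inverse of [peaks_to_distances()].
#'
#' @param conf A `conformation`.
#' @param r_ref Reference distance (Angstrom).
#' @param I_ref Reference intensity.
#' @param max_distance NOE cutoff (Angstrom, default 5).
#' @param sigma_log Log-normal noise sd (default 0.1).
#' @param seed Integer seed.
#' @return A [roesy_peaks()] table (empty, with a warning, if no pair is
#'   within the cutoff).
#' @export
forward_roesy <- function(conf, r_ref = 2.5, I_ref = 1.0, max_distance = 5,
                          sigma_log = 0.1, seed = 1L) {
  stopifnot(r_ref > 0, I_ref > 0)
  topo <- conf$topology
  at <- topo$atoms
  prot <- which(at$role %in% .NOE_ROLES)
  pairs <- which(upper.tri(diag(length(prot))), arr.ind = TRUE)
  a <- prot[pairs[, 1]]; b <- prot[pairs[, 2]]
  d <- sqrt(rowSums((conf$coords[a, , drop = FALSE] -
                       conf$coords[b, , drop = FALSE])^2))
  keep <- d <= max_distance & at$position[a] != at$position[b]
  if (!any(keep)) {
    warning("no proton pair within the NOE cutoff: empty peak table")
    empty <- data.frame(res_a = integer(), role_a = character(),
                        res_b = integer(), role_b = character(),
                        intensity = numeric(), is_ref = logical(),
                        r_ref = numeric(), true_distance = numeric(),
                        stringsAsFactors = FALSE)
    class(empty) <- c("roesy_peaks", "data.frame")
    return(empty)
  }
  a <- a[keep]; b <- b[keep]; d <- d[keep]
  set.seed(as.integer(seed))
  eps <- rnorm(length(d), 0, sigma_log)
  pk <- data.frame(
    res_a = at$position[a], role_a = at$role[a],
    res_b = at$position[b], role_b = at$role[b],
    intensity = I_ref * (r_ref / d)^6 * exp(eps),
    is_ref = FALSE, r_ref = NA_real_, true_distance = d,
    stringsAsFactors = FALSE)
  # noise-free synthetic calibration pair at exactly r_ref
  ref_row <- data.frame(res_a = 0L, role_a = "calibration", res_b = 0L,
                        role_b = "calibration", intensity = I_ref,
                        is_ref = TRUE, r_ref = r_ref, true_distance = r_ref,
                        stringsAsFactors = FALSE)
  validate_roesy_peaks(rbind(pk, ref_row))
}

#' Ideal-gas point-set frames for RDF null tests
#'
#' Uniform random points at the requested density in a cube of the given
#' half-width around a fixed origin reference atom; the per-frame point count
#' is Poisson with mean `density * (2 * half_width)^3`. Optionally plants one
#' point at a fixed radius in every frame (delta-peak test input).
#'
#' @param density Number density (Angstrom^-3).
#' @param half_width Cube half-width (Angstrom).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @param planted_radius Optional fixed radius for one planted point per frame.
#' @return List: `frames` (list of n x 3 matrices), `reference` (the origin).
#' @export
ideal_gas_frames <- function(density, half_width, n_frames, seed = 1L,
                             planted_radius = NULL) {
  if (density <= 0 || half_width <= 0)
    stop("value error: density and half_width must be > 0")
  if (n_frames < 1L) stop("value error: n_frames must be >= 1")
  set.seed(as.integer(seed))
  mu <- density * (2 * half_width)^3
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    m <- stats::rpois(1, mu)
    pts <- matrix(runif(3 * m, -half_width, half_width), ncol = 3)
    if (!is.null(planted_radius)) {
      u <- rnorm(3)
      pts <- rbind(pts, planted_radius * u / sqrt(sum(u^2)))
    }
    frames[[f]] <- pts
  }
  list(frames = frames, reference = c(0, 0, 0))
}

#' Plant contradictory (unsatisfiable) restraints into a set
#'
#' Test fixture for the pruning loop: adds upper-bound restraints whose bound
#' lies below the covalent-geometry minimum distance of an intra-residue
#' proton pair on the first and last residues. Because no backbone torsion can
#' satisfy them, their penalty exceeds the ceiling in every replica, so a
#' correct pruning loop must remove exactly these. (A loose long-range bound,
#' e.g. 2 Angstrom between chain termini, is NOT contradictory for upper-bound
#' restraints: the chain can always compact to satisfy it.) The default bound
#' of 0.5 Angstrom sits well below the ~1.26 Angstrom eclipsed minimum of a
#' geminal proton pair, so the residual penalty is at least ~18 kcal/mol.
#'
#' @param set A [restraint_set()].
#' @param topology The matching [foldamer_topology].
#' @param r_upper Planted bound (Angstrom, default 0.5).
#' @param k Force constant (default 32).
#' @return List: `set` (with planted restraints appended), `planted_ids`.
#' @export
plant_artifact_restraints <- function(set, topology, r_upper = 0.5,
                                      k = .DEFAULT_K_RESTRAINT) {
  res <- topology$residues
  pick <- function(pos) {
    roles <- topology$atoms$role[topology$atoms$position == pos]
    if (all(c("H_A", "SC_centroid") %in% roles))
      c("H_A", "SC_centroid")
    else if (all(c("H_N", "H_A") %in% roles))
      c("H_N", "H_A")
    else stop("value error: no intra-residue proton pair at this position")
  }
  targets <- c(res$position_index[1], res$position_index[nrow(res)])
  rs <- set$restraints
  next_id <- if (nrow(rs)) max(rs$id) + 1L else 1L
  planted <- do.call(rbind, lapply(seq_along(targets), function(i) {
    roles <- pick(targets[i])
    data.frame(id = next_id + i - 1L, res_a = targets[i], role_a = roles[1],
               res_b = targets[i], role_b = roles[2], r_upper = r_upper,
               k = k, active = TRUE, source = "planted_artifact",
               stringsAsFactors = FALSE)
  }))
  list(set = restraint_set(rbind(rs, planted), set$history),
       planted_ids = planted$id)
}
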