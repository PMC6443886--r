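# Trajectory analytics: superposed RMSD series, radius-of-gyration series,
# phi/psi distributions, hierarchical RMSD clustering with representative
# (medoid) selection and cluster merging, and radial distribution functions.

#' Trajectory container
#'
#' Ordered conformations sharing one topology, with optional frame times and
#' an analysis window (frame indices). Windows are frame-index based: protocol
#' statements like "the last half" map to window fractions because the
#' desk-scale sampler has no physical time.
#'
#' @param topology A [foldamer_topology].
#' @param frames A 3-D array `(atoms, 3, frames)`, or a list of `conformation`
#'   objects / coordinate matrices.
#' @param times Optional frame times (ps).
#' @param window Length-2 integer vector (first, last frame), default all.
#' @return A `trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL, window = NULL) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("value error: trajectory needs >= 1 frame")
    mats <- lapply(frames, function(f)
      if (inherits(f, "conformation")) f$coords else as.matrix(f))
    frames <- array(unlist(mats), dim = c(nrow(mats[[1]]), 3, length(mats)))
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[2] == 3L)
  if (dim(frames)[3] < 1L) stop("value error: trajectory needs >= 1 frame")
  if (dim(frames)[1] != nrow(topology$atoms))
    stop("value error: frame atom count does not match the topology")
  if (is.null(window)) window <- c(1L, dim(frames)[3])
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > dim(frames)[3] || window[1] > window[2])
    stop("value error: analysis window out of bounds")
  structure(list(topology = topology, coords = frames, times = times,
                 window = window), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, window [%d, %d]\n",
              n_frames(x), dim(x$coords)[1], x$window[1], x$window[2]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count (ignores the window).
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Set the analysis window of a trajectory
#'
#' @param traj A [trajectory()].
#' @param first,last Frame indices; alternatively `fraction` keeps the last
#'   given fraction of frames (e.g. 0.5 for the converged second half).
#' @param fraction Optional trailing fraction in (0, 1].
#' @return The trajectory with an updated window.
#' @export
set_window <- function(traj, first = NULL, last = NULL, fraction = NULL) {
  nf <- n_frames(traj)
  if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    first <- nf - max(1L, floor(nf * fraction)) + 1L
    last <- nf
  }
  if (is.null(first)) first <- traj$window[1]
  if (is.null(last)) last <- traj$window[2]
  trajectory(traj$topology, traj$coords, traj$times, c(first, last))
}

# frames of the window restricted to a selection, as an (atoms, 3, frames) cube
.window_cube <- function(traj, selection) {
  idx <- seq(traj$window[1], traj$window[2])
  traj$coords[selection, , idx, drop = FALSE]
}

#' Frame as a conformation
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @return A `conformation`.
#' @export
frame_conformation <- function(traj, i) {
  coords <- traj$coords[, , i]
  rownames(coords) <- traj$topology$atoms$label
  conformation(traj$topology, coords, sprintf("frame_%d", i))
}

#' Per-frame superposed RMSD against a reference structure
#'
#' Each window frame is optimally superposed (Kabsch, proper rotations only)
#' onto the reference over the backbone selection; the convention follows the
#' protocol of measuring against the starting/heat-up structure rather than
#' the trajectory mean.
#'
#' @param traj A [trajectory()].
#' @param reference A `conformation` or coordinate matrix.
#' @param selection Atom indices (default: topology backbone selection).
#' @return Numeric vector of RMSD (Angstrom), one per window frame.
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  if (is.null(selection)) selection <- backbone_selection(traj$topology)
  if (length(selection) < 3L) stop("value error: selection too small")
  ref <- if (inherits(reference, "conformation")) reference$coords else
    as.matrix(reference)
  if (nrow(ref) == nrow(traj$topology$atoms))
    ref <- ref[selection, , drop = FALSE]
  if (nrow(ref) != length(selection))
    stop("value error: selection mismatch between trajectory and reference")
  as.numeric(.rmsd_to_ref_cpp(.window_cube(traj, selection), ref))
}

#' Radius-of-gyration series over the analysis window
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (default backbone).
#' @param mass_weighted Mass-weighted by default.
#' @return Numeric vector (Angstrom) per window frame.
#' @export
rog_series <- function(traj, selection = NULL, mass_weighted = TRUE) {
  if (is.null(selection)) selection <- backbone_selection(traj$topology)
  if (length(selection) < 1L) stop("value error: empty selection")
  w <- if (mass_weighted) traj$topology$atoms$mass[selection] else
    rep(1, length(selection))
  cube <- .window_cube(traj, selection)
  vapply(seq_len(dim(cube)[3]), function(i)
    radius_of_gyration.default(cube[, , i], weights = w), 0)
}

#' Ramachandran-style torsion distribution of a trajectory
#'
#' Measures every residue's (phi, psi) on each window frame and pools them
#' into a 2-D histogram on `(-180, 180]^2`. Undefined dihedrals are skipped
#' and counted.
#'
#' @param traj A [trajectory()].
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return List: `samples` (long data frame: frame, position_index, phi, psi),
#'   `histogram` (counts matrix, phi rows x psi columns), `breaks`,
#'   `n_undefined`.
#' @export
torsion_distribution <- function(traj, bin_width = 5) {
  stopifnot(bin_width > 0)
  topo <- traj$topology
  n <- nrow(topo$residues)
  quads <- rbind(topo$phi_quads, topo$psi_quads) - 1L
  idx <- seq(traj$window[1], traj$window[2])
  samples <- lapply(idx, function(f) {
    ang <- .measure_dihedrals_cpp(traj$coords[, , f], quads)
    data.frame(frame = f, position_index = topo$residues$position_index,
               phi = ang[seq_len(n)], psi = ang[n + seq_len(n)])
  })
  samples <- do.call(rbind, samples)
  breaks <- seq(-180, 180, by = bin_width)
  ok <- !is.na(samples$phi) & !is.na(samples$psi)
  # bin by right-closed intervals matching the (-180, 180] angle range
  bi <- function(a) pmin(pmax(ceiling((a + 180) / bin_width), 1L),
                         length(breaks) - 1L)
  h <- matrix(0L, length(breaks) - 1L, length(breaks) - 1L,
              dimnames = list(phi = NULL, psi = NULL))
  if (any(ok)) {
    tab <- table(factor(bi(samples$phi[ok]), levels = seq_len(nrow(h))),
                 factor(bi(samples$psi[ok]), levels = seq_len(ncol(h))))
    h <- h + unclass(tab)
  }
  list(samples = samples, histogram = h, breaks = breaks,
       n_undefined = sum(!ok))
}

#' Hierarchical RMSD clustering of trajectory frames
#'
#' Agglomerative clustering (average linkage by default, following the
#' reference implementation's default; single/complete available) on the
#' pairwise superposed backbone RMSD matrix of the window frames, cut at
#' `n_clusters`. Clusters are relabelled by decreasing population; the
#' representative of a cluster is its medoid (the member minimizing mean RMSD
#' to the other members).
#'
#' @param traj A [trajectory()].
#' @param n_clusters Number of clusters (default 10, the protocol value).
#' @param selection Atom indices (default backbone selection).
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return A `cluster_result`: `labels` (per window frame), `populations`,
#'   `representatives` (frame indices into the trajectory), `rep_rmsd`
#'   (pairwise representative RMSD matrix), `rmsd_matrix`, `frames` (window
#'   frame indices), `linkage`, `merge_log`.
#' @export
cluster_frames <- function(traj, n_clusters = 10, selection = NULL,
                           linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.null(selection)) selection <- backbone_selection(traj$topology)
  idx <- seq(traj$window[1], traj$window[2])
  nf <- length(idx)
  if (n_clusters < 1L) stop("value error: n_clusters must be >= 1")
  if (n_clusters > nf)
    stop("value error: n_clusters exceeds the number of window frames")
  D <- .pairwise_rmsd_cpp(.window_cube(traj, selection))
  hc <- hclust(stats::as.dist(D), method = linkage)
  raw <- cutree(hc, k = n_clusters)
  .cluster_result(raw, D, idx, linkage)
}

# shared assembly: relabel by decreasing size, medoids, representative RMSDs
.cluster_result <- function(labels, D, frames, linkage, merge_log = list()) {
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  lab <- unname(relabel[as.character(labels)])
  k <- length(sizes)
  reps <- integer(k)
  for (c in seq_len(k)) {
    members <- which(lab == c)
    if (length(members) == 1L) {
      reps[c] <- members
    } else {
      sub <- D[members, members, drop = FALSE]
      reps[c] <- members[which.min(rowMeans(sub))]
    }
  }
  rep_rmsd <- D[reps, reps, drop = FALSE]
  dimnames(rep_rmsd) <- list(seq_len(k), seq_len(k))
  structure(list(
    labels = lab,
    populations = as.numeric(table(lab)) / length(lab),
    representatives = frames[reps],
    rep_rmsd = rep_rmsd,
    rmsd_matrix = D,
    frames = frames,
    linkage = linkage,
    merge_log = merge_log
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d frames (%s linkage)\n",
              length(x$populations), length(x$labels), x$linkage))
  cat("  populations:",
      paste(sprintf("%.3f", x$populations), collapse = " "), "\n")
  invisible(x)
}

#' Merge clusters whose representatives are within an RMSD threshold
#'
#' Iteratively merges the closest pair of clusters whose representative-to-
#' representative backbone RMSD is below the threshold (default 1.0 Angstrom),
#' re-summing populations and recomputing the merged representative, until no
#' pair qualifies. With threshold 0 nothing merges.
#'
#' @param result A `cluster_result` from [cluster_frames()].
#' @param traj The trajectory it was computed on (unused when the result
#'   retains its RMSD matrix; kept for interface stability).
#' @param threshold Merge threshold in Angstrom.
#' @return An updated `cluster_result` with a `merge_log`.
#' @export
merge_similar_clusters <- function(result, traj = NULL, threshold = 1.0) {
  if (threshold < 0) stop("value error: threshold must be >= 0")
  lab <- result$labels
  D <- result$rmsd_matrix
  log <- result$merge_log
  repeat {
    k <- length(unique(lab))
    if (k < 2L) break
    res <- .cluster_result(lab, D, result$frames, result$linkage, log)
    rr <- res$rep_rmsd
    diag(rr) <- Inf
    if (min(rr) >= threshold || min(rr) == Inf) {
      result <- res
      break
    }
    at <- which(rr == min(rr), arr.ind = TRUE)[1, ]
    keep <- min(at); drop <- max(at)
    log[[length(log) + 1L]] <- list(
      merged = as.integer(c(keep, drop)),
      rep_rmsd = min(rr),
      population = sum(res$populations[c(keep, drop)]))
    lab <- res$labels
    lab[lab == drop] <- keep
  }
  if (length(unique(lab)) < 2L)
    result <- .cluster_result(lab, D, result$frames, result$linkage, log)
  result
}

#' Radial distribution function
#'
#' `g(r)` in bin `b` is the pair count in the bin divided by
#' `frames * n_ref * 4 pi r_b^2 dr * density`, with `r_b` the bin center. The
#' default normalization density is the conventional bulk number density of
#' water, 0.033456 per cubic Angstrom; override for other solvents. Inputs are
#' non-periodic point sets (no minimum-image handling; documented limitation).
#'
#' @param x A [trajectory()] (with `reference`/`target` as atom indices), or a
#'   list of per-frame target coordinate matrices (with `reference` a fixed
#'   point or matrix of points).
#' @param reference Reference selection (atom indices) or point(s).
#' @param target Target selection (trajectory method only).
#' @param bin_width Bin spacing in Angstrom (default 0.1).
#' @param density Normalization number density (Angstrom^-3).
#' @param r_max Histogram range (Angstrom).
#' @return An `rdf_profile`: bin `edges`, centers `r`, `g`, raw `counts`,
#'   normalization metadata.
#' @export
compute_rdf <- function(x, reference, target = NULL, bin_width = 0.1,
                        density = .WATER_DENSITY, r_max = 12) {
  if (bin_width <= 0) stop("value error: bin width must be > 0")
  if (inherits(x, "trajectory")) {
    if (is.null(target) || length(target) == 0L)
      stop("value error: empty target selection")
    if (length(reference) == 0L) stop("value error: empty reference selection")
    idx <- seq(x$window[1], x$window[2])
    frames <- lapply(idx, function(f)
      matrix(x$coords[target, , f], ncol = 3))
    refs <- lapply(idx, function(f)
      matrix(x$coords[reference, , f], ncol = 3))
  } else {
    frames <- lapply(x, as.matrix)
    if (length(frames) == 0L) stop("value error: zero frames")
    if (is.list(reference)) {
      refs <- lapply(reference, as.matrix)
    } else {
      ref <- if (is.matrix(reference)) reference else
        matrix(reference, ncol = 3)
      refs <- rep(list(ref), length(frames))
    }
  }
  n_ref <- nrow(refs[[1]])
  edges <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(edges) - 1L)
  for (f in seq_along(frames)) {
    tg <- frames[[f]]
    rf <- refs[[f]]
    for (a in seq_len(nrow(rf))) {
      d2 <- (tg[, 1] - rf[a, 1])^2 + (tg[, 2] - rf[a, 2])^2 +
        (tg[, 3] - rf[a, 3])^2
      d <- sqrt(d2[d2 > 1e-12])  # drop self-pairs
      d <- d[d < r_max]
      if (length(d))
        counts <- counts + tabulate(pmin(floor(d / bin_width) + 1L,
                                         length(counts)),
                                    nbins = length(counts))
    }
  }
  r_b <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- 4 * pi * r_b^2 * bin_width
  g <- counts / (length(frames) * n_ref * shell * density)
  structure(list(edges = edges, r = r_b, g = g, counts = counts,
                 density = density, bin_width = bin_width,
                 n_frames = length(frames), n_ref = n_ref),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf(
    "rdf_profile: %d bins of %.2f A over %d frames; peak g=%.2f at r=%.2f A\n",
    length(x$g), x$bin_width, x$n_frames, x$g[pk], x$r[pk]))
  invisible(x)
}

#' Write analysis series as TSV
#'
#' @param values Numeric vector (e.g. RMSD or ROG series).
#' @param path Output path.
#' @param name Column name.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(values, path, name = "value") {
  df <- data.frame(frame = seq_along(values), value = values)
  names(df)[2] <- name
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
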