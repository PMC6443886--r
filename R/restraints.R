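# ROESY cross-peaks -> upper-bound interproton distance restraints, and the
# AMBER-style flat-bottom harmonic penalty. Distances use the isolated
# spin-pair calibration r = r_ref * (I_ref / I)^(1/6) against a single
# reference peak of known distance.

#' ROESY cross-peak table
#'
#' @param res_a,res_b Position indices of the two protons.
#' @param role_a,role_b Proton roles (`H_N`, `H_A`, `ring_H5`, `SC_centroid`).
#' @param intensity Integrated cross-peak intensity (arbitrary positive units).
#' @param is_ref Logical flag; exactly one peak must be the calibration
#'   reference.
#' @param r_ref Known distance (Angstrom) of the reference pair; `NA`
#'   elsewhere.
#' @return A `roesy_peaks` data frame.
#' @export
roesy_peaks <- function(res_a, role_a, res_b, role_b, intensity, is_ref,
                        r_ref = NA_real_) {
  pk <- data.frame(res_a = as.integer(res_a), role_a = as.character(role_a),
                   res_b = as.integer(res_b), role_b = as.character(role_b),
                   intensity = as.numeric(intensity),
                   is_ref = as.logical(is_ref),
                   r_ref = as.numeric(r_ref), stringsAsFactors = FALSE)
  validate_roesy_peaks(pk)
}

validate_roesy_peaks <- function(pk) {
  if (any(!is.finite(pk$intensity)) || any(pk$intensity <= 0))
    stop("value error: all peak intensities must be positive")
  n_ref <- sum(pk$is_ref)
  if (n_ref != 1L)
    stop(sprintf(
      "configuration error: exactly one reference peak required, found %d",
      n_ref))
  if (!is.finite(pk$r_ref[pk$is_ref]) || pk$r_ref[pk$is_ref] <= 0)
    stop("configuration error: reference peak must carry a positive r_ref")
  class(pk) <- c("roesy_peaks", "data.frame")
  pk
}

#' Convert ROESY intensities to interproton distances
#'
#' Isolated spin-pair calibration: `r = r_ref * (I_ref / I)^(1/6)`. Only the
#' ratio `I_ref / I` enters, so rescaling all intensities by a constant leaves
#' every distance unchanged. The reference peak maps to exactly `r_ref`.
#'
#' @param peaks A [roesy_peaks()] table.
#' @return Data frame of proton pairs with a `distance` column (Angstrom).
#' @export
peaks_to_distances <- function(peaks) {
  peaks <- validate_roesy_peaks(as.data.frame(peaks))
  ref <- peaks[peaks$is_ref, ]
  out <- peaks[, c("res_a", "role_a", "res_b", "role_b")]
  out$distance <- ref$r_ref * (ref$intensity / peaks$intensity)^(1 / 6)
  out
}

#' Build an upper-bound restraint set from distances
#'
#' Upper bounds are `distance + slack`. The default slack is 0; NOE practice
#' often adds 0.5-1.0 Angstrom of calibration tolerance, so it is exposed.
#'
#' @param distances Data frame with `res_a`, `role_a`, `res_b`, `role_b`,
#'   `distance` (e.g. from [peaks_to_distances()]).
#' @param k Force constant, kcal mol^-1 A^-2 (default 32, the AMBER-style
#'   upper-bound value).
#' @param slack Added to every distance (Angstrom, >= 0).
#' @return A `restraint_set`.
#' @export
distances_to_restraints <- function(distances, k = .DEFAULT_K_RESTRAINT,
                                    slack = 0) {
  if (k < 0) stop("value error: force constant must be >= 0")
  if (slack < 0) stop("value error: slack must be >= 0")
  if (nrow(distances) == 0L) return(restraint_set())
  restraint_set(data.frame(
    id = seq_len(nrow(distances)),
    res_a = distances$res_a, role_a = distances$role_a,
    res_b = distances$res_b, role_b = distances$role_b,
    r_upper = distances$distance + slack,
    k = k, active = TRUE,
    source = sprintf("peak_%d", seq_len(nrow(distances))),
    stringsAsFactors = FALSE
  ))
}

#' Restraint-set container
#'
#' An ordered table of upper-bound interproton restraints plus the pruning
#' history accumulated by [prune_once()] / [refine()]. Removal during pruning
#' deactivates a restraint (audit trail preserved) rather than deleting it.
#'
#' @param restraints Data frame with columns `id`, `res_a`, `role_a`, `res_b`,
#'   `role_b`, `r_upper`, `k`, `active`, `source`.
#' @param history List of pruning iterations.
#' @return A `restraint_set`.
#' @export
restraint_set <- function(restraints = NULL, history = list()) {
  if (is.null(restraints))
    restraints <- data.frame(id = integer(), res_a = integer(),
                             role_a = character(), res_b = integer(),
                             role_b = character(), r_upper = numeric(),
                             k = numeric(), active = logical(),
                             source = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(restraints$id))
    stop("value error: restraint ids must be unique")
  if (any(restraints$r_upper <= 0))
    stop("value error: r_upper must be positive")
  if (any(restraints$k < 0))
    stop("value error: force constants must be >= 0")
  structure(list(restraints = restraints, history = history),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d restraints (%d active), %d pruning iteration(s)\n",
              nrow(x$restraints), sum(x$restraints$active), length(x$history)))
  invisible(x)
}

# resolve proton references of a restraint table to atom indices
.resolve_restraint_atoms <- function(topology, restraints) {
  n <- nrow(restraints)
  a <- b <- integer(n)
  for (i in seq_len(n)) {
    a[i] <- atom_index(topology, restraints$res_a[i], restraints$role_a[i])
    b[i] <- atom_index(topology, restraints$res_b[i], restraints$role_b[i])
  }
  cbind(a, b)
}

#' Flat-bottom harmonic restraint energy
#'
#' `E = k * max(0, r - r_upper)^2` (AMBER upper-bound convention, `k * delta^2`
#' rather than `k/2 * delta^2`): zero inside the bound, harmonic beyond it,
#' continuous and once-differentiable at the bound. With the default
#' `k = 32 kcal mol^-1 A^-2`, a violation of 1 Angstrom costs 32 kcal/mol.
#'
#' @param restraint One-row restraint data frame (or list) with `res_a`,
#'   `role_a`, `res_b`, `role_b`, `r_upper`, `k`.
#' @param conf A `conformation`.
#' @return Penalty in kcal/mol.
#' @export
restraint_energy <- function(restraint, conf) {
  restraint <- as.data.frame(restraint, stringsAsFactors = FALSE)
  ab <- .resolve_restraint_atoms(conf$topology, restraint)
  r <- sqrt(sum((conf$coords[ab[1, 1], ] - conf$coords[ab[1, 2], ])^2))
  viol <- max(0, r - restraint$r_upper)
  restraint$k * viol^2
}

#' Total restraint energy of a conformation
#'
#' @param set A [restraint_set()].
#' @param conf A `conformation`.
#' @return List with `total` (sum over ACTIVE restraints, kcal/mol) and
#'   `penalties` (per-restraint penalties for all restraints, active or not;
#'   inactive restraints are reported but excluded from the total).
#' @export
total_restraint_energy <- function(set, conf) {
  rs <- set$restraints
  if (nrow(rs) == 0L)
    return(list(total = 0, penalties = numeric()))
  ab <- .resolve_restraint_atoms(conf$topology, rs)
  d <- sqrt(rowSums((conf$coords[ab[, 1], , drop = FALSE] -
                       conf$coords[ab[, 2], , drop = FALSE])^2))
  pen <- rs$k * pmax(0, d - rs$r_upper)^2
  list(total = sum(pen[rs$active]),
       penalties = setNames(pen, rs$id))
}

#' Read / write restraint and peak tables (TSV)
#'
#' Plain-text interchange: the peak table has columns `res_a role_a res_b
#' role_b intensity is_ref r_ref` (blank `r_ref` except on the reference
#' row); the restraint table has `res_a role_a res_b role_b r_upper k active`.
#'
#' @param path File path.
#' @param peaks,set Objects to write.
#' @return The read object, or (for writers) `path` invisibly.
#' @export
read_roesy_tsv <- function(path) {
  pk <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_roesy_peaks(pk)
}

#' @rdname read_roesy_tsv
#' @export
write_roesy_tsv <- function(peaks, path) {
  write.table(as.data.frame(peaks), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname read_roesy_tsv
#' @export
read_restraints_tsv <- function(path) {
  rs <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(rs$id)) rs$id <- seq_len(nrow(rs))
  if (is.null(rs$active)) rs$active <- TRUE
  if (is.null(rs$source)) rs$source <- "file"
  restraint_set(rs)
}

#' @rdname read_roesy_tsv
#' @export
write_restraints_tsv <- function(set, path) {
  write.table(set$restraints, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
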