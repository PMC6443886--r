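# Shared geometry kernel: signed dihedrals, Kabsch superposition, radius of
# gyration. Thin wrappers around the compiled routines with input checking.

#' Signed dihedral angle of four points
#'
#' IUPAC convention: eclipsed (cis) = 0 degrees, sign by the right-hand rule
#' along the central bond `p2 -> p3`; range `(-180, 180]`. Reversing the atom
#' order negates the angle.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral in degrees, or `NA` (with a warning) when either outer
#'   triplet is collinear and the dihedral is undefined.
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180 (trans)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  pts <- list(p1, p2, p3, p4)
  if (any(!vapply(pts, function(p) is.numeric(p) && length(p) == 3L, TRUE)))
    stop("each point must be a numeric vector of length 3")
  if (sqrt(sum((p2 - p3)^2)) < 1e-12)
    stop("zero-length central bond: p2 and p3 coincide")
  ang <- .dihedral_cpp(as.numeric(p1), as.numeric(p2), as.numeric(p3),
                       as.numeric(p4))
  if (is.na(ang))
    warning("collinear triplet: dihedral undefined, returning NA")
  ang
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of `mobile` onto `reference` using the SVD-based
#' Kabsch algorithm, restricted to proper rotations (reflections excluded via
#' the determinant correction).
#'
#' @param mobile,reference Numeric n x 3 matrices with matched rows (n >= 3).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `transformed` (the superposed mobile coordinates). The
#'   transform maps mobile points x to `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("point sets must be n x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop("point sets must have the same number of matched points")
  if (nrow(mobile) < 3L)
    stop("at least 3 matched points are required")
  ctr <- sweep(mobile, 2, colMeans(mobile))
  if (sum(svd(ctr)$d > 1e-9) < 2L)
    stop("all points are collinear: superposition is degenerate")
  fit <- .kabsch_cpp(mobile, reference)
  fit$translation <- as.numeric(fit$translation)
  fit$transformed <- mobile %*% t(fit$rotation) +
    matrix(fit$translation, nrow(mobile), 3, byrow = TRUE)
  fit
}

#' Radius of gyration
#'
#' `sqrt(sum(w_i * |x_i - xbar|^2) / sum(w_i))` with `xbar` the (weighted)
#' centroid. For a [conformation], the default selection is the topology's
#' backbone atoms and weights are atomic masses (side-chain centroids carry the
#' summed heavy-atom mass of the side chain they replace).
#'
#' @param x A [conformation] or an n x 3 coordinate matrix.
#' @param selection Integer atom indices (conformation method); default the
#'   topology backbone selection.
#' @param mass_weighted Use atomic masses as weights (default `TRUE`);
#'   otherwise unit weights.
#' @param weights Optional explicit weights (matrix method).
#' @param ... Passed between methods.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(x, ...) UseMethod("radius_of_gyration")

#' @rdname radius_of_gyration
#' @export
radius_of_gyration.default <- function(x, weights = NULL, ...) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("empty selection: no atoms to measure")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (length(weights) != nrow(x)) stop("weights length must match points")
  w <- weights / sum(weights)
  ctr <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)))
}

#' @rdname radius_of_gyration
#' @export
radius_of_gyration.conformation <- function(x, selection = NULL,
                                            mass_weighted = TRUE, ...) {
  if (is.null(selection)) selection <- backbone_selection(x$topology)
  if (length(selection) < 1L) stop("empty selection: no atoms to measure")
  w <- if (mass_weighted) x$topology$atoms$mass[selection] else
    rep(1, length(selection))
  radius_of_gyration.default(x$coords[selection, , drop = FALSE], weights = w)
}
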