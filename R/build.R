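# Conformation building from backbone torsions and the inverse measurement.

#' Construct a torsion state
#'
#' One (phi, psi) pair per residue (never per ring), angles in degrees in
#' `(-180, 180]`.
#'
#' @param position_index Residue position indices.
#' @param phi,psi Backbone torsions in degrees.
#' @param convention Tag identifying the torsion-definition table.
#' @return A `torsion_state` data frame.
#' @export
torsion_state <- function(position_index, phi, psi,
                          convention = "tz4-shortpath") {
  stopifnot(length(position_index) == length(phi),
            length(phi) == length(psi))
  ok <- function(a) all(is.na(a) | (a > -180 & a <= 180))
  if (!ok(phi) || !ok(psi))
    stop("value error: torsions must lie in (-180, 180]")
  structure(data.frame(position_index = as.integer(position_index),
                       phi = as.numeric(phi), psi = as.numeric(psi)),
            convention = convention,
            class = c("torsion_state", "data.frame"))
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  w <- a - 360 * ceiling((a - 180) / 360)
  w[w == -180] <- 180
  w
}

# flat torsion vector (phi1, psi1, phi2, ...) in residue order for the builder
.torsion_vector <- function(topology, torsions) {
  res <- topology$residues
  if (!all(c("position_index", "phi", "psi") %in% names(torsions)))
    stop("value error: torsions must have position_index, phi and psi")
  ring_pos <- setdiff(seq_len(max(res$position_index)), res$position_index)
  if (any(torsions$position_index %in% ring_pos))
    stop("value error: torsion supplied for a ring position")
  m <- match(res$position_index, torsions$position_index)
  if (anyNA(m))
    stop(sprintf("value error: missing torsion entry for position(s) %s",
                 paste(res$position_index[is.na(m)], collapse = ", ")))
  v <- as.numeric(rbind(torsions$phi[m], torsions$psi[m]))
  if (anyNA(v)) stop("value error: NA torsion value")
  v
}

#' Build a 3-D conformation from backbone torsions
#'
#' Atoms are placed by sequential internal-coordinate (NeRF) construction from
#' the fixed ideal-geometry table; triazole rings are rigid planar pentagons,
#' amide omega is fixed trans, and CB is placed to satisfy the residue's
#' chirality flag. Re-measuring the torsions of the output with
#' [measure_torsions()] reproduces the input.
#'
#' @param topology A [foldamer_topology].
#' @param torsions A [torsion_state()] covering every residue.
#' @param provenance Optional free-text metadata.
#' @return A `conformation` object (topology reference, coordinates in
#'   Angstrom, provenance).
#' @export
build_conformation <- function(topology, torsions, provenance = "builder") {
  v <- .torsion_vector(topology, torsions)
  zm <- topology$zmatrix
  xyz <- .build_chain_cpp(zm[, 1:3, drop = FALSE] - 1L, zm[, "bond"],
                          zm[, "angle"], zm[, "toroff"],
                          as.integer(zm[, "link"]), v)
  rownames(xyz) <- topology$atoms$label
  conformation(topology, xyz, provenance)
}

#' Conformation container
#'
#' @param topology A [foldamer_topology].
#' @param coords n x 3 coordinate matrix (Angstrom), one row per atom.
#' @param provenance Free-text metadata (generator, seed, frame index).
#' @return A `conformation` object.
#' @export
conformation <- function(topology, coords, provenance = "") {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topology$atoms) || ncol(coords) != 3L)
    stop("value error: coordinate count must equal atom count")
  if (!all(is.finite(coords)))
    stop("value error: non-finite coordinates")
  structure(list(topology = topology, coords = coords,
                 provenance = provenance), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: %d atoms (%s)\n", nrow(x$coords),
              if (nzchar(x$provenance)) x$provenance else "no provenance"))
  invisible(x)
}

#' Measure backbone torsions of a conformation
#'
#' Signed dihedrals in the IUPAC convention over the triazole-aware quadruples:
#' amide phi = C(prev)-N-CA-C, psi = N-CA-C-N(next); 4n phi ends at ring C4
#' with psi = N-CA-C4-C5; 4c phi = C5-N1-CA-C with psi = N1-CA-C-N(next). The
#' C-terminal psi is measured to the ester oxygen and the first phi to the
#' N-cap carbonyl (or amine proton for uncapped chains).
#'
#' @param conf A `conformation`.
#' @return A [torsion_state()]; undefined dihedrals (collinear central
#'   triplet) are reported as `NA` with a warning.
#' @export
measure_torsions <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  topo <- conf$topology
  n <- nrow(topo$residues)
  quads <- rbind(topo$phi_quads, topo$psi_quads)
  ang <- .measure_dihedrals_cpp(conf$coords, quads - 1L)
  if (anyNA(ang))
    warning("undefined dihedral(s): collinear central triplet, reported as NA")
  torsion_state(topo$residues$position_index, ang[seq_len(n)],
                ang[n + seq_len(n)])
}

#' Measure residue chirality labels from coordinates
#'
#' Uses the sign of the CA improper dihedral (CB-CA-N-C); mirroring the
#' coordinates flips every L to D and vice versa. Glycine is achiral.
#'
#' @param conf A `conformation`.
#' @return Character vector of `"L"`, `"D"`, `"achiral"` per residue.
#' @export
measure_chirality <- function(conf) {
  topo <- conf$topology
  res <- topo$residues
  out <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    if (res$chirality[i] == "achiral") {
      out[i] <- "achiral"
      next
    }
    cb <- atom_index(topo, res$position_index[i], "CB")
    ca <- atom_index(topo, res$position_index[i], "CA")
    nl <- topo$phi_quads[i, 2]
    cl <- topo$phi_quads[i, 4]
    imp <- .dihedral_cpp(conf$coords[cb, ], conf$coords[ca, ],
                         conf$coords[nl, ], conf$coords[cl, ])
    out[i] <- if (is.na(imp)) NA_character_ else if (imp < 0) "L" else "D"
  }
  out
}

#' All-trans (fully extended) torsion state for a topology
#'
#' @param topology A [foldamer_topology].
#' @return A [torsion_state()] with every phi and psi at 180 degrees.
#' @export
extended_torsions <- function(topology) {
  n <- nrow(topology$residues)
  torsion_state(topology$residues$position_index, rep(180, n), rep(180, n))
}
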