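# Plain-text structure interchange: multi-MODEL PDB (strict v3.3 columns) and
# XYZ trajectories. Ring atoms are written as HETATM with residue name TZ4;
# cap atoms carry residue number 0. Residue numbering equals the position
# index (rings included), chain A.

.PDB_ATOM_NAMES <- c(
  N = "N", CA = "CA", C_O = "C", O = "O", OXT = "OXT", CB = "CB",
  H_N = "H", H_A = "HA", SC_centroid = "SCE",
  ring_N1 = "N1", ring_N2 = "N2", ring_N3 = "N3", ring_C4 = "C4",
  ring_C5 = "C5", ring_H5 = "H5",
  cap_C = "C", cap_O = "O", cap_CT = "CT", cap_H = "H", cap_CM = "CM"
)

# per-atom PDB fields of a topology
.pdb_fields <- function(topo) {
  at <- topo$atoms
  res <- topo$residues
  resname <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    p <- at$position[i]
    if (p == 0L) {
      resname[i] <- switch(topo$n_cap, Boc = "BOC", Bus = "BUS", "NH2")
    } else if (p %in% res$position_index) {
      resname[i] <- toupper(res$name[match(p, res$position_index)])
    } else {
      resname[i] <- "TZ4"
    }
  }
  nm <- unname(.PDB_ATOM_NAMES[at$role])
  # PDB column 13-16: names of <= 3 chars start in column 14
  nm4 <- ifelse(nchar(nm) >= 4, nm, paste0(" ", formatC(nm, width = -3)))
  list(name4 = nm4, resname = resname,
       record = ifelse(startsWith(at$role, "ring_"), "HETATM", "ATOM"),
       resseq = at$position, element = at$element)
}

.pdb_model_lines <- function(coords, fld) {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          fld$record, seq_len(nrow(coords)), fld$name4, "", fld$resname, "A",
          fld$resseq, "", coords[, 1], coords[, 2], coords[, 3], 1, 0,
          fld$element)
}

#' Write conformations or a trajectory as multi-MODEL PDB
#'
#' @param x A `conformation`, a list of conformations, or a [trajectory()]
#'   (all frames are written, regardless of the analysis window).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "conformation")) {
    topo <- x$topology
    frames <- list(x$coords)
  } else if (inherits(x, "trajectory")) {
    topo <- x$topology
    frames <- lapply(seq_len(n_frames(x)), function(i) x$coords[, , i])
  } else {
    topo <- x[[1]]$topology
    frames <- lapply(x, `[[`, "coords")
  }
  fld <- .pdb_fields(topo)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(.pdb_model_lines(frames[[i]], fld), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-MODEL PDB file
#'
#' @param path Input path.
#' @param topology Optional [foldamer_topology]; when given, atom counts are
#'   validated and a [trajectory()] is returned, else a list with raw
#'   coordinate frames and atom metadata.
#' @return A [trajectory()] or a list (`frames`, `atoms`).
#' @export
read_pdb <- function(path, topology = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_brk <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_brk) == 0L) model_brk <- rep(1L, length(lines))
  at <- which(is_atom)
  if (!length(at)) stop("value error: no ATOM/HETATM records in PDB")
  coords <- cbind(as.numeric(substr(lines[at], 31, 38)),
                  as.numeric(substr(lines[at], 39, 46)),
                  as.numeric(substr(lines[at], 47, 54)))
  meta <- data.frame(
    name = trimws(substr(lines[at], 13, 16)),
    resname = trimws(substr(lines[at], 18, 20)),
    resseq = as.integer(substr(lines[at], 23, 26)),
    element = trimws(substr(lines[at], 77, 78)),
    stringsAsFactors = FALSE)
  frames <- split(seq_along(at), model_brk[at])
  mats <- lapply(frames, function(ix) coords[ix, , drop = FALSE])
  n0 <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != n0))
    stop("value error: models differ in atom count")
  if (!is.null(topology)) {
    if (n0 != nrow(topology$atoms))
      stop("value error: PDB atom count does not match the topology")
    return(trajectory(topology, mats))
  }
  list(frames = mats, atoms = meta[seq_len(n0), ])
}

#' Write an XYZ trajectory
#'
#' Standard XYZ: atom count line, comment line carrying the frame index and
#' provenance, then `element x y z`.
#'
#' @param x A `conformation`, list of conformations, or [trajectory()].
#' @param path Output path.
#' @param comment Provenance tag written on every frame's comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "triazolamer") {
  if (inherits(x, "conformation")) {
    topo <- x$topology
    frames <- list(x$coords)
  } else if (inherits(x, "trajectory")) {
    topo <- x$topology
    frames <- lapply(seq_len(n_frames(x)), function(i) x$coords[, , i])
  } else {
    topo <- x[[1]]$topology
    frames <- lapply(x, `[[`, "coords")
  }
  el <- topo$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(as.character(nrow(frames[[i]])), con)
    writeLines(sprintf("frame %d %s", i, comment), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el,
                       frames[[i]][, 1], frames[[i]][, 2], frames[[i]][, 3]),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path Input path.
#' @param topology Optional [foldamer_topology] for validation; when given a
#'   [trajectory()] is returned.
#' @return A [trajectory()] or a list (`frames`, `elements`, `comments`).
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  comments <- character()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop(sprintf("value error: bad XYZ count line %d", i))
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!is.null(topology)) {
    if (length(elements) != nrow(topology$atoms))
      stop("value error: XYZ atom count does not match the topology")
    return(trajectory(topology, frames))
  }
  list(frames = frames, elements = elements, comments = comments)
}
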