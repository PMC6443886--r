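# Construction of the coarse-grained foldamer topology: atom list, bond graph,
# Z-matrix template for the internal-coordinate builder, torsion definitions
# and the backbone selection.
#
# Model resolution: backbone N, CA, C(=O), O (+ ester O and cap atoms), the
# five triazole ring atoms, polar/alpha protons (H_N, H_A, ring H5), and side
# chains coarse-grained to CB plus one centroid pseudo-atom. Each atom's
# internal coordinates are constants from [ideal_geometry()] except the
# designated phi/psi torsions; amide omega is fixed trans and the triazole is
# a rigid planar pentagon, so a conformation is fully determined by the
# 2-per-residue backbone torsions.

.BACKBONE_ROLES_DEFAULT <- c("N", "C_O", "CA", "ring_N1", "ring_N2", "ring_N3")

#' Build a foldamer topology from a residue table
#'
#' Normally called through [parse_sequence()]. Residues of kind `tz4n` own the
#' triazole ring that follows them; the ring occupies its own position index.
#'
#' @param residues Data frame with columns `name`, `code1`, `kind`
#'   (`amide`/`tz4n`/`tz4c`), `chirality` (`L`/`D`/`achiral`), `sc_dist`,
#'   `sc_mass`, `position_index`.
#' @param n_cap One of `"Boc"`, `"Bus"`, `"H"`, `"none"`.
#' @param c_cap One of `"OAll"`, `"OBzl"`, `"OH"`, `"none"`.
#' @param source Free-text provenance (the sequence string).
#' @param backbone_roles Atom roles forming the backbone selection used for
#'   RMSD and clustering. The default follows the convention that the triazole
#'   contributes its three nitrogens alongside N, C(=O) and CA; add
#'   `"ring_C4"`/`"ring_C5"` to use all five ring atoms.
#' @return A `foldamer_topology` object: residue table, atom table (id, label,
#'   element, role, position, mass, radius), bond list, Z-matrix template,
#'   torsion definitions and steric pair list.
#' @export
build_topology <- function(residues, n_cap = "none", c_cap = "none",
                           source = "", backbone_roles = .BACKBONE_ROLES_DEFAULT) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1L)
  if (residues$kind[1] == "tz4c" || residues$kind[nrow(residues)] == "tz4n")
    stop("structural error: dangling triazole linkage at a terminus")
  geo <- ideal_geometry()
  bd <- geo$bonds
  an <- geo$angles
  n_res <- nrow(residues)

  atoms <- list()   # each: label, element, role, position
  zm <- list()      # each: ref1..3 (1-based, 0 = none), bond, angle, toroff, link
  xbonds <- list()  # bonds beyond the ref1 parent bonds (ring closure)
  add <- function(role, element, position, r1, r2, r3, bond, angle, toroff,
                  link = 0L, mass = NA_real_) {
    i <- length(atoms) + 1L
    lab <- if (position == 0L) role else paste0(role, "_", position)
    atoms[[i]] <<- list(label = lab, element = element, role = role,
                        position = position, mass = mass)
    zm[[i]] <<- c(r1, r2, r3, bond, angle, toroff, link)
    i
  }

  phi_q <- matrix(0L, n_res, 4)
  psi_q <- matrix(0L, n_res, 4)
  omega_q <- list()

  # ---- N-cap and first-residue seed atoms -----------------------------------
  p1 <- residues$position_index[1]
  if (n_cap %in% c("Boc", "Bus")) {
    capC <- add("cap_C", "C", 0L, 0L, 0L, 0L, 0, 0, 0)
    capO <- add("cap_O", "O", 0L, capC, 0L, 0L, bd[["C_O"]], 0, 0)
    N_i <- add("N", "N", p1, capC, capO, 0L, bd[["C_N_amide"]], an[["O_C_N"]], 0)
    capT <- add("cap_CT", "C", 0L, capC, capO, N_i, 2.20, 115, 180,
                mass = 73.09)
    add("H_N", "H", p1, N_i, capC, capO, bd[["N_H"]], an[["C_N_H"]], 180)
    CA_i <- add("CA", "C", p1, N_i, capC, capO, bd[["N_CA"]], an[["C_N_CA"]], 180)
    anchor <- capC
    omega_q[[1]] <- c(capO, capC, N_i, CA_i)
  } else {
    capH <- add("cap_H", "H", 0L, 0L, 0L, 0L, 0, 0, 0)
    N_i <- add("N", "N", p1, capH, 0L, 0L, bd[["N_H"]], 0, 0)
    CA_i <- add("CA", "C", p1, N_i, capH, 0L, bd[["N_CA"]], an[["H_N_CA"]], 0)
    anchor <- capH
  }

  prevC <- prevCA <- prevN <- 0L  # trailing carbonyl frame
  ringC4 <- ringC5 <- ringN1 <- 0L
  pending_psi <- 0L               # residue whose psi waits for the next N

  for (i in seq_len(n_res)) {
    kind <- residues$kind[i]
    p <- residues$position_index[i]
    chir <- residues$chirality[i]
    phi_id <- 2L * i - 1L
    psi_id <- 2L * i

    if (i > 1L) {
      if (kind %in% c("amide", "tz4n")) {
        # amide bond to the previous residue's carbonyl; the dihedral placing
        # N is the previous residue's psi
        N_i <- add("N", "N", p, prevC, prevCA, prevN, bd[["C_N_amide"]],
                   an[["CA_C_N"]], 0, link = 2L * (i - 1L))
        add("H_N", "H", p, N_i, prevC, prevCA, bd[["N_H"]], an[["C_N_H"]], 0)
        CA_i <- add("CA", "C", p, N_i, prevC, prevCA, bd[["N_CA"]],
                    an[["C_N_CA"]], 180)
        anchor <- prevC
        omega_q[[length(omega_q) + 1L]] <- c(prevCA, prevC, N_i, CA_i)
        if (pending_psi > 0L) {
          psi_q[pending_psi, 4] <- N_i
          pending_psi <- 0L
        }
      } else {  # tz4c: CA attaches to ring N1 of the preceding triazole
        CA_i <- add("CA", "C", p, ringN1, ringC5, ringC4, bd[["N1_CA"]],
                    an[["C5_N1_CA"]], 180)
        N_i <- ringN1
        anchor <- ringC5
      }
    }
    Nlike <- N_i

    if (kind == "tz4n") {
      Clike <- add("ring_C4", "C", p + 1L, CA_i, Nlike, anchor, bd[["CA_C4"]],
                   an[["N_CA_C4"]], 0, link = phi_id)
    } else {
      ang_c <- if (kind == "tz4c") an[["N1_CA_C"]] else an[["N_CA_C"]]
      Clike <- add("C_O", "C", p, CA_i, Nlike, anchor, bd[["CA_C"]], ang_c, 0,
                   link = phi_id)
    }
    phi_q[i, ] <- c(anchor, Nlike, CA_i, Clike)

    chi <- .CHI[[chir]]
    ang_h <- if (kind == "tz4c") an[["N1_CA_H"]] else an[["N_CA_H"]]
    add("H_A", "H", p, CA_i, Nlike, Clike, bd[["CA_H"]], ang_h, chi[["H_A"]])
    if (chir != "achiral") {
      ang_b <- if (kind == "tz4c") an[["N1_CA_CB"]] else an[["N_CA_CB"]]
      CB <- add("CB", "C", p, CA_i, Nlike, Clike, bd[["CA_CB"]], ang_b,
                chi[["CB"]])
      if (!is.na(residues$sc_dist[i]) && residues$sc_dist[i] > 0)
        add("SC_centroid", "C", p, CB, CA_i, Nlike, residues$sc_dist[i],
            an[["CA_CB_SC"]], 180, mass = residues$sc_mass[i])
    }

    if (kind == "tz4n") {
      # rigid planar pentagon at position p + 1
      C4 <- Clike
      C5 <- add("ring_C5", "C", p + 1L, C4, CA_i, Nlike, bd[["ring"]],
                an[["CA_C4_C5"]], 0, link = psi_id)
      N1 <- add("ring_N1", "N", p + 1L, C5, C4, CA_i, bd[["ring"]],
                an[["ring"]], 180)
      N2 <- add("ring_N2", "N", p + 1L, N1, C5, C4, bd[["ring"]],
                an[["ring"]], 0)
      N3 <- add("ring_N3", "N", p + 1L, N2, N1, C5, bd[["ring"]],
                an[["ring"]], 0)
      add("ring_H5", "H", p + 1L, C5, C4, CA_i, bd[["C5_H5"]],
          an[["C4_C5_H5"]], 0)
      xbonds[[length(xbonds) + 1L]] <- c(N3, C4)
      psi_q[i, ] <- c(Nlike, CA_i, C4, C5)
      ringC4 <- C4; ringC5 <- C5; ringN1 <- N1
    } else {
      add("O", "O", p, Clike, CA_i, Nlike, bd[["C_O"]], an[["CA_C_O"]], 180,
          link = psi_id)
      psi_q[i, ] <- c(Nlike, CA_i, Clike, 0L)
      if (i == n_res) {
        OXT <- add("OXT", "O", p, Clike, CA_i, Nlike, bd[["C_OXT"]],
                   an[["CA_C_OXT"]], 0, link = psi_id)
        psi_q[i, 4] <- OXT
        if (c_cap %in% c("OAll", "OBzl"))
          add("cap_CM", "C", p, OXT, Clike, CA_i, bd[["OXT_CM"]],
              an[["C_OXT_CM"]], 180,
              mass = if (c_cap == "OAll") 41.07 else 91.13)
      } else {
        pending_psi <- i
      }
      prevC <- Clike; prevCA <- CA_i; prevN <- Nlike
    }
  }

  atom_df <- data.frame(
    atom_id = seq_along(atoms),
    label = vapply(atoms, `[[`, "", "label"),
    element = vapply(atoms, `[[`, "", "element"),
    role = vapply(atoms, `[[`, "", "role"),
    position = vapply(atoms, function(a) as.integer(a$position), 0L),
    mass = vapply(atoms, function(a) as.numeric(a$mass), 0.0),
    stringsAsFactors = FALSE
  )
  need_mass <- is.na(atom_df$mass)
  atom_df$mass[need_mass] <- .ELEMENT_MASS[atom_df$element[need_mass]]
  atom_df$radius <- unname(.ROLE_RADIUS[atom_df$role])

  zmat <- do.call(rbind, zm)
  colnames(zmat) <- c("ref1", "ref2", "ref3", "bond", "angle", "toroff", "link")

  bonds <- cbind(parent = zmat[, "ref1"], child = seq_len(nrow(zmat)))
  bonds <- bonds[bonds[, 1] > 0L, , drop = FALSE]
  if (length(xbonds))
    bonds <- rbind(bonds, do.call(rbind, xbonds))
  dimnames(bonds) <- list(NULL, c("a", "b"))

  residues$side_chain <- ifelse(residues$chirality == "achiral", "none",
                                ifelse(!is.na(residues$sc_dist) &
                                         residues$sc_dist > 0,
                                       "CB+centroid", "CB"))
  topo <- structure(list(
    residues = residues,
    n_triazoles = sum(residues$kind == "tz4n"),
    n_cap = n_cap, c_cap = c_cap,
    atoms = atom_df, bonds = bonds, zmatrix = zmat,
    phi_quads = phi_q, psi_quads = psi_q,
    omega_quads = if (length(omega_q)) do.call(rbind, omega_q) else
      matrix(0L, 0, 4),
    backbone_roles = backbone_roles,
    source = source
  ), class = "foldamer_topology")
  topo$steric_pairs <- .steric_pairs(topo)
  topo
}

# nonbonded pair list (> 3 bonds apart) with per-pair contact distance
.steric_pairs <- function(topo) {
  n <- nrow(topo$atoms)
  d <- .bond_graph_distances(topo$bonds, n)
  sel <- which(upper.tri(matrix(0, n, n)) & d > 3L, arr.ind = TRUE)
  rad <- topo$atoms$radius
  # arithmetic-mean combination: permissive contacts, but self-intersection
  # (r well under either radius) is still strongly repelled
  list(i = sel[, 1], j = sel[, 2],
       sigma = (rad[sel[, 1]] + rad[sel[, 2]]) / 2)
}

# all-pairs shortest path (in bonds) by BFS; small graphs only
.bond_graph_distances <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- dist[frontier[1]] + 1L
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d[is.na(d)] <- n + 1L
  d
}

#' Backbone atom selection of a topology
#'
#' @param topology A [foldamer_topology].
#' @param roles Atom roles to select; defaults to the topology's configured
#'   backbone roles (`N`, `C_O`, `CA` and the three triazole nitrogens).
#' @return Integer atom indices in atom order.
#' @export
backbone_selection <- function(topology, roles = topology$backbone_roles) {
  which(topology$atoms$role %in% roles)
}

#' Resolve an atom by position index and role
#'
#' @param topology A [foldamer_topology].
#' @param position Position index (residues and rings each count one).
#' @param role Atom role, e.g. `"H_A"`, `"H_N"`, `"ring_H5"`, `"SC_centroid"`.
#' @return Integer atom index.
#' @export
atom_index <- function(topology, position, role) {
  hit <- which(topology$atoms$position == position & topology$atoms$role == role)
  if (length(hit) != 1L)
    stop(sprintf("lookup error: no atom with role '%s' at position %d",
                 role, position))
  hit
}

#' @export
print.foldamer_topology <- function(x, ...) {
  cat(sprintf("foldamer_topology: %d residues, %d triazole rings, caps %s/%s\n",
              nrow(x$residues), x$n_triazoles, x$n_cap, x$c_cap))
  cat(sprintf("  %d atoms, %d bonds; backbone selection: %d atoms (%s)\n",
              nrow(x$atoms), nrow(x$bonds), length(backbone_selection(x)),
              paste(x$backbone_roles, collapse = ", ")))
  lab <- paste0(x$residues$code1,
                ifelse(x$residues$kind == "amide", "",
                       ifelse(x$residues$kind == "tz4n", "4n", "4c")),
                x$residues$position_index)
  cat("  positions:", paste(lab, collapse = " "), "\n")
  invisible(x)
}
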