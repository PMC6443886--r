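# Parser for peptidotriazolamer sequence notation, e.g.
# "Boc-Ala-ValPsi[4Tz]Phe-LeuPsi[4Tz]Phe-LeuPsi[4Tz]Val-OAll".
# A "Psi[4Tz]" token marks the replacement of the central amide of a dipeptide
# by a 1,4-disubstituted 1,2,3-triazole: the residue left of the token becomes
# a 4n residue (CA bonded to ring C4), the residue right of it a 4c residue
# (CA bonded to ring N1).

.TZ_SENTINEL <- "\u0001"
.D_SENTINEL <- "\u0002"

.N_CAPS <- c("Boc", "Bus", "(S)-Bus", "(R)-Bus", "H")
.C_CAPS <- c("OAll", "OBzl", "OH")

#' Parse a foldamer sequence string into a topology
#'
#' Accepted tokens: an optional N-cap (`Boc`, `Bus`, `(S)-Bus`, `(R)-Bus`,
#' `H`), residue codes (1- or 3-letter, optional `d-`/`D-` prefix for the
#' (R)-configured residue), the triazole linkage token (`Ψ[4Tz]`, ASCII
#' aliases `psi[4Tz]` and `~[4Tz]`), parenthesized repeats `(...)n`, and an
#' optional C-cap (`OAll`, `OBzl`, `OH`). Position indices count each triazole
#' ring as its own position, so `Boc-Ala-ValΨ[4Tz]Phe-...` numbers
#' Ala1, Val2 (4n), ring 3, Phe4 (4c), and so on.
#'
#' @param text Sequence string.
#' @return A [foldamer_topology] object.
#' @examples
#' topo <- parse_sequence("Boc-Ala-Val~[4Tz]Phe-Leu~[4Tz]Phe-Leu~[4Tz]Val-OAll")
#' topo$n_triazoles  # 3
#' @export
parse_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("parse error: sequence must be a single character string")
  s <- trimws(text)
  if (!nzchar(s)) stop("parse error: empty sequence string")

  # normalize the triazole linkage token
  for (alias in c("Ψ[4Tz]", "psi[4Tz]", "Psi[4Tz]", "PSI[4Tz]", "~[4Tz]"))
    s <- gsub(alias, .TZ_SENTINEL, s, fixed = TRUE)

  # N-cap
  n_cap <- "none"
  for (cap in .N_CAPS) {
    pre <- paste0(cap, "-")
    if (startsWith(s, pre)) {
      n_cap <- if (grepl("Bus", cap, fixed = TRUE)) "Bus" else cap
      s <- substring(s, nchar(pre) + 1L)
      break
    }
  }
  # C-cap
  c_cap <- "none"
  for (cap in .C_CAPS) {
    suf <- paste0("-", cap)
    if (endsWith(s, suf)) {
      c_cap <- cap
      s <- substring(s, 1L, nchar(s) - nchar(suf))
      break
    }
  }
  if (!nzchar(s)) stop("parse error: sequence contains no residues")

  # expand parenthesized repeats, innermost first
  repeat {
    m <- regexpr("\\(([^()]*)\\)([0-9]+)", s)
    if (m == -1L) break
    span <- regmatches(s, m)
    inner <- sub("\\(([^()]*)\\)([0-9]+)", "\\1", span)
    count <- as.integer(sub("\\(([^()]*)\\)([0-9]+)", "\\2", span))
    if (count < 1L)
      stop(sprintf("value error: repeat count %d < 1 in '%s'", count, span))
    if (!nzchar(inner))
      stop(sprintf("parse error: empty repeat group '%s'", span))
    regmatches(s, m) <- paste(rep(inner, count), collapse = "-")
  }
  if (grepl("[()]", s))
    stop(sprintf("parse error: unbalanced parentheses near '%s'", s))

  # a dash next to the linkage token is decorative; D-prefixes are protected
  # from the dash split
  s <- gsub(paste0("-?", .TZ_SENTINEL, "-?"), .TZ_SENTINEL, s)
  s <- gsub(paste0("(^|[-", .TZ_SENTINEL, "])[dD]-"),
            paste0("\\1", .D_SENTINEL), s)

  chunks <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(chunks)))
    stop(sprintf("parse error: empty token in '%s'", text))

  res <- list()
  for (chunk in chunks) {
    parts <- strsplit(chunk, .TZ_SENTINEL, fixed = TRUE)[[1]]
    n_tz <- lengths(regmatches(chunk, gregexpr(.TZ_SENTINEL, chunk)))
    if (n_tz >= 1L && (length(parts) != n_tz + 1L || any(!nzchar(parts))))
      stop(sprintf(
        "structural error: dangling triazole linkage in '%s'",
        gsub(.TZ_SENTINEL, "Ψ[4Tz]", chunk)))
    if (length(parts) > 2L)
      stop(sprintf(
        "structural error: residue '%s' cannot carry two triazole linkages",
        parts[2]))
    kinds <- if (length(parts) == 2L) c("tz4n", "tz4c") else "amide"
    for (k in seq_along(parts))
      res[[length(res) + 1L]] <- .parse_residue(parts[k], kinds[k])
  }
  if (length(res) == 0L) stop("parse error: sequence contains no residues")
  residues <- do.call(rbind, res)

  # a 4c residue must directly follow its ring's 4n residue
  kinds <- residues$kind
  tz4c_at <- which(kinds == "tz4c")
  if (length(tz4c_at) && (any(tz4c_at == 1L) ||
      any(kinds[tz4c_at - 1L] != "tz4n")))
    stop("structural error: dangling Ψ[4Tz] linkage at a terminus")
  if (length(kinds) > 1L && kinds[length(kinds)] == "tz4n")
    stop("structural error: dangling Ψ[4Tz] linkage at the C-terminus")

  # position indices, counting each ring as one position
  pos <- integer(nrow(residues))
  p <- 1L
  for (i in seq_len(nrow(residues))) {
    pos[i] <- p
    p <- p + 1L
    if (residues$kind[i] == "tz4n") p <- p + 1L  # ring takes the next slot
  }
  residues$position_index <- pos

  build_topology(residues, n_cap = n_cap, c_cap = c_cap, source = text)
}

.parse_residue <- function(tok, kind) {
  chir <- "L"
  body <- tok
  if (startsWith(tok, .D_SENTINEL)) {
    chir <- "D"
    body <- substring(tok, 2L)
  }
  hit <- match(body, .RESIDUES$code3)
  if (is.na(hit)) hit <- match(body, .RESIDUES$code1)
  if (is.na(hit))
    stop(sprintf("parse error: unknown residue token '%s'",
                 sub(.D_SENTINEL, "d-", tok, fixed = TRUE)))
  r <- .RESIDUES[hit, ]
  if (r$code3 == "Gly") chir <- "achiral"
  data.frame(name = r$code3, code1 = r$code1, kind = kind, chirality = chir,
             sc_dist = r$sc_dist, sc_mass = r$sc_mass, position_index = NA_integer_,
             stringsAsFactors = FALSE)
}
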