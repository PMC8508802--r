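# Harmonic Oscillator Model of Aromaticity (HOMA).
#
# HOMA = 1 - (alpha / n) * sum_i (d_opt - d_i)^2 over the n C-C bonds of a
# ring, with the standard C-C parameterisation alpha = 257.7 and
# d_opt = 1.388 Angstrom: 1 for a fully bond-equalised aromatic ring, 0 for
# a hypothetical Kekule-localised ring, negative for strongly localised
# (antiaromatic) rings such as the quinoid ring of 1,4-naphthoquinones.

#' HOMA aromaticity index from bond lengths
#'
#' @param lengths Numeric vector of C-C bond lengths in Angstrom (>= 3).
#' @param alpha Empirical normalisation constant; default 257.7, the
#'   standard C-C value.
#' @param d_opt Optimal (fully delocalised) C-C bond length in Angstrom;
#'   default 1.388.
#' @return The HOMA score (dimensionless, <= 1; negative values indicate
#'   strong bond-length alternation).
#' @examples
#' homa(rep(1.388, 6))          # ideal aromatic ring -> 1
#' homa(rep(c(1.35, 1.45), 3))  # alternating ring -> well below 1
#' @export
homa <- function(lengths, alpha = 257.7, d_opt = 1.388) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 3) abort("HOMA needs at least 3 bond lengths")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("bond lengths must be positive and finite")
  }
  if (alpha <= 0 || d_opt <= 0) abort("`alpha` and `d_opt` must be positive")
  1 - (alpha / length(lengths)) * sum((d_opt - lengths)^2)
}

#' HOMA per compound from a long bond-length table
#'
#' @param bonds Data frame with columns `compound` and `length` (Angstrom),
#'   e.g. from [read_bond_table()]. Rows with missing lengths are dropped.
#' @param alpha,d_opt As in [homa()].
#' @return Tibble with one row per compound: `compound`, `n_bonds`, `homa`.
#' @export
homa_table <- function(bonds, alpha = 257.7, d_opt = 1.388) {
  stopifnot(all(c("compound", "length") %in% names(bonds)))
  bonds <- dplyr::filter(bonds, !is.na(.data$length))
  dplyr::summarise(
    dplyr::group_by(as_tibble(bonds), .data$compound),
    n_bonds = dplyr::n(),
    homa = homa(.data$length, alpha = alpha, d_opt = d_opt),
    .groups = "drop"
  )
}

#' HOMA of a ring measured on a Cartesian geometry
#'
#' Measures the consecutive (cyclic) bond lengths of the ring in the given
#' frame and evaluates [homa()]. All ring atoms must be carbon: the shipped
#' parameterisation is for C-C bonds only, and heteroatom rings (e.g. the
#' O-H...O quasi-rings closed by the hydrogen bridges) are rejected rather
#' than silently approximated.
#'
#' @param geom A single frame (data frame with `atom`, `element`, `x`, `y`,
#'   `z`).
#' @param ring A [ring_def()].
#' @param alpha,d_opt As in [homa()].
#' @return The HOMA score.
#' @export
homa_ring <- function(geom, ring, alpha = 257.7, d_opt = 1.388) {
  stopifnot(inherits(ring, "qb_ring"))
  elems <- vapply(ring$atoms, function(i) {
    row <- dplyr::filter(geom, .data$atom == i)
    if (nrow(row) == 0) abort(paste0("ring atom ", i, " out of range"))
    row$element[1]
  }, "")
  if (any(elems != "C")) {
    bad <- ring$atoms[elems != "C"][1]
    abort(paste0("ring atom ", bad, " is ", elems[elems != "C"][1],
                 ", not carbon; HOMA is parameterised for C-C bonds only"))
  }
  lengths <- apply(ring$bonds, 1, function(b) bond_length(geom, b[1], b[2]))
  homa(lengths, alpha = alpha, d_opt = d_opt)
}

#' Read a per-compound bond-length table
#'
#' Expects delimited text (tab or comma) whose first column holds bond
#' labels (e.g. `C5-C6`) and whose remaining columns hold bond lengths in
#' Angstrom, one column per compound. A dash (`-` or en dash) marks a bond
#' absent in that compound; such entries are dropped.
#'
#' @param path Path to the table.
#' @return Long tibble with columns `bond`, `compound`, `length`.
#' @export
read_bond_table <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) abort("empty bond table")
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()))
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort("bond table needs a bond-label column and at least one compound")
  }
  names(raw)[1] <- "bond"
  long <- tidyr::pivot_longer(raw, -"bond", names_to = "compound",
                              values_to = "raw")
  dash <- c("-", "–", "—", "")
  long$raw <- trimws(long$raw)
  long <- dplyr::filter(long, !is.na(.data$raw), !(.data$raw %in% dash))
  val <- suppressWarnings(as.numeric(long$raw))
  if (any(is.na(val))) {
    bad <- which(is.na(val))[1]
    abort(sprintf("non-numeric bond length '%s' (bond %s, compound %s)",
                  long$raw[bad], long$bond[bad], long$compound[bad]))
  }
  tibble(bond = long$bond, compound = long$compound, length = val)
}

#' Bond labels of the two fused rings of the 1,4-naphthoquinone skeleton
#'
#' Convenience selector for bond tables that follow the usual
#' crystallographic labelling: ring I is the quinoid (carbonyl-bearing)
#' ring, ring II the benzenoid ring.
#'
#' @param ring `"I"` or `"II"`.
#' @return Character vector of six bond labels.
#' @examples
#' tab <- read_bond_table(system.file("extdata", "parent_bond_lengths.tsv",
#'                                    package = "quinbridge"))
#' ringII <- dplyr::filter(tab, bond %in% naphthoquinone_ring_bonds("II"))
#' homa_table(ringII)
#' @export
naphthoquinone_ring_bonds <- function(ring = c("I", "II")) {
  ring <- match.arg(ring)
  if (ring == "I") {
    c("C1-C2", "C2-C3", "C3-C4", "C4-C10", "C9-C10", "C1-C9")
  } else {
    c("C10-C5", "C5-C6", "C6-C7", "C7-C8", "C8-C9", "C9-C10")
  }
}
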