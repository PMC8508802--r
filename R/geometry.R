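# Ring / bridge definitions (1-based atom indices, matching the usual
# crystallographic numbering of the naphthoquinone skeleton) and
# interatomic metrics.

#' Define a ring by its ordered atom indices
#'
#' @param atoms Ordered 1-based atom indices closing the cycle (>= 3,
#'   no repeats). Consecutive pairs, wrapping around, are the ring bonds.
#' @param label Optional ring label, e.g. `"I"` (quinoid) or `"II"`
#'   (aromatic).
#' @return A list of class `qb_ring` with elements `label`, `atoms` and the
#'   derived `bonds` (two-column matrix of index pairs).
#' @export
ring_def <- function(atoms, label = "ring") {
  atoms <- as.integer(atoms)
  if (length(atoms) < 3) abort("a ring needs at least 3 atoms")
  if (anyDuplicated(atoms)) abort("ring atom indices must be distinct")
  if (any(atoms < 1)) abort("ring atom indices are 1-based")
  bonds <- cbind(atoms, c(atoms[-1], atoms[1]))
  structure(list(label = label, atoms = atoms, bonds = bonds),
            class = "qb_ring")
}

#' Define a donor-H-acceptor hydrogen bridge
#'
#' @param donor,proton,acceptor 1-based atom indices of the donor oxygen,
#'   the bridging hydrogen and the acceptor oxygen.
#' @param label Bridge label, e.g. `"O1-H1-O3"`.
#' @return A list of class `qb_bridge`.
#' @export
bridge_spec <- function(donor, proton, acceptor, label = NULL) {
  idx <- c(donor = donor, proton = proton, acceptor = acceptor)
  if (anyDuplicated(idx)) abort("donor, proton and acceptor must be distinct")
  if (any(idx < 1)) abort("bridge atom indices are 1-based")
  label <- label %||% sprintf("O%d-H%d-O%d", donor, proton, acceptor)
  structure(list(donor = as.integer(donor), proton = as.integer(proton),
                 acceptor = as.integer(acceptor), label = label),
            class = "qb_bridge")
}

# coordinates of one atom in one frame (or a single-frame trajectory)
.atom_xyz <- function(geom, i) {
  row <- dplyr::filter(geom, .data$atom == i)
  if (nrow(row) == 0) abort(paste0("atom index ", i, " out of range"))
  c(row$x[1], row$y[1], row$z[1])
}

#' Euclidean distance between two atoms of a single geometry
#'
#' @param geom A single frame: any data frame with columns `atom`, `x`,
#'   `y`, `z` (e.g. one frame of a [trajectory()]).
#' @param i,j Distinct 1-based atom indices.
#' @return Distance in Angstrom.
#' @examples
#' g <- tibble::tibble(atom = 1:2, element = "C",
#'                     x = c(0, 1.388), y = 0, z = 0)
#' bond_length(g, 1, 2)
#' @export
bond_length <- function(geom, i, j) {
  if (i == j) abort("`i` and `j` must differ")
  sqrt(sum((.atom_xyz(geom, i) - .atom_xyz(geom, j))^2))
}

#' Geometric parameters of a hydrogen bridge in one frame
#'
#' Reports the donor-acceptor distance, the donor-proton and
#' proton-acceptor distances, and the O-H...O angle at the proton vertex.
#'
#' @param geom A single frame (data frame with `atom`, `element`, `x`, `y`,
#'   `z`).
#' @param bridge A [bridge_spec()].
#' @return One-row tibble: `bridge`, `d_oo`, `d_oh`, `d_ho` (Angstrom) and
#'   `angle_oho` (degrees).
#' @export
bridge_metrics <- function(geom, bridge) {
  stopifnot(inherits(bridge, "qb_bridge"))
  d <- .atom_xyz(geom, bridge$donor)
  h <- .atom_xyz(geom, bridge$proton)
  a <- .atom_xyz(geom, bridge$acceptor)
  d_oh <- sqrt(sum((d - h)^2))
  d_ho <- sqrt(sum((h - a)^2))
  d_oo <- sqrt(sum((d - a)^2))
  if (d_oh == 0 || d_ho == 0 || d_oo == 0) {
    abort("coincident atoms in bridge")
  }
  cosang <- sum((d - h) * (a - h)) / (d_oh * d_ho)
  cosang <- min(1, max(-1, cosang))
  tibble(bridge = bridge$label, d_oo = d_oo, d_oh = d_oh, d_ho = d_ho,
         angle_oho = acos(cosang) * 180 / pi)
}

#' Read a structure configuration file
#'
#' A YAML file describing a compound: a `compound` label, a `rings` block
#' (label to ordered 1-based index list) and a `bridges` block (label to
#' `donor` / `proton` / `acceptor` indices).
#'
#' @param path Path to the YAML file.
#' @return A list with `compound` (character), `rings` (named list of
#'   [ring_def()]) and `bridges` (named list of [bridge_spec()]).
#' @export
read_structure_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rings <- purrr::imap(cfg$rings %||% list(),
                       function(atoms, lab) ring_def(unlist(atoms), lab))
  bridges <- purrr::imap(cfg$bridges %||% list(), function(b, lab) {
    bridge_spec(b$donor, b$proton, b$acceptor, label = lab)
  })
  list(compound = cfg$compound %||% NA_character_,
       rings = rings, bridges = bridges)
}
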