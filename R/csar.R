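# Charge of the Substituent Active Region (cSAR): for a substituent X
# attached at an ipso carbon, cSAR(X) = q(X) + q(C_ipso), the sum of the
# partial charges of the substituent's atoms plus the ipso carbon. The
# descriptor is partial-charge-scheme agnostic; the tables consumed here
# typically carry Hirshfeld charges.

#' Define a substituent group for cSAR
#'
#' @param ipso 1-based index of the ipso carbon bearing the substituent.
#' @param atoms Non-empty vector of 1-based indices of the substituent's
#'   atoms (a single Br or H, or e.g. the O and H of a hydroxyl).
#' @param position Ring-position label (1-8 on the naphthoquinone skeleton).
#' @return A list of class `qb_subst_group`.
#' @export
substituent_group <- function(ipso, atoms, position) {
  atoms <- as.integer(atoms)
  if (length(atoms) == 0) abort("a substituent group needs at least one atom")
  if (ipso %in% atoms) abort("the ipso carbon cannot be a substituent atom")
  if (anyDuplicated(atoms)) abort("substituent atom indices must be distinct")
  structure(list(ipso = as.integer(ipso), atoms = atoms,
                 position = as.character(position)),
            class = "qb_subst_group")
}

.charge_lookup <- function(charges, idx) {
  pos <- match(idx, charges$atom)
  if (anyNA(pos)) {
    abort(paste0("atom index ", idx[which(is.na(pos))[1]],
                 " missing from charge table"))
  }
  charges$charge[pos]
}

#' cSAR of one substituent group
#'
#' @param charges Data frame with columns `atom` (1-based index, unique),
#'   `element` and `charge` (e), e.g. from [read_charge_table()].
#' @param group A [substituent_group()].
#' @return cSAR in elementary charge units: `q(X) + q(C_ipso)`.
#' @examples
#' ct <- tibble::tibble(atom = 1:3, element = c("C", "Br", "H"),
#'                      charge = c(0.05, -0.08, 0))
#' csar(ct, substituent_group(ipso = 1, atoms = 2, position = "2"))
#' @export
csar <- function(charges, group) {
  stopifnot(inherits(group, "qb_subst_group"))
  if (anyDuplicated(charges$atom)) abort("duplicate atom index in charge table")
  sum(.charge_lookup(charges, group$atoms)) +
    .charge_lookup(charges, group$ipso)
}

#' cSAR across ring positions
#'
#' Evaluates [csar()] for each group and returns one row per ring position,
#' ordered by position label. Unsubstituted positions are conventionally
#' passed as one-atom hydrogen groups so the profile covers all positions.
#'
#' @param charges As in [csar()].
#' @param groups List of [substituent_group()] with distinct positions.
#' @return Tibble with columns `position` and `csar`. The total molecular
#'   charge is attached as attribute `total_charge` (diagnostic sum rule).
#' @export
csar_profile <- function(charges, groups) {
  if (length(groups) == 0) {
    return(tibble(position = character(0), csar = numeric(0)))
  }
  pos <- vapply(groups, function(g) g$position, "")
  if (anyDuplicated(pos)) abort("duplicate position labels in `groups`")
  out <- tibble(
    position = pos,
    csar = vapply(groups, function(g) csar(charges, g), numeric(1))
  )
  out <- dplyr::arrange(out, .data$position)
  attr(out, "total_charge") <- sum(charges$charge)
  out
}

#' Read a per-atom partial-charge table
#'
#' Delimited text (tab or comma) with three columns: 1-based atom index,
#' element symbol, partial charge in e. A header row is detected and
#' skipped automatically.
#'
#' @param path Path to the table.
#' @return Tibble with columns `atom`, `element`, `charge`.
#' @export
read_charge_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty charge table")
  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else "\\s+"
  rows <- strsplit(lines, delim)
  first <- suppressWarnings(as.integer(rows[[1]][1]))
  if (is.na(first)) rows <- rows[-1]  # header
  if (length(rows) == 0) abort("charge table has no data rows")
  parse_row <- function(i) {
    v <- trimws(rows[[i]])
    if (length(v) < 3) {
      abort(sprintf("row %d: expected 3 columns (index, element, charge)", i))
    }
    idx <- suppressWarnings(as.integer(v[1]))
    q <- suppressWarnings(as.numeric(v[3]))
    if (is.na(idx)) abort(sprintf("row %d: non-integer atom index '%s'", i, v[1]))
    if (is.na(q)) abort(sprintf("row %d: non-numeric charge '%s'", i, v[3]))
    tibble(atom = idx, element = v[2], charge = q)
  }
  out <- dplyr::bind_rows(lapply(seq_along(rows), parse_row))
  if (anyDuplicated(out$atom)) {
    abort(paste0("duplicate atom index ",
                 out$atom[duplicated(out$atom)][1], " in charge table"))
  }
  if (any(!is.finite(out$charge))) abort("charges must be finite")
  out
}

#' Write a charge table
#'
#' @param charges Tibble as returned by [read_charge_table()].
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(charges, path) {
  readr::write_tsv(charges[c("atom", "element", "charge")], path)
  invisible(path)
}
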