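# One-dimensional proton-transfer energetics from relaxed-scan profiles:
# E(r) sampled on a fixed O-H increment (typically 0.05 Angstrom). The two
# quantities of interest are the barrier height and the energy of the
# second minimum (the proton-transferred tautomer), both relative to the
# global minimum. Grid extrema are reported as-is by default; scans
# underestimate the true barrier, converging to it from below as the grid
# is refined.

#' Construct a proton-transfer scan profile
#'
#' @param r Strictly increasing O-H distances in Angstrom (>= 5 points).
#' @param energy Energies in kcal/mol (any additive reference).
#' @param compound,bridge Optional labels.
#' @return Tibble of class `qb_pt_profile` with columns `r`, `energy`.
#' @export
pt_profile <- function(r, energy, compound = NA_character_,
                       bridge = NA_character_) {
  if (length(r) != length(energy)) abort("`r` and `energy` lengths differ")
  if (length(r) < 5) abort("a scan profile needs at least 5 points")
  if (any(diff(r) <= 0)) abort("`r` must be strictly increasing")
  if (any(!is.finite(r)) || any(!is.finite(energy))) {
    abort("profile values must be finite")
  }
  out <- tibble(r = as.numeric(r), energy = as.numeric(energy))
  attr(out, "compound") <- compound
  attr(out, "bridge") <- bridge
  class(out) <- c("qb_pt_profile", class(out))
  out
}

#' Read a two-column proton-transfer scan profile
#'
#' @param path Delimited text file: O-H distance (Angstrom), energy.
#' @param units Energy units in the file: `"kcal"` (kcal/mol, default) or
#'   `"hartree"` (converted with 1 hartree = 627.5095 kcal/mol).
#' @param compound,bridge Optional labels.
#' @return A [pt_profile()], energies re-referenced so the minimum is 0.
#' @export
read_pt_profile <- function(path, units = c("kcal", "hartree"),
                            compound = NA_character_,
                            bridge = NA_character_) {
  units <- match.arg(units)
  tab <- readr::read_table(path, col_names = c("r", "energy"),
                           col_types = "dd", comment = "#")
  if (anyNA(tab$r) || anyNA(tab$energy)) abort("non-numeric profile entry")
  if (anyDuplicated(tab$r)) abort("duplicated r value in profile")
  tab <- dplyr::arrange(tab, .data$r)
  e <- tab$energy
  if (units == "hartree") e <- e * .hartree_kcal
  pt_profile(tab$r, e - min(e), compound = compound, bridge = bridge)
}

# run-compressed stationary points; plateaus collapse to their leftmost
# grid index
.local_minima_idx <- function(e) {
  runs <- rle(e)
  k <- length(runs$values)
  starts <- cumsum(c(1, runs$lengths[-k]))
  is_min <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1 || runs$values[i - 1] > runs$values[i]
    right_ok <- i == k || runs$values[i + 1] > runs$values[i]
    left_ok && right_ok
  }, TRUE)
  starts[is_min]
}

#' Locate minima, barrier and second-minimum energy of a scan profile
#'
#' Minima are grid points lower than both neighbours (endpoints qualify
#' against their single neighbour; plateaus count once, at their leftmost
#' point). Energies are re-referenced so the global minimum is zero. When
#' at least two minima exist, the two lowest define the wells; the barrier
#' is the maximum sampled energy strictly between them.
#'
#' @param profile A [pt_profile()] (or data frame with `r`, `energy`).
#' @param refine If `TRUE`, refine interior stationary points by a
#'   three-point parabolic fit through each grid extremum and its
#'   neighbours. Default `FALSE`: raw scan-grid energetics are reported.
#' @return Object of class `qb_pt_analysis`; see [glance.qb_pt_analysis()].
#' @export
analyze_profile <- function(profile, refine = FALSE) {
  if (!all(c("r", "energy") %in% names(profile))) {
    abort("profile needs columns `r` and `energy`")
  }
  r <- profile$r
  if (any(diff(r) <= 0)) abort("`r` must be strictly increasing")
  e <- profile$energy - min(profile$energy)
  min_idx <- .local_minima_idx(e)
  minima <- tibble(r = r[min_idx], energy = e[min_idx])
  has2 <- length(min_idx) >= 2
  res <- list(
    profile = pt_profile(r, e,
                         compound = attr(profile, "compound") %||% NA_character_,
                         bridge = attr(profile, "bridge") %||% NA_character_),
    minima = minima,
    has_second_minimum = has2,
    refined = refine,
    r_min1 = NA_real_, r_barrier = NA_real_, r_min2 = NA_real_,
    e_barrier = NA_real_, e_min2 = NA_real_
  )
  if (has2) {
    two <- min_idx[order(e[min_idx])][1:2]
    lo <- min(two)
    hi <- max(two)
    between <- (lo + 1):(hi - 1)
    b_rel <- which.max(e[between])  # leftmost grid index on plateaus
    b_idx <- between[b_rel]
    r_min1 <- r[lo]; e_min1 <- e[lo]
    r_min2 <- r[hi]; e_min2 <- e[hi]
    r_b <- r[b_idx]; e_b <- e[b_idx]
    if (refine) {
      ref <- function(i) {
        if (i <= 1 || i >= length(r)) return(c(r[i], e[i]))
        y <- e[(i - 1):(i + 1)]
        x <- r[(i - 1):(i + 1)]
        denom <- (y[1] - 2 * y[2] + y[3])
        if (denom == 0) return(c(x[2], y[2]))
        dx <- 0.5 * (y[1] - y[3]) / denom * (x[3] - x[2])
        c(x[2] + dx, y[2] - 0.25 * (y[1] - y[3]) * dx / (x[3] - x[2]))
      }
      m1 <- ref(lo); m2 <- ref(hi); bb <- ref(b_idx)
      r_min1 <- m1[1]; e_min1 <- m1[2]
      r_min2 <- m2[1]; e_min2 <- m2[2]
      r_b <- bb[1]; e_b <- bb[2]
      shift <- min(e_min1, e_min2)
      e_min1 <- e_min1 - shift; e_min2 <- e_min2 - shift; e_b <- e_b - shift
    }
    res$r_min1 <- r_min1
    res$r_barrier <- r_b
    res$r_min2 <- r_min2
    res$e_barrier <- e_b
    res$e_min2 <- max(e_min1, e_min2)
  }
  class(res) <- "qb_pt_analysis"
  res
}

#' @export
print.qb_pt_analysis <- function(x, ...) {
  cat("<qb_pt_analysis>\n")
  if (x$has_second_minimum) {
    cat(sprintf(
      "  wells at r = %.3f / %.3f A, barrier %.3f kcal/mol at r = %.3f A,\n",
      x$r_min1, x$r_min2, x$e_barrier, x$r_barrier))
    cat(sprintf("  second minimum %.3f kcal/mol above the global minimum\n",
                x$e_min2))
  } else {
    cat("  single-well profile (no second minimum)\n")
  }
  invisible(x)
}

#' Tidy a proton-transfer profile analysis
#'
#' @param x A `qb_pt_analysis` from [analyze_profile()].
#' @param ... Unused.
#' @return `tidy()`: one row per stationary point (`type`, `r`, `energy`);
#'   `glance()`: a one-row tibble with `r_min1`, `r_barrier`, `r_min2`,
#'   `e_barrier`, `e_min2` (kcal/mol above the global minimum),
#'   `has_second_minimum` and `n_minima`.
#' @export
tidy.qb_pt_analysis <- function(x, ...) {
  pts <- tibble(type = rep("minimum", nrow(x$minima)),
                r = x$minima$r, energy = x$minima$energy)
  if (x$has_second_minimum) {
    pts <- dplyr::bind_rows(
      pts, tibble(type = "barrier", r = x$r_barrier, energy = x$e_barrier))
  }
  dplyr::arrange(pts, .data$r)
}

#' @rdname tidy.qb_pt_analysis
#' @export
glance.qb_pt_analysis <- function(x, ...) {
  tibble(
    compound = attr(x$profile, "compound"),
    bridge = attr(x$profile, "bridge"),
    r_min1 = x$r_min1, r_barrier = x$r_barrier, r_min2 = x$r_min2,
    e_barrier = x$e_barrier, e_min2 = x$e_min2,
    has_second_minimum = x$has_second_minimum,
    n_minima = nrow(x$minima)
  )
}

#' Tabulate and pair barrier energetics across compounds
#'
#' Collates per-compound barrier and second-minimum energies and, for
#' compound labels that differ only in their leading group digit (e.g.
#' `2b` vs `3b`), reports the pairwise differences — the natural comparison
#' between the single-bridge and twin-bridge series.
#'
#' @param analyses Named list of `qb_pt_analysis` objects (names are
#'   compound labels), or a data frame like `glance()` output with a
#'   `compound` column.
#' @return List of class `qb_profile_comparison`: `per_compound` (tibble of
#'   `compound`, `e_barrier`, `e_min2`) and `pairs` (tibble of matched
#'   labels and their `d_barrier`, `d_min2` differences, first minus
#'   second).
#' @export
compare_profiles <- function(analyses) {
  if (is.data.frame(analyses)) {
    tab <- as_tibble(analyses)[c("compound", "e_barrier", "e_min2")]
  } else {
    if (length(analyses) < 2) {
      warn("fewer than 2 analyses; no pairs to compare")
    }
    tab <- dplyr::bind_rows(purrr::imap(analyses, function(a, nm) {
      g <- glance(a)
      g$compound <- nm
      g[c("compound", "e_barrier", "e_min2")]
    }))
  }
  m <- regmatches(tab$compound,
                  regexec("^([0-9]+)([a-z])(\\(M\\))?$", tab$compound))
  tab$.suffix <- vapply(m, function(v) {
    if (length(v) == 0) NA_character_ else paste0(v[3], v[4])
  }, "")
  suff <- unique(tab$.suffix[!is.na(tab$.suffix)])
  pairs <- purrr::map_dfr(suff, function(s) {
    sub <- tab[!is.na(tab$.suffix) & tab$.suffix == s, ]
    if (nrow(sub) < 2) return(NULL)
    cmb <- utils::combn(seq_len(nrow(sub)), 2)
    purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]; j <- cmb[2, k]
      tibble(compound_a = sub$compound[i], compound_b = sub$compound[j],
             d_barrier = sub$e_barrier[i] - sub$e_barrier[j],
             d_min2 = sub$e_min2[i] - sub$e_min2[j])
    })
  })
  structure(list(per_compound = tab[c("compound", "e_barrier", "e_min2")],
                 pairs = pairs),
            class = "qb_profile_comparison")
}

#' @export
print.qb_profile_comparison <- function(x, ...) {
  cat("<qb_profile_comparison>\nPer compound:\n")
  print(x$per_compound)
  cat("Matched pairs:\n")
  print(x$pairs)
  invisible(x)
}
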