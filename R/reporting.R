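# Series-level reporting: per-compound descriptor records and the
# rank-correlation summary linking aromaticity to proton-transfer
# energetics and O-H stretching wavenumbers. Rank (Spearman) correlation is
# the headline statistic because the claims of interest are monotone-
# association claims, not linearity claims.

.label_grammar <- "^[0-9][a-z](\\(M\\))?$"

#' Validate a compound label
#'
#' Labels follow the group-digit + letter + optional mirror marker grammar,
#' e.g. `"3b"` or `"2c(M)"`. Mirror compounds are distinct records.
#'
#' @param label Character vector of labels.
#' @return Logical vector.
#' @export
is_compound_label <- function(label) grepl(.label_grammar, label)

.report_vars <- c("homa_quinoid", "e_barrier", "e_min2", "nu_oh")

#' Build a descriptor series report with rank correlations
#'
#' @param records Data frame with a `compound` column and any of
#'   `homa_quinoid`, `homa_aromatic`, `e_barrier`, `e_min2`, `nu_oh`.
#'   Missing fields are excluded pairwise.
#' @return Object of class `qb_series_report`: `records` and
#'   `correlations`, a tibble of pairwise Spearman rank correlations
#'   (average-rank tie handling) among `homa_quinoid`, `e_barrier`,
#'   `e_min2`, `nu_oh` with the number of complete pairs `n`. A
#'   correlation is `NA` when fewer than 3 complete pairs exist or a
#'   variable is constant over them.
#' @export
build_series_report <- function(records) {
  records <- as_tibble(records)
  if (!("compound" %in% names(records))) {
    abort("`records` needs a `compound` column")
  }
  if (nrow(records) < 3) abort("need at least 3 records")
  vars <- intersect(.report_vars, names(records))
  cmb <- utils::combn(vars, 2)
  correlations <- purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
    v1 <- records[[cmb[1, k]]]
    v2 <- records[[cmb[2, k]]]
    ok <- !is.na(v1) & !is.na(v2)
    rho <- if (sum(ok) < 3 || sd(v1[ok]) == 0 || sd(v2[ok]) == 0) {
      NA_real_
    } else {
      cor(v1[ok], v2[ok], method = "spearman")
    }
    tibble(var1 = cmb[1, k], var2 = cmb[2, k], rho = rho, n = sum(ok))
  })
  structure(list(records = records, correlations = correlations),
            class = "qb_series_report")
}

#' @export
print.qb_series_report <- function(x, ...) {
  cat(sprintf("<qb_series_report> %d compound(s)\n", nrow(x$records)))
  print(x$correlations)
  invisible(x)
}

#' Tidy a series report
#'
#' @param x A `qb_series_report`.
#' @param ... Unused.
#' @return `tidy()`: the pairwise correlation table; `glance()`: one row
#'   with `n_records` and the correlations of each descriptor with the
#'   barrier height.
#' @export
tidy.qb_series_report <- function(x, ...) x$correlations

#' @rdname tidy.qb_series_report
#' @export
glance.qb_series_report <- function(x, ...) {
  get_rho <- function(a, b) {
    hit <- (x$correlations$var1 == a & x$correlations$var2 == b) |
           (x$correlations$var1 == b & x$correlations$var2 == a)
    if (any(hit)) x$correlations$rho[hit][1] else NA_real_
  }
  tibble(
    n_records = nrow(x$records),
    rho_homa_barrier = get_rho("homa_quinoid", "e_barrier"),
    rho_min2_barrier = get_rho("e_min2", "e_barrier"),
    rho_nuoh_barrier = get_rho("nu_oh", "e_barrier")
  )
}

#' Load a compound series from a directory of per-compound files
#'
#' Recognised files, all optional per compound (missing files leave the
#' corresponding fields `NA`):
#' * `<label>_bonds.tsv` — bond table ([read_bond_table()]) whose columns
#'   are ring labels `I` (quinoid) and/or `II` (aromatic); filled into
#'   `homa_quinoid` / `homa_aromatic`.
#' * `<label>_profile.tsv` — proton-transfer scan ([read_pt_profile()],
#'   kcal/mol); filled into `e_barrier` / `e_min2`.
#' * `<label>_nuoh.tsv` — a single O-H stretching wavenumber in cm^-1.
#'
#' File names whose `<label>` does not match the compound-label grammar
#' are skipped with a warning.
#'
#' @param dir Directory of per-compound files.
#' @return Tibble with one row per compound and columns `compound`,
#'   `homa_quinoid`, `homa_aromatic`, `e_barrier`, `e_min2`, `nu_oh`.
#' @export
load_series <- function(dir) {
  files <- list.files(dir, pattern = "_(bonds|profile|nuoh)\\.tsv$")
  labels <- unique(sub("_(bonds|profile|nuoh)\\.tsv$", "", files))
  bad <- labels[!is_compound_label(labels)]
  if (length(bad) > 0) {
    warn(paste0("skipping file label(s) outside the compound grammar: ",
                paste(bad, collapse = ", ")))
    labels <- setdiff(labels, bad)
  }
  purrr::map_dfr(sort(labels), function(lab) {
    rec <- tibble(compound = lab, homa_quinoid = NA_real_,
                  homa_aromatic = NA_real_, e_barrier = NA_real_,
                  e_min2 = NA_real_, nu_oh = NA_real_)
    bonds_f <- file.path(dir, paste0(lab, "_bonds.tsv"))
    if (file.exists(bonds_f)) {
      h <- homa_table(read_bond_table(bonds_f))
      if ("I" %in% h$compound) {
        rec$homa_quinoid <- h$homa[h$compound == "I"]
      }
      if ("II" %in% h$compound) {
        rec$homa_aromatic <- h$homa[h$compound == "II"]
      }
    }
    prof_f <- file.path(dir, paste0(lab, "_profile.tsv"))
    if (file.exists(prof_f)) {
      g <- glance(analyze_profile(read_pt_profile(prof_f, compound = lab)))
      rec$e_barrier <- g$e_barrier
      rec$e_min2 <- g$e_min2
    }
    nu_f <- file.path(dir, paste0(lab, "_nuoh.tsv"))
    if (file.exists(nu_f)) {
      rec$nu_oh <- as.numeric(readLines(nu_f, n = 1))
    }
    rec
  })
}

#' One-stop dynamics summary for a twin-bridge trajectory
#'
#' Chains the trajectory analytics into a single reproducible table:
#' per-bridge donor possession, proton-transfer event counts, inter-bridge
#' synchrony and O-H stretching barycenters.
#'
#' @param traj A [trajectory()] with velocities.
#' @param bridges List of two [bridge_spec()] (default
#'   [synthetic_bridges()]).
#' @param hysteresis Event-detection threshold, Angstrom
#'   ([detect_pt_events()]).
#' @param window Synchrony matching window, fs ([bridge_synchrony()]).
#' @param band Barycenter window, cm^-1 ([spectrum_barycenter()]).
#' @return List of class `qb_dynamics_report`: `bridges` (tibble `bridge`,
#'   `donor_percent`, `n_events`, `barycenter`), `synchrony` (tibble
#'   `n_matched`, `match_fraction`, `mean_delay`, `max_delay`).
#' @export
bridge_dynamics_report <- function(traj, bridges = synthetic_bridges(),
                                   hysteresis = 0.05, window = 500,
                                   band = c(2200, 3400)) {
  stopifnot(length(bridges) == 2)
  series <- purrr::map(bridges, ~ bridge_series(traj, .x))
  events <- purrr::map(series, detect_pt_events, hysteresis = hysteresis)
  poss <- possession_report(traj, bridges)
  spec <- compare_bridge_spectra(traj, bridges, window = band)
  sync <- bridge_synchrony(events[[1]], events[[2]], window = window)
  per_bridge <- tibble(
    bridge = poss$bridge,
    donor_percent = poss$donor_percent,
    n_events = vapply(events, nrow, 1L),
    barycenter = spec$summary$barycenter
  )
  structure(list(
    bridges = per_bridge,
    synchrony = tibble(
      n_matched = nrow(sync$delays),
      match_fraction = sync$match_fraction,
      mean_delay = if (nrow(sync$delays)) mean(sync$delays$delay)
                   else NA_real_,
      max_delay = sync$max_delay
    ),
    barycenter_split = spec$split
  ), class = "qb_dynamics_report")
}

#' @export
print.qb_dynamics_report <- function(x, ...) {
  cat("<qb_dynamics_report>\n")
  print(x$bridges)
  print(x$synchrony)
  cat(sprintf("barycenter split: %.1f cm^-1\n", x$barycenter_split))
  invisible(x)
}
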