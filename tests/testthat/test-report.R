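test_that("perfectly anti-monotone descriptors give rank correlation -1", {
  rec <- tibble::tibble(
    compound = c("3a", "3b", "3c", "3d", "3e"),
    homa_quinoid = c(-0.4, -0.5, -0.6, -0.7, -0.8),
    e_barrier = c(4, 5, 6.5, 7, 9),
    e_min2 = c(1, 2, 2.5, 3, 4),
    nu_oh = c(2700, 2720, 2740, 2770, 2800)
  )
  rep <- build_series_report(rec)
  corr <- tidy(rep)
  get <- function(a, b) {
    corr$rho[(corr$var1 == a & corr$var2 == b) |
               (corr$var1 == b & corr$var2 == a)]
  }
  expect_equal(get("homa_quinoid", "e_barrier"), -1)
  expect_equal(get("e_min2", "e_barrier"), 1)
  expect_equal(get("nu_oh", "e_barrier"), 1)
  # the classic sign pattern: barrier up, second minimum up, stretching
  # wavenumber up, quinoid aromaticity down
  g <- glance(rep)
  expect_lt(g$rho_homa_barrier, 0)
  expect_gt(g$rho_min2_barrier, 0)
  expect_gt(g$rho_nuoh_barrier, 0)
})

test_that("rank correlations survive strictly monotone transforms", {
  rec <- tibble::tibble(
    compound = c("2a", "2b", "2c", "2d", "2e", "2f"),
    homa_quinoid = c(-0.31, -0.52, -0.44, -0.61, -0.38, -0.55),
    e_barrier = c(5.5, 8.2, 7.1, 9.0, 6.2, 8.6)
  )
  r1 <- tidy(build_series_report(rec))
  rec2 <- rec
  rec2$e_barrier <- exp(rec2$e_barrier / 3)
  rec2$homa_quinoid <- rec2$homa_quinoid^3  # monotone on negatives
  r2 <- tidy(build_series_report(rec2))
  expect_equal(r1$rho, r2$rho)
})

test_that("degenerate and missing data are flagged rather than guessed", {
  rec <- tibble::tibble(
    compound = c("1a", "1b", "1c"),
    homa_quinoid = c(-0.5, -0.5, -0.5),
    e_barrier = c(4, 5, 6),
    e_min2 = c(NA, 2, 3),
    nu_oh = c(2700, NA, 2750)
  )
  corr <- tidy(build_series_report(rec))
  # constant variable: correlation undefined
  expect_true(is.na(corr$rho[corr$var1 == "homa_quinoid" &
                               corr$var2 == "e_barrier"]))
  # fewer than 3 complete pairs: flagged absent
  row <- corr[corr$var1 == "e_min2" & corr$var2 == "nu_oh", ]
  expect_true(is.na(row$rho))
  expect_lt(row$n, 3)
  expect_error(build_series_report(rec[1:2, ]), "at least 3")
})

test_that("the compound-label grammar admits groups and mirror marks", {
  expect_true(all(is_compound_label(c("1a", "2b", "3g", "2c(M)"))))
  expect_false(any(is_compound_label(c("4", "2B", "notalabel", "2b(m)"))))
})

test_that("series directories load with graceful gaps", {
  dir <- file.path(tempdir(), "series_test")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  ring2 <- function(lengths) {
    paste0(c("bond\tI\tII",
             paste(naphthoquinone_ring_bonds("II"),
                   "–", lengths, sep = "\t")), collapse = "\n")
  }
  writeLines(ring2(c(1.378, 1.396, 1.376, 1.400, 1.404, 1.408)),
             file.path(dir, "2a_bonds.tsv"))
  writeLines(ring2(c(1.391, 1.412, 1.364, 1.412, 1.391, 1.421)),
             file.path(dir, "3a_bonds.tsv"))
  prof <- generate_pt_profile(6, 2)
  readr::write_tsv(tibble::tibble(r = prof$r, e = prof$energy),
                   file.path(dir, "3a_profile.tsv"), col_names = FALSE)
  writeLines("2742.5", file.path(dir, "3a_nuoh.tsv"))
  # a file whose label breaks the grammar is skipped with a warning
  writeLines("2700", file.path(dir, "xx_nuoh.tsv"))

  expect_warning(series <- load_series(dir), "xx")
  expect_equal(nrow(series), 2)
  r3a <- series[series$compound == "3a", ]
  expect_equal(r3a$homa_aromatic, 0.87823675, tolerance = 1e-8)
  expect_equal(r3a$e_barrier, 6)
  expect_equal(r3a$e_min2, 2)
  expect_equal(r3a$nu_oh, 2742.5)
  r2a <- series[series$compound == "2a", ]
  expect_true(is.na(r2a$e_barrier))
  expect_equal(r2a$homa_aromatic, 0.95241140, tolerance = 1e-8)

  expect_equal(nrow(load_series(file.path(tempdir(), "no_such_dir"))), 0)
})

test_that("report generation is deterministic", {
  rec <- tibble::tibble(
    compound = c("3a", "3b", "3c", "3d"),
    homa_quinoid = c(-0.4, -0.55, -0.62, -0.71),
    e_barrier = c(4.2, 6.1, 7.3, 8.8)
  )
  expect_identical(tidy(build_series_report(rec)),
                   tidy(build_series_report(rec)))
})

test_that("autoplot methods return ggplot objects", {
  prof <- generate_pt_profile(6, 2)
  expect_s3_class(autoplot(prof, analysis = analyze_profile(prof)), "ggplot")
  tr <- make_velocity_traj(cos(0.5 * (0:2047)))
  expect_s3_class(autoplot(power_spectrum(tr, atoms = 2)), "ggplot")
  g <- generate_bridge_trajectory(coupled_bridge_model(duration = 1, seed = 4))
  s <- bridge_series(g$trajectory, synthetic_bridges()[[1]])
  expect_s3_class(autoplot(s), "ggplot")
  rec <- tibble::tibble(compound = c("3a", "3b", "3c"),
                        homa_quinoid = c(-0.4, -0.5, -0.6),
                        e_barrier = c(4, 6, 8),
                        e_min2 = c(1, 2, 3), nu_oh = c(2700, 2750, 2800))
  expect_s3_class(autoplot(build_series_report(rec)), "ggplot")
})
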