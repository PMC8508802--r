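test_that("stationary possession follows the chain's generator matrix", {
  # symmetric rates: exactly one half regardless of coupling
  gt_sym <- bridge_ground_truth(coupled_bridge_model(k_fwd = 2, k_rev = 2,
                                                     coupling = 7))
  expect_equal(unname(gt_sym$stationary_donor_fraction), c(0.5, 0.5),
               tolerance = 1e-12)
  # independent bridges: two-state stationary value k_rev / (k_fwd + k_rev)
  gt <- bridge_ground_truth(coupled_bridge_model(k_fwd = 1, k_rev = 3,
                                                 coupling = 1))
  expect_equal(unname(gt$stationary_donor_fraction), c(0.75, 0.75),
               tolerance = 1e-12)
  # independent oracle: solve pi Q = 0 as a linear system instead of the
  # packaged eigen route
  m <- coupled_bridge_model(k_fwd = 1.7, k_rev = 0.6, coupling = 4)
  q <- quinbridge:::.bridge_generator_matrix(m)
  a <- t(q)
  a[4, ] <- 1  # replace one balance equation by the normalisation
  pi_ref <- solve(a, c(0, 0, 0, 1))
  gt2 <- bridge_ground_truth(m)
  expect_equal(unname(gt2$stationary), unname(pi_ref), tolerance = 1e-10)
  # strong coupling locks the protons together
  gt_lock <- bridge_ground_truth(coupled_bridge_model(k_fwd = 1, k_rev = 2,
                                                      coupling = 1000))
  expect_gt(gt_lock$concordance, 0.999)
})

test_that("trajectory generation is reproducible and leaves the RNG alone", {
  m <- coupled_bridge_model(k_fwd = 2, k_rev = 3, duration = 2, seed = 99)
  g1 <- generate_bridge_trajectory(m)
  set.seed(1)
  probe <- stats::rnorm(1)
  g2 <- generate_bridge_trajectory(m)
  expect_identical(g1$trajectory, g2$trajectory)
  set.seed(1)
  expect_identical(stats::rnorm(1), probe)
  # too-short durations are rejected
  expect_error(generate_bridge_trajectory(
    coupled_bridge_model(duration = 0.05)), "100 frames")
})

test_that("possession recovery stays within sojourn-count standard errors", {
  # across a seed sweep the empirical donor fraction must match the
  # analytic stationary value within 3 binomial-style SEs of the number
  # of independent sojourns
  m0 <- coupled_bridge_model(k_fwd = 1, k_rev = 3, coupling = 1,
                             duration = 25)
  tr_frac <- bridge_ground_truth(m0)$stationary_donor_fraction[[1]]
  b1 <- synthetic_bridges()[[1]]
  for (seed in 1:10) {
    m <- coupled_bridge_model(k_fwd = 1, k_rev = 3, coupling = 1,
                              duration = 25, seed = seed)
    g <- generate_bridge_trajectory(m)
    s <- bridge_series(g$trajectory, b1)
    p <- possession(s)$donor_fraction
    n_soj <- nrow(detect_pt_events(s)) + 1
    se <- sqrt(tr_frac * (1 - tr_frac) / n_soj)
    expect_lt(abs(p - tr_frac), 3 * se)
  }
})

test_that("noise-free generated protons recover the injected wavenumber", {
  m <- coupled_bridge_model(k_fwd = 1, k_rev = 1, nu_OH = 2750,
                            noise_sigma = 0, duration = 15, seed = 2)
  g <- generate_bridge_trajectory(m)
  sp <- power_spectrum(g$trajectory, atoms = 2)
  bc <- spectrum_barycenter(sp, c(2200, 3400))
  expect_lt(abs(bc$barycenter - 2750), attr(sp, "resolution"))
})

test_that("generated trajectories survive an XYZ round-trip unchanged", {
  m <- coupled_bridge_model(k_fwd = 2, k_rev = 2, duration = 2, seed = 12)
  g <- generate_bridge_trajectory(m)
  f <- tempfile(fileext = ".xyz")
  write_xyz(g$trajectory, f)
  back <- read_xyz(f)
  b1 <- synthetic_bridges()[[1]]
  p0 <- possession(bridge_series(g$trajectory, b1))
  p1 <- possession(bridge_series(back, b1))
  expect_identical(p1$donor_fraction, p0$donor_fraction)
  expect_lt(max(abs(back$x - g$trajectory$x)), 1e-6)
  expect_lt(max(abs(back$vx - g$trajectory$vx)), 1e-6)
})

test_that("double-well generation honours its stated stationary values", {
  prof <- generate_pt_profile(barrier = 5, asymmetry = 0)
  truth <- attr(prof, "truth")
  expect_equal(truth$e_barrier, 5)
  g <- glance(analyze_profile(prof))
  expect_equal(g$e_barrier, truth$e_barrier)
  expect_equal(g$e_min2, truth$e_min2)
  expect_error(generate_pt_profile(5, 5), "second minimum")
  expect_error(generate_pt_profile(-1), "positive")
})

test_that("charge tables close the loop between generator and descriptor", {
  groups <- list(
    list(position = "2", ipso = 2, atoms = 11, q_ipso = 0.05,
         q_atoms = -0.08),
    list(position = "8", ipso = 8, atoms = c(12, 13), q_ipso = 0.06,
         q_atoms = c(-0.20, 0.12))
  )
  gen <- generate_charge_table(13, groups)
  prof <- csar_profile(gen$charges, gen$groups)
  expect_identical(prof$csar, gen$expected$csar)
  expect_equal(gen$expected$csar, c(-0.03, -0.02))

  # seeded noise: recovery within 3 sigma sqrt(group size + 1)
  for (seed in 1:10) {
    gen_n <- generate_charge_table(13, groups, noise_sigma = 0.001,
                                   seed = seed)
    prof_n <- csar_profile(gen_n$charges, gen_n$groups)
    m_sz <- c(1, 2)
    tol <- 3 * 0.001 * sqrt(m_sz + 1)
    expect_true(all(abs(prof_n$csar - gen_n$expected$csar) < tol))
  }

  expect_error(generate_charge_table(13, list(
    list(position = "2", ipso = 2, atoms = 11, q_ipso = 0, q_atoms = 0),
    list(position = "3", ipso = 3, atoms = 11, q_ipso = 0, q_atoms = 0))),
    "overlap")
})
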