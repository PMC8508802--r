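test_that("bridge series reproduce static geometry and demand oxygen ends", {
  coords <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.6, 0, 0))
  tr <- make_static_traj(coords, c("O", "H", "O"), n_frames = 10)
  s <- bridge_series(tr, bridge_spec(1, 2, 3))
  expect_equal(nrow(s), 10)
  expect_true(all(s$d_donor_h == 1.0))
  expect_true(all(s$d_h_acceptor == 1.6))
  p <- possession(s)
  expect_identical(p$donor_fraction, 1)
  expect_identical(p$acceptor_fraction, 0)
  # donor/acceptor indices must point at oxygens
  tr_c <- make_static_traj(coords, c("C", "H", "O"), n_frames = 5)
  expect_error(bridge_series(tr_c, bridge_spec(1, 2, 3)), "oxygen")
})

test_that("exact ties are assigned to the donor", {
  coords <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.6, 0, 0))
  tr <- make_static_traj(coords, c("O", "H", "O"), n_frames = 8)
  p <- possession(bridge_series(tr, bridge_spec(1, 2, 3)))
  expect_identical(p$donor_fraction, 1)
})

test_that("possession fractions always sum to one exactly", {
  set.seed(99)
  for (rep in 1:20) {
    delta <- stats::rnorm(200, sd = 0.6)
    p <- possession(make_series_from_delta(delta))
    expect_identical(p$donor_fraction + p$acceptor_fraction, 1)
  }
})

test_that("donor/acceptor swap with time reversal complements possession", {
  g <- generate_bridge_trajectory(
    coupled_bridge_model(k_fwd = 1, k_rev = 2, duration = 5, seed = 17))
  s <- bridge_series(g$trajectory, synthetic_bridges()[[1]])
  p <- possession(s)$donor_fraction
  swapped <- s
  swapped$d_donor_h <- rev(s$d_h_acceptor)
  swapped$d_h_acceptor <- rev(s$d_donor_h)
  # ties go to the donor on both sides, but are measure-zero here
  expect_identical(possession(swapped)$donor_fraction, 1 - p)
})

test_that("event detection counts crossings once despite hysteresis chatter", {
  # clean monotone crossing: exactly one donor-to-acceptor event
  s <- make_series_from_delta(seq(-0.5, 0.5, length.out = 21))
  ev <- detect_pt_events(s, hysteresis = 0.05)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "donor_to_acceptor")
  # the event is stamped at the first frame past zero
  expect_equal(ev$time, s$time[which(s$d_donor_h > s$d_h_acceptor)[1]])

  # chatter confined to the hysteresis band: no confirmed events
  chatter <- make_series_from_delta(
    c(-0.5, -0.2, 0.02, -0.03, 0.04, -0.02, 0.03, -0.4, -0.5))
  expect_equal(nrow(detect_pt_events(chatter, hysteresis = 0.05)), 0)

  # chatter then a genuine exit: one event, stamped at the first crossing
  committed <- make_series_from_delta(
    c(-0.5, -0.2, 0.02, -0.03, 0.04, 0.01, 0.3, 0.5))
  ev2 <- detect_pt_events(committed, hysteresis = 0.05)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$time, committed$time[5])

  # no crossing at all
  expect_equal(nrow(detect_pt_events(make_series_from_delta(rep(-0.3, 10)))), 0)
})

test_that("event directions alternate and segments reproduce possession", {
  g <- generate_bridge_trajectory(
    coupled_bridge_model(k_fwd = 2, k_rev = 3, duration = 10, seed = 23))
  s <- bridge_series(g$trajectory, synthetic_bridges()[[1]])
  ev <- detect_pt_events(s, hysteresis = 0.05)
  expect_gt(nrow(ev), 2)
  expect_true(all(ev$direction[-1] != ev$direction[-nrow(ev)]))

  # with zero hysteresis, integrating the event segments equals the
  # frame-wise possession count
  ev0 <- detect_pt_events(s, hysteresis = 0)
  state0 <- s$d_donor_h[1] <= s$d_h_acceptor[1]
  boundaries <- c(s$time[1], ev0$time, s$time[nrow(s)] + 1)
  on_donor_frames <- 0
  state <- state0
  for (k in seq_len(length(boundaries) - 1)) {
    in_seg <- s$time >= boundaries[k] & s$time < boundaries[k + 1]
    if (state) on_donor_frames <- on_donor_frames + sum(in_seg)
    state <- !state
  }
  expect_equal(on_donor_frames / nrow(s), possession(s)$donor_fraction)
})

test_that("synchrony matching handles identical, shifted and disjoint trains", {
  ev1 <- tibble::tibble(time = c(100, 900, 2000, 3500),
                        direction = rep(c("donor_to_acceptor",
                                          "acceptor_to_donor"), 2))
  sy <- bridge_synchrony(ev1, ev1, window = 500)
  expect_equal(sy$match_fraction, 1)
  expect_true(all(sy$delays$delay == 0))

  ev2 <- ev1
  ev2$time <- ev1$time + 30
  sy2 <- bridge_synchrony(ev1, ev2, window = 500)
  expect_equal(sy2$match_fraction, 1)
  expect_true(all(sy2$delays$delay == 30))
  expect_equal(sy2$max_delay, 30)

  ev3 <- ev1
  ev3$time <- ev1$time + 10000
  sy3 <- bridge_synchrony(ev1, ev3, window = 500)
  expect_equal(sy3$match_fraction, 0)
  expect_equal(nrow(sy3$delays), 0)
})

test_that("possession percentages track the generator's bias limits", {
  br <- synthetic_bridges()
  g_acc <- generate_bridge_trajectory(
    coupled_bridge_model(k_fwd = 100, k_rev = 0.01, duration = 5, seed = 3))
  rep_acc <- possession_report(g_acc$trajectory, br)
  expect_true(all(rep_acc$donor_percent < 5))
  g_don <- generate_bridge_trajectory(
    coupled_bridge_model(k_fwd = 0.01, k_rev = 100, duration = 5, seed = 3))
  rep_don <- possession_report(g_don$trajectory, br)
  expect_true(all(rep_don$donor_percent > 95))
})

test_that("equivalent strongly-coupled bridges show near-equal possession", {
  g <- generate_bridge_trajectory(
    coupled_bridge_model(k_fwd = 2, k_rev = 4, coupling = 25,
                         duration = 25, seed = 41))
  rep <- possession_report(g$trajectory, synthetic_bridges())
  expect_lt(abs(rep$donor_percent[1] - rep$donor_percent[2]), 5)
})
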