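# Synthetic coupled-bridge trajectories with analytically known ground
# truth. The joint proton configuration of the twin bridges evolves as a
# four-state continuous-time Markov chain (DD, DA, AD, AA: each letter is
# one bridge, D = proton on the donor, A = on the acceptor). A coupling
# knob gamma >= 1 multiplies the rates of transitions that create
# concordant joint states (DD/AA) and divides those that create discordant
# ones, reproducing the heavily correlated proton motion of twin
# intramolecular bridges with a single parameter. On top of the discrete
# state, each proton carries a deterministic O-H stretching oscillation
# plus Gaussian positional noise; velocities are emitted analytically.
# Stationary possession fractions and the concordance probability follow
# from the chain's generator matrix, giving exact oracles for every
# downstream statistic.

#' Parameterise a synthetic coupled-bridge model
#'
#' @param R_OO Donor-acceptor O...O distance, Angstrom (default 2.585, the
#'   middle of the 2.58-2.60 range typical of these bridges).
#' @param d_eq Equilibrium O-H bond length, Angstrom (default 1.00).
#' @param k_fwd,k_rev Per-bridge donor-to-acceptor / acceptor-to-donor
#'   hopping rates, ps^-1.
#' @param coupling Gamma >= 1; 1 = independent bridges, large values lock
#'   the two protons to the same side.
#' @param nu_OH O-H stretching wavenumber(s), cm^-1; length 1 or 2
#'   (per bridge). Default 2750.
#' @param amplitude Stretching oscillation amplitude, Angstrom (default
#'   0.05).
#' @param noise_sigma Gaussian positional noise, Angstrom (default 0.01).
#' @param dt Sampling interval, fs (default 1.452, i.e. a 0.0726 fs
#'   integration step recorded every 20 steps).
#' @param duration Trajectory length, ps (default 25).
#' @param seed Integer seed for reproducible generation.
#' @return List of class `qb_bridge_model`.
#' @export
coupled_bridge_model <- function(R_OO = 2.585, d_eq = 1.00,
                                 k_fwd = 1, k_rev = 1, coupling = 1,
                                 nu_OH = 2750, amplitude = 0.05,
                                 noise_sigma = 0.01, dt = 1.452,
                                 duration = 25, seed = 1) {
  if (k_fwd <= 0 || k_rev <= 0) abort("hopping rates must be positive")
  if (coupling < 1) abort("`coupling` (gamma) must be >= 1")
  if (dt <= 0) abort("`dt` must be positive")
  if (d_eq <= 0 || d_eq >= R_OO) abort("need 0 < d_eq < R_OO")
  nu_OH <- rep(as.numeric(nu_OH), length.out = 2)
  structure(list(R_OO = R_OO, d_eq = d_eq, k_fwd = k_fwd, k_rev = k_rev,
                 coupling = coupling, nu_OH = nu_OH, amplitude = amplitude,
                 noise_sigma = noise_sigma, dt = dt, duration = duration,
                 seed = as.integer(seed)),
            class = "qb_bridge_model")
}

# 4-state generator matrix, state order DD, DA, AD, AA
.bridge_generator_matrix <- function(model) {
  kf <- model$k_fwd
  kr <- model$k_rev
  g <- model$coupling
  q <- matrix(0, 4, 4,
              dimnames = list(c("DD", "DA", "AD", "AA"),
                              c("DD", "DA", "AD", "AA")))
  # bridge 1 flips change the first letter, bridge 2 flips the second;
  # rates into concordant states x gamma, into discordant states / gamma
  q["DD", "AD"] <- kf / g;  q["DD", "DA"] <- kf / g
  q["DA", "AA"] <- kf * g;  q["DA", "DD"] <- kr * g
  q["AD", "DD"] <- kr * g;  q["AD", "AA"] <- kf * g
  q["AA", "DA"] <- kr / g;  q["AA", "AD"] <- kr / g
  diag(q) <- -rowSums(q)
  q
}

#' Analytic ground truth of a coupled-bridge model
#'
#' Solves the stationary distribution of the model's four-state generator
#' matrix (no simulation involved).
#'
#' @param model A [coupled_bridge_model()].
#' @return List of class `qb_ground_truth`: `stationary_donor_fraction`
#'   (length 2, per bridge), `concordance` (stationary probability that
#'   both protons sit on the same side), `nu_OH` (injected wavenumbers,
#'   cm^-1), `stationary` (named length-4 state distribution).
#' @export
bridge_ground_truth <- function(model) {
  q <- .bridge_generator_matrix(model)
  # stationary distribution: left null vector of Q
  ns <- eigen(t(q))
  k <- which.min(abs(ns$values))
  pi_s <- Re(ns$vectors[, k])
  pi_s <- pi_s / sum(pi_s)
  names(pi_s) <- rownames(q)
  structure(list(
    stationary_donor_fraction = c(bridge1 = pi_s[["DD"]] + pi_s[["DA"]],
                                  bridge2 = pi_s[["DD"]] + pi_s[["AD"]]),
    concordance = pi_s[["DD"]] + pi_s[["AA"]],
    nu_OH = model$nu_OH,
    stationary = pi_s
  ), class = "qb_ground_truth")
}

# exact CTMC path sampled onto the frame grid; returns per-frame state ids
.simulate_chain <- function(q, pi_s, times_ps) {
  n <- length(times_ps)
  state <- sample.int(4, 1, prob = pi_s)
  out <- integer(n)
  t_now <- 0
  i <- 1L
  rates <- -diag(q)
  repeat {
    dwell <- if (rates[state] > 0) rexp(1, rates[state]) else Inf
    t_next <- t_now + dwell
    while (i <= n && times_ps[i] < t_next) {
      out[i] <- state
      i <- i + 1L
    }
    if (i > n) break
    jump_p <- q[state, ]
    jump_p[state] <- 0
    state <- sample.int(4, 1, prob = jump_p)
    t_now <- t_next
  }
  out
}

#' Atom layout of generated twin-bridge trajectories
#'
#' Generated trajectories hold six atoms: donor O, bridging H and acceptor
#' O of bridge 1 (atoms 1-3), then the same for bridge 2 (atoms 4-6), each
#' bridge along x in its own plane.
#'
#' @return List of two [bridge_spec()] matching
#'   [generate_bridge_trajectory()] output.
#' @export
synthetic_bridges <- function() {
  list(bridge_spec(1, 2, 3, label = "O1-H1-O3"),
       bridge_spec(4, 5, 6, label = "O2-H2-O4"))
}

#' Generate a synthetic coupled twin-bridge trajectory
#'
#' Simulates the model's four-state proton chain exactly (Gillespie
#' sampling started from the stationary distribution), places each proton
#' on its current side at `d_eq` from the holding oxygen plus the
#' stretching oscillation `amplitude * cos(2 pi nu c t + phase)` along the
#' O...O axis plus Gaussian noise, and emits velocities as the analytic
#' oscillation derivative plus matched noise. Oxygen atoms are fixed.
#'
#' @param model A [coupled_bridge_model()].
#' @return List: `trajectory` (a [trajectory()], atoms per
#'   [synthetic_bridges()]), `truth` (the [bridge_ground_truth()]).
#' @export
generate_bridge_trajectory <- function(model) {
  stopifnot(inherits(model, "qb_bridge_model"))
  n <- floor(model$duration * 1000 / model$dt) + 1
  if (n < 100) abort("`duration` must span at least 100 frames")
  truth <- bridge_ground_truth(model)
  q <- .bridge_generator_matrix(model)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(model$seed)
  t_fs <- (seq_len(n) - 1) * model$dt
  states <- .simulate_chain(q, truth$stationary, t_fs / 1000)
  # per-bridge side: +1 while the proton is held by the donor
  on_donor1 <- states %in% c(1L, 2L)   # DD, DA
  on_donor2 <- states %in% c(1L, 3L)   # DD, AD
  phase <- runif(2, 0, 2 * pi)
  omega <- 2 * pi * .c_cm_fs * model$nu_OH  # rad/fs per bridge
  make_bridge <- function(on_donor, om, ph) {
    osc <- model$amplitude * cos(om * t_fs + ph)
    x <- ifelse(on_donor, model$d_eq + osc, model$R_OO - model$d_eq - osc)
    x <- x + rnorm(n, sd = model$noise_sigma)
    v_osc <- -model$amplitude * om * sin(om * t_fs + ph)
    vx <- ifelse(on_donor, v_osc, -v_osc)
    vx <- vx + rnorm(n, sd = model$noise_sigma * om)
    list(x = x, vx = vx)
  }
  b1 <- make_bridge(on_donor1, omega[1], phase[1])
  b2 <- make_bridge(on_donor2, omega[2], phase[2])
  zero <- rep(0, n)
  atom_tbl <- function(atom, element, x, y, vx) {
    tibble(frame = seq_len(n), time = t_fs, atom = atom, element = element,
           x = x, y = y, z = zero, vx = vx, vy = zero, vz = zero)
  }
  data <- dplyr::bind_rows(
    atom_tbl(1L, "O", zero, zero, zero),
    atom_tbl(2L, "H", b1$x, zero, b1$vx),
    atom_tbl(3L, "O", rep(model$R_OO, n), zero, zero),
    atom_tbl(4L, "O", zero, rep(10, n), zero),
    atom_tbl(5L, "H", b2$x, rep(10, n), b2$vx),
    atom_tbl(6L, "O", rep(model$R_OO, n), rep(10, n), zero)
  )
  list(trajectory = trajectory(data, dt = model$dt),
       truth = truth)
}

#' Generate an analytic quartic double-well proton-transfer profile
#'
#' The symmetric branch is `barrier * ((x^2 - w^2)^2 / w^4)` with
#' `x = r - r0`; beyond the barrier top the curve is rescaled to
#' `asymmetry + (barrier - asymmetry) * (...)`, keeping the profile
#' continuous, the barrier exactly `barrier`, and the second minimum
#' exactly `asymmetry` above the first. Wells sit at `r0 -/+ w`
#' (`r0 = 1.3`, `w = 0.3` Angstrom) and the barrier at `r0`, all on grid
#' nodes whenever `w` is a multiple of `increment`.
#'
#' @param barrier Barrier height, kcal/mol (> 0).
#' @param asymmetry Second-minimum energy above the first, kcal/mol
#'   (>= 0, < barrier).
#' @param increment Scan grid spacing, Angstrom (default 0.05).
#' @return A [pt_profile()] with attribute `truth` (list: `e_barrier`,
#'   `e_min2`, `r_min1`, `r_barrier`, `r_min2`).
#' @export
generate_pt_profile <- function(barrier, asymmetry = 0, increment = 0.05) {
  if (barrier <= 0) abort("`barrier` must be positive")
  if (increment <= 0) abort("`increment` must be positive")
  if (asymmetry < 0) abort("`asymmetry` must be >= 0")
  if (asymmetry >= barrier) {
    abort("`asymmetry` must be below `barrier` (the second minimum vanishes)")
  }
  r0 <- 1.3
  w <- 0.3
  kmax <- ceiling((w + 4 * increment) / increment)
  r <- r0 + increment * (-kmax:kmax)
  x <- r - r0
  qq <- ((x^2 - w^2)^2) / w^4
  e <- ifelse(x <= 0, barrier * qq, asymmetry + (barrier - asymmetry) * qq)
  prof <- pt_profile(r, e)
  attr(prof, "truth") <- list(e_barrier = barrier, e_min2 = asymmetry,
                              r_min1 = r0 - w, r_barrier = r0,
                              r_min2 = r0 + w)
  prof
}

#' Generate a per-atom charge table with known cSAR values
#'
#' Builds a baseline table of `n_atoms` atoms with zero (or small Gaussian)
#' charges and injects the specified ipso/substituent charges, so that the
#' expected cSAR of every position is known exactly by construction.
#'
#' @param n_atoms Total number of atoms.
#' @param groups List of groups, each a list with `position`, `ipso`
#'   (index), `atoms` (indices), `q_ipso` (charge on the ipso carbon) and
#'   `q_atoms` (charges on the substituent atoms, recycled to length).
#' @param noise_sigma Gaussian noise added to every atom's charge
#'   (default 0).
#' @param seed Integer seed used when `noise_sigma > 0`.
#' @return List: `charges` (tibble `atom`, `element`, `charge`),
#'   `expected` (tibble `position`, `csar` — exact injected values),
#'   `groups` (list of [substituent_group()]).
#' @export
generate_charge_table <- function(n_atoms, groups = list(),
                                  noise_sigma = 0, seed = 1) {
  all_sub <- unlist(lapply(groups, function(g) g$atoms))
  if (anyDuplicated(all_sub)) {
    abort("substituent atom sets overlap between groups")
  }
  charge <- rep(0, n_atoms)
  element <- rep("C", n_atoms)
  expected <- tibble(position = character(0), csar = numeric(0))
  sgroups <- list()
  for (g in groups) {
    qa <- rep(g$q_atoms, length.out = length(g$atoms))
    charge[g$atoms] <- charge[g$atoms] + qa
    charge[g$ipso] <- charge[g$ipso] + g$q_ipso
    expected <- dplyr::bind_rows(
      expected, tibble(position = as.character(g$position),
                       csar = sum(qa) + g$q_ipso))
    sgroups <- c(sgroups, list(
      substituent_group(g$ipso, g$atoms, g$position)))
  }
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    charge <- charge + rnorm(n_atoms, sd = noise_sigma)
  }
  list(
    charges = tibble(atom = seq_len(n_atoms), element = element,
                     charge = charge),
    expected = dplyr::arrange(expected, .data$position),
    groups = sgroups
  )
}
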