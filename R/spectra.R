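# Atomic-velocity power spectra via the Wiener-Khinchin route: velocity
# autocorrelation up to a maximum lag, Hann lag-window taper, cosine
# transform on a zero-padded power-of-two grid, frequency axis in
# wavenumbers (cm^-1). Summed over Cartesian components and selected atoms;
# no mass weighting (the bridge-proton comparison is per-proton).

.next_pow2 <- function(n) 2^ceiling(log2(n))

# biased autocovariance (divide by n) of a zero-padded series via FFT;
# positive semidefinite as a full sequence
.autocov_fft <- function(v, max_lag) {
  n <- length(v)
  m <- .next_pow2(2 * n)
  f <- fft(c(v, rep(0, m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / m / n
  ac[seq_len(max_lag + 1)]
}

#' Velocity power spectrum of selected atoms
#'
#' Computes the velocity autocorrelation of each selected atom and
#' Cartesian component over the production (post-equilibration) frames,
#' applies a Hann taper up to `max_lag_fs`, cosine-transforms on a
#' zero-padded power-of-two grid, and sums the contributions. The one-sided
#' spectrum is normalised so that its integral over wavenumber equals the
#' summed mean squared velocity of the selection (Parseval); negative
#' taper sidelobes are clipped at zero.
#'
#' @param traj A [trajectory()] with velocities (see
#'   [estimate_velocities()] for position-only data).
#' @param atoms Vector of 1-based atom indices to include.
#' @param max_lag_fs Maximum autocorrelation lag in fs; default 2000 fs
#'   (2 ps), which sets the intrinsic line width.
#' @param pad 	Zero-padding factor (>= 1) refining the wavenumber grid;
#'   default 2.
#' @return Tibble of class `qb_power_spectrum` with columns `wavenumber`
#'   (cm^-1, 0 to the Nyquist limit `1/(2 dt c)`) and `intensity`
#'   (Angstrom^2/fs^2 per cm^-1). Attributes: `resolution` (cm^-1 per bin),
#'   `atoms`, `dt`, `mean_sq_velocity`.
#' @export
power_spectrum <- function(traj, atoms, max_lag_fs = 2000, pad = 2) {
  if (!traj_has_velocities(traj)) {
    abort("trajectory has no velocities; see estimate_velocities()")
  }
  prod <- traj_production(traj)
  nf <- dplyr::n_distinct(prod$frame)
  if (nf < 1024) {
    abort(sprintf("need >= 1024 frames after equilibration, have %d", nf))
  }
  dt <- traj_dt(traj)
  lag <- min(floor(max_lag_fs / dt), nf - 1)
  if (lag < 8) abort("`max_lag_fs` too short for this sampling interval")
  acc <- numeric(lag + 1)
  msv <- 0
  for (a in atoms) {
    vm <- traj_atom_matrix(prod, a, "velocity")
    for (k in 1:3) {
      acc <- acc + .autocov_fft(vm[, k], lag)
      msv <- msv + mean(vm[, k]^2)
    }
  }
  taper <- 0.5 * (1 + cos(pi * (0:lag) / lag))
  cw <- acc * taper
  n_fft <- .next_pow2(2 * (lag + 1)) * max(1, round(pad))
  padded <- c(cw, rep(0, n_fft - length(cw)))
  re_f <- Re(fft(padded))
  s_full <- dt * (2 * re_f - cw[1])
  half <- n_fft / 2
  s <- s_full[1:(half + 1)]
  s[2:half] <- 2 * s[2:half]          # one-sided doubling
  s[s < 0] <- 0
  dnu <- 1 / (n_fft * dt * .c_cm_fs)  # cm^-1 per bin
  # density per wavenumber: S(f) df = I(nu) dnu with f = nu * c
  out <- tibble(wavenumber = (0:half) * dnu, intensity = s * .c_cm_fs)
  attr(out, "resolution") <- dnu
  attr(out, "atoms") <- atoms
  attr(out, "dt") <- dt
  attr(out, "mean_sq_velocity") <- msv
  class(out) <- c("qb_power_spectrum", class(out))
  out
}

#' Intensity-weighted band barycenter of a spectrum window
#'
#' @param spec A [power_spectrum()] (or data frame with `wavenumber`,
#'   `intensity`).
#' @param window Numeric `c(lo, hi)` in cm^-1; default `c(2200, 3400)`,
#'   bracketing both red-shifted dynamical and harmonic-like O-H
#'   stretching bands.
#' @return One-row tibble: `barycenter` (cm^-1), `lo`, `hi`,
#'   `integrated_intensity`.
#' @export
spectrum_barycenter <- function(spec, window = c(2200, 3400)) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be c(lo, hi) with lo < hi")
  }
  sel <- dplyr::filter(as_tibble(spec),
                       .data$wavenumber >= window[1],
                       .data$wavenumber <= window[2])
  if (nrow(sel) == 0) abort("window does not overlap the spectrum grid")
  tot <- sum(sel$intensity)
  if (tot <= 0) abort("zero intensity inside the window")
  res <- attr(spec, "resolution") %||% mean(diff(sel$wavenumber))
  tibble(
    barycenter = sum(sel$wavenumber * sel$intensity) / tot,
    lo = window[1], hi = window[2],
    integrated_intensity = tot * res
  )
}

#' Compare the O-H stretching bands of twin bridge protons
#'
#' Computes a per-proton velocity power spectrum for each bridge, the
#' band barycenter inside `window`, and the absolute barycenter split — the
#' quantity whose near-vanishing signals dynamically equivalent bridges.
#'
#' @param traj A [trajectory()] with velocities.
#' @param bridges List of two [bridge_spec()].
#' @param window Barycenter window, cm^-1 (see [spectrum_barycenter()]).
#' @param ... Passed on to [power_spectrum()].
#' @return List of class `qb_bridge_spectra`: `summary` (tibble `bridge`,
#'   `barycenter`, `integrated_intensity`), `split` (cm^-1), `spectra`
#'   (named list of the two spectra).
#' @export
compare_bridge_spectra <- function(traj, bridges, window = c(2200, 3400),
                                   ...) {
  stopifnot(length(bridges) == 2)
  spectra <- purrr::map(bridges, function(b) {
    power_spectrum(traj, atoms = b$proton, ...)
  })
  names(spectra) <- vapply(bridges, function(b) b$label, "")
  summ <- purrr::map2_dfr(spectra, names(spectra), function(s, nm) {
    bc <- spectrum_barycenter(s, window)
    tibble(bridge = nm, barycenter = bc$barycenter,
           integrated_intensity = bc$integrated_intensity)
  })
  structure(list(summary = summ,
                 split = abs(diff(summ$barycenter)),
                 spectra = spectra),
            class = "qb_bridge_spectra")
}

#' @export
print.qb_bridge_spectra <- function(x, ...) {
  cat("<qb_bridge_spectra>\n")
  print(x$summary)
  cat(sprintf("barycenter split: %.1f cm^-1\n", x$split))
  invisible(x)
}

#' Write a spectrum as a two-column text file
#'
#' @param spec A [power_spectrum()].
#' @param path Output path (tab-separated `wavenumber`, `intensity`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  readr::write_tsv(as_tibble(spec)[c("wavenumber", "intensity")], path)
  invisible(path)
}
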