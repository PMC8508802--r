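# Small in-code fixtures shared across test files.

# one static frame as a plain tibble
make_frame <- function(coords, elements) {
  tibble::tibble(
    frame = 1L, atom = seq_len(nrow(coords)), element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
}

# repeat a static frame into a trajectory
make_static_traj <- function(coords, elements, n_frames = 10, dt = 1.452) {
  one <- make_frame(coords, elements)
  frames <- dplyr::bind_rows(lapply(seq_len(n_frames), function(f) {
    fr <- one
    fr$frame <- f
    fr
  }))
  trajectory(frames, dt = dt)
}

# hand-built bridge series from a signed asymmetry sequence:
# delta = d_donor_h - d_h_acceptor with d_oo fixed at 2.6
make_series_from_delta <- function(delta, dt = 1.452) {
  s <- tibble::tibble(
    time = (seq_along(delta) - 1) * dt,
    d_donor_h = (2.6 + delta) / 2,
    d_h_acceptor = (2.6 - delta) / 2,
    bridge = "test"
  )
  class(s) <- c("qb_bridge_series", class(s))
  s
}

# regular planar carbon hexagon with the given side length
make_hexagon <- function(side = 1.388, elements = rep("C", 6)) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  r <- side  # circumradius equals side for a regular hexagon
  make_frame(cbind(r * cos(ang), r * sin(ang), 0), elements)
}

# trajectory with prescribed per-frame x-velocities for a single H atom
# flanked by two fixed O atoms (for spectral tests)
make_velocity_traj <- function(vx, dt = 1.452) {
  n <- length(vx)
  zero <- rep(0, n)
  frames <- dplyr::bind_rows(
    tibble::tibble(frame = seq_len(n), atom = 1L, element = "O",
                   x = 0, y = 0, z = 0, vx = zero, vy = zero, vz = zero),
    tibble::tibble(frame = seq_len(n), atom = 2L, element = "H",
                   x = 1, y = 0, z = 0, vx = vx, vy = zero, vz = zero),
    tibble::tibble(frame = seq_len(n), atom = 3L, element = "O",
                   x = 2.6, y = 0, z = 0, vx = zero, vy = zero, vz = zero)
  )
  trajectory(frames, dt = dt)
}

parent_table_path <- function() {
  system.file("extdata", "parent_bond_lengths.tsv", package = "quinbridge")
}
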