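# Trajectory container: a long tibble (frame, time, atom, element, x, y, z
# [, vx, vy, vz]) with sampling metadata carried as attributes.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

#' Build a trajectory from a long coordinate table
#'
#' A trajectory is a tibble in long format with one row per atom per frame
#' and columns `frame`, `time` (fs), `atom` (1-based index), `element`,
#' `x`, `y`, `z` (Angstrom) and, optionally, velocities `vx`, `vy`, `vz`
#' (Angstrom/fs). The sampling interval `dt` (fs) and the equilibration
#' window to drop from analyses (fs) travel with the object as attributes.
#'
#' @param data Data frame with at least `frame`, `atom`, `element`,
#'   `x`, `y`, `z`. A `time` column is derived from `frame` and `dt` when
#'   absent.
#' @param dt Sampling interval between consecutive frames, fs.
#' @param equilibration Initial time span (fs) that trajectory analyses
#'   discard before computing statistics. Default 0.
#' @return A tibble of class `qb_trajectory`.
#' @examples
#' frames <- tidyr::expand_grid(frame = 1:3, atom = 1:2)
#' frames$element <- "O"
#' frames$x <- as.numeric(frames$atom)
#' frames$y <- 0
#' frames$z <- 0
#' trajectory(frames, dt = 1.452)
#' @export
trajectory <- function(data, dt, equilibration = 0) {
  data <- as_tibble(data)
  needed <- c("frame", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (fs)")
  }
  if (equilibration < 0) abort("`equilibration` must be >= 0 fs")
  bad <- setdiff(unique(data$element), .element_symbols)
  if (length(bad) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(data$x) & is.finite(data$y) & is.finite(data$z))) {
    abort("coordinates must be finite")
  }
  data <- dplyr::arrange(data, .data$frame, .data$atom)
  # constant atom count and element ordering across frames (vectorised:
  # after sorting, every frame block must repeat the first frame's layout)
  frames <- sort(unique(data$frame))
  nf <- length(frames)
  if (nrow(data) %% nf != 0) {
    abort("atom count and element ordering must be identical in every frame")
  }
  na <- nrow(data) %/% nf
  ok <- all(data$frame == rep(frames, each = na)) &&
    all(data$atom == rep(data$atom[seq_len(na)], nf)) &&
    all(data$element == rep(data$element[seq_len(na)], nf))
  if (!ok) {
    abort("atom count and element ordering must be identical in every frame")
  }
  if (!("time" %in% names(data))) {
    data$time <- (match(data$frame, frames) - 1) * dt
  }
  dur <- (length(frames) - 1) * dt
  if (length(frames) > 1 && equilibration >= dur) {
    abort("`equilibration` must be shorter than the trajectory duration")
  }
  vel_cols <- c("vx", "vy", "vz")
  has_vel <- all(vel_cols %in% names(data))
  keep <- c("frame", "time", "atom", "element", "x", "y", "z",
            if (has_vel) vel_cols)
  out <- data[keep]
  attr(out, "dt") <- dt
  attr(out, "equilibration") <- equilibration
  class(out) <- c("qb_trajectory", class(out))
  out
}

#' @export
print.qb_trajectory <- function(x, ...) {
  nf <- dplyr::n_distinct(x$frame)
  na <- dplyr::n_distinct(x$atom)
  cat(sprintf(
    "<qb_trajectory> %d frame(s) x %d atoms, dt = %g fs, equilibration = %g fs, velocities: %s\n",
    nf, na, traj_dt(x), traj_equilibration(x),
    if (traj_has_velocities(x)) "yes" else "no"))
  NextMethod()
}

#' Trajectory metadata accessors
#'
#' @param traj A [trajectory()].
#' @return `traj_dt()` and `traj_equilibration()` return a number (fs);
#'   `traj_n_frames()` an integer; `traj_has_velocities()` a logical.
#' @export
traj_dt <- function(traj) attr(traj, "dt")

#' @rdname traj_dt
#' @export
traj_equilibration <- function(traj) attr(traj, "equilibration") %||% 0

#' @rdname traj_dt
#' @export
traj_n_frames <- function(traj) dplyr::n_distinct(traj$frame)

#' @rdname traj_dt
#' @export
traj_has_velocities <- function(traj) {
  all(c("vx", "vy", "vz") %in% names(traj))
}

#' Set the equilibration window of a trajectory
#'
#' @param traj A [trajectory()].
#' @param equilibration Time span (fs) to drop from the start in analyses.
#' @return The trajectory with the new equilibration attribute.
#' @export
set_equilibration <- function(traj, equilibration) {
  trajectory(traj, dt = traj_dt(traj), equilibration = equilibration)
}

# rows after the equilibration cut; errors when nothing remains
traj_production <- function(traj) {
  eq <- traj_equilibration(traj)
  t0 <- min(traj$time)
  out <- dplyr::filter(traj, .data$time >= t0 + eq)
  if (nrow(out) == 0) {
    abort("equilibration window spans the whole trajectory")
  }
  out
}

# per-atom coordinate (or velocity) matrix, frames x 3, time-ordered
traj_atom_matrix <- function(traj, atom, what = c("position", "velocity")) {
  what <- match.arg(what)
  rows <- dplyr::arrange(dplyr::filter(traj, .data$atom == !!atom), .data$time)
  if (nrow(rows) == 0) abort(paste0("atom index ", atom, " not present"))
  cols <- if (what == "position") c("x", "y", "z") else c("vx", "vy", "vz")
  if (what == "velocity" && !traj_has_velocities(traj)) {
    abort("trajectory carries no velocities")
  }
  as.matrix(rows[cols])
}

#' Read a (multi-frame) XYZ file
#'
#' Parses standard XYZ: an atom-count line, a comment line (which may carry
#' time metadata as `t= <fs>`), then one `element x y z` line per atom.
#' Three additional numeric columns per atom line are read as velocities in
#' Angstrom/fs; when the comment line declares `vel_unit=au`, velocities are
#' converted from atomic units (Bohr per atomic time unit) on read.
#'
#' @param path Path to the XYZ file.
#' @param dt Sampling interval in fs. Required when the file's comment lines
#'   carry no `t=` metadata; there is no silent default.
#' @param equilibration Equilibration window (fs) recorded on the result.
#' @return A [trajectory()].
#' @export
read_xyz <- function(path, dt = NULL, equilibration = 0) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  pos <- 1L
  frame <- 0L
  recs <- list()
  times <- numeric(0)
  au_vel <- 0.529177210903 / 0.02418884254  # Bohr/atu -> Angstrom/fs
  while (pos <= length(lines)) {
    if (grepl("^\\s*$", lines[pos])) {
      pos <- pos + 1L
      next
    }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0) {
      abort(sprintf("frame %d: malformed atom-count header '%s'",
                    frame, lines[pos]))
    }
    if (pos + 1L + n > length(lines)) {
      abort(sprintf("frame %d: declared %d atoms but file ends early",
                    frame, n))
    }
    comment <- lines[pos + 1L]
    tmatch <- regmatches(comment,
                         regexpr("t=\\s*([-0-9.eE+]+)", comment))
    t_fs <- if (length(tmatch) == 1) {
      as.numeric(sub("t=\\s*", "", tmatch))
    } else {
      NA_real_
    }
    vel_au <- grepl("vel_unit=au", comment, fixed = TRUE)
    atom_lines <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(atom_lines), "\\s+")
    nfield <- lengths(tok)
    if (any(nfield < 4)) {
      abort(sprintf("frame %d: atom line with fewer than 4 fields", frame))
    }
    elem <- vapply(tok, `[[`, "", 1L)
    num <- lapply(tok, function(v) suppressWarnings(as.numeric(v[-1])))
    if (any(vapply(num, function(v) any(is.na(v[1:3])), TRUE))) {
      abort(sprintf("frame %d: non-numeric coordinate field", frame))
    }
    xyz <- t(vapply(num, function(v) v[1:3], numeric(3)))
    rec <- tibble(
      frame = frame, atom = seq_len(n), element = elem,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
    if (all(nfield >= 7)) {
      vel <- t(vapply(num, function(v) v[4:6], numeric(3)))
      if (vel_au) vel <- vel * au_vel
      rec$vx <- vel[, 1]
      rec$vy <- vel[, 2]
      rec$vz <- vel[, 3]
    }
    recs[[frame]] <- rec
    times[frame] <- t_fs
    pos <- pos + 2L + n
  }
  if (frame == 0L) abort("empty XYZ file")
  counts <- vapply(recs, nrow, 1L)
  if (dplyr::n_distinct(counts) != 1) {
    abort("inconsistent atom count across frames")
  }
  data <- dplyr::bind_rows(recs)
  if (all(is.finite(times)) && frame > 1) {
    data$time <- rep(times, each = counts[1])
    dt_file <- diff(times)
    dt <- dt %||% mean(dt_file)
  } else if (frame == 1) {
    dt <- dt %||% 1
  } else if (is.null(dt)) {
    abort("file carries no time metadata; supply `dt` explicitly")
  }
  trajectory(data, dt = dt, equilibration = equilibration)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' Coordinates (and velocities when present) are written with six decimal
#' places; each comment line carries the frame time as `t= <fs>`.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (nrow(traj) == 0) abort("cannot write an empty trajectory")
  has_vel <- traj_has_velocities(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  split_frames <- split(as_tibble(traj), traj$frame)
  for (fr in split_frames) {
    fr <- dplyr::arrange(fr, .data$atom)
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("t= %.6f", fr$time[1]), con)
    if (has_vel) {
      writeLines(sprintf("%-3s %14.6f %14.6f %14.6f %14.6f %14.6f %14.6f",
                         fr$element, fr$x, fr$y, fr$z,
                         fr$vx, fr$vy, fr$vz), con)
    } else {
      writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                         fr$element, fr$x, fr$y, fr$z), con)
    }
  }
  invisible(path)
}

#' Estimate velocities by central finite differences of positions
#'
#' For trajectories recorded without velocities, approximates the velocity
#' of every atom as (r(t+dt) - r(t-dt)) / (2 dt); one-sided differences are
#' used at the ends. The finite-difference transfer function attenuates
#' high-frequency content by sinc(2 pi f dt), so spectra from estimated
#' velocities are slightly damped near the Nyquist limit.
#'
#' @param traj A [trajectory()] without velocity columns.
#' @return The trajectory with `vx`, `vy`, `vz` columns added (Angstrom/fs).
#' @export
estimate_velocities <- function(traj) {
  if (traj_has_velocities(traj)) return(traj)
  dt <- traj_dt(traj)
  grad1 <- function(v) {
    n <- length(v)
    if (n < 2) return(rep(0, n))
    c(v[2] - v[1],
      if (n > 2) (v[3:n] - v[1:(n - 2)]) / 2 else NULL,
      v[n] - v[n - 1]) / dt
  }
  out <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(as_tibble(traj), .data$atom, .data$time),
                    .data$atom),
    vx = grad1(.data$x), vy = grad1(.data$y), vz = grad1(.data$z)
  )
  out <- dplyr::ungroup(out)
  trajectory(out, dt = dt, equilibration = traj_equilibration(traj))
}
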