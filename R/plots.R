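# ggplot2 views of the main result types.

#' Plot a velocity power spectrum
#'
#' @param object A [power_spectrum()].
#' @param window Optional `c(lo, hi)` shading the barycenter window.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qb_power_spectrum <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)),
                  y = "spectral density (arb.)")
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

#' Plot a proton-transfer scan profile
#'
#' @param object A [pt_profile()].
#' @param analysis Optional `qb_pt_analysis` whose stationary points are
#'   marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qb_pt_profile <- function(object, analysis = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$r, .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "O-H distance (Å)", y = "E (kcal/mol)")
  if (!is.null(analysis)) {
    p <- p + ggplot2::geom_point(data = tidy(analysis),
                                 ggplot2::aes(colour = .data$type), size = 2)
  }
  p
}

#' Plot donor-proton and proton-acceptor distance traces
#'
#' @param object A [bridge_series()].
#' @param ... Unused.
#' @return A ggplot with one line per distance, the classic view in which
#'   proton-transfer events appear as crossings of the two traces.
#' @export
autoplot.qb_bridge_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("d_donor_h", "d_h_acceptor"),
                              names_to = "pair", values_to = "d")
  ggplot2::ggplot(long, ggplot2::aes(.data$time / 1000, .data$d,
                                     colour = .data$pair)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(d_donor_h = "#c0392b", d_h_acceptor = "#27ae60"),
      labels = c(d_donor_h = "donor-H", d_h_acceptor = "H-acceptor")) +
    ggplot2::labs(x = "t (ps)", y = "distance (Å)", colour = NULL)
}

#' Plot descriptor relations of a compound series
#'
#' @param object A `qb_series_report` from [build_series_report()].
#' @param ... Unused.
#' @return A ggplot of each available descriptor against the barrier
#'   height, faceted by descriptor.
#' @export
autoplot.qb_series_report <- function(object, ...) {
  rec <- object$records
  vars <- intersect(c("homa_quinoid", "e_min2", "nu_oh"), names(rec))
  long <- tidyr::pivot_longer(rec[c("compound", "e_barrier", vars)],
                              dplyr::all_of(vars),
                              names_to = "descriptor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$e_barrier, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = "barrier (kcal/mol)", y = NULL)
}
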