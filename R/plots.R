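#' Plot a waveform record
#'
#' Line plot of the signal with the generator's ground-truth R apexes (when
#' present) marked.
#'
#' @param object A [waveform_record()].
#' @param window Optional numeric length-2 time window in seconds to zoom
#'   into.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot waveform_record
#' @export
autoplot.waveform_record <- function(object, window = NULL, ...) {
  dat <- tibble::as_tibble(object)
  gt <- attr(object, "ground_truth")
  if (!is.null(window)) {
    dat <- dat[dat$t >= window[1] & dat$t <= window[2], ]
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)",
                  title = attr(object, "record_id")) +
    ggplot2::theme_minimal()
  if (!is.null(gt) && length(gt$r_times)) {
    rt <- gt$r_times
    if (!is.null(window)) rt <- rt[rt >= window[1] & rt <= window[2]]
    if (length(rt)) {
      p <- p + ggplot2::geom_vline(xintercept = rt, colour = "red",
                                   linetype = "dotted", alpha = 0.5)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the triage-level distribution of an outcome table
#'
#' Stacked bar chart of triage levels per disease class.
#'
#' @param table Tidy outcome tibble (e.g. [triage_fixture()] output, or the
#'   `"tidy"` attribute of [build_triage_dataset()]); needs `ecg_class` and
#'   `triage` columns.
#' @return A ggplot object.
#' @export
plot_triage_distribution <- function(table = triage_fixture("table6")) {
  stopifnot(all(c("ecg_class", "triage") %in% names(table)))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$ecg_class,
                                      fill = .data$triage)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_viridis_d(direction = -1) +
    ggplot2::labs(x = NULL, y = "patients", fill = "triage level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
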