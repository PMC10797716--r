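#' Convenience plots (CEAC, cost-effectiveness plane, tornado)
#'
#' Thin ggplot2 wrappers over the exported data; the CSV/JSON exports are
#' the source of truth and these plots carry no formatting guarantees.
#'
#' @param curve A `ceac_curve`.
#' @param wtp Optional threshold to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, wtp = NULL) {
  requireNamespace("ggplot2", quietly = TRUE) ||
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(as.data.frame(curve),
                       ggplot2::aes(x = lambda, y = probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (US$ per QALY)",
                  y = "P(add-on cost-effective)")
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp,
                                                  linetype = "dashed")
  p
}

#' @rdname plot_ceac
#' @param draws A `psa_draws` data frame.
#' @export
plot_ce_plane <- function(draws, wtp = attr(draws, "wtp")) {
  requireNamespace("ggplot2", quietly = TRUE) ||
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(as.data.frame(draws),
                       ggplot2::aes(x = delta_qaly,
                                    y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (US$)")
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' @rdname plot_ceac
#' @param dsa A `dsa_result`.
#' @export
plot_tornado <- function(dsa) {
  requireNamespace("ggplot2", quietly = TRUE) ||
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- as.data.frame(dsa)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  d$lo <- pmin(d$nmb_low, d$nmb_high)
  d$hi <- pmax(d$nmb_low, d$nmb_high)
  ggplot2::ggplot(d, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       yend = parameter),
                          linewidth = 4) +
    ggplot2::geom_vline(xintercept = attr(dsa, "base_nmb"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Incremental net monetary benefit (US$)", y = NULL)
}
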