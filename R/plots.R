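#' Plot a cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness against willingness-to-pay, one
#' line per estimation method (and per probability source when the
#' bootstrap column is present).
#'
#' @param object A `"nbr_ceac"` tibble from [ceac()], or several bound
#'   together with `dplyr::bind_rows()`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbr_ceac <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- df[c("wtp", "method", "prob_ce")]
  long$source <- "regression"
  if ("prob_ce_bootstrap" %in% names(df)) {
    boot <- df[c("wtp", "method")]
    boot$prob_ce <- df$prob_ce_bootstrap
    boot$source <- "bootstrap"
    long <- dplyr::bind_rows(long, boot)
  }
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$wtp, y = .data$prob_ce,
                 colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "willingness-to-pay per unit of effectiveness",
                  y = "probability of cost-effectiveness",
                  colour = "estimator") +
    ggplot2::theme_minimal()
  if (length(unique(long$source)) > 1) {
    p <- p + ggplot2::aes(linetype = .data$source) +
      ggplot2::labs(linetype = "probability")
  }
  p
}

#' @rdname autoplot.nbr_ceac
#' @export
plot_ceac <- function(object, ...) autoplot.nbr_ceac(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
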