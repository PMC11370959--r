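#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-probe results of a scan
#'
#' @param x An `ewas_result`.
#' @param ... Unused.
#' @return Tibble of per-probe estimates sorted by p.
#' @method tidy ewas_result
#' @export
tidy.ewas_result <- function(x, ...) {
  tibble::as_tibble(x$results)
}

#' Scan-level summary
#'
#' @param x An `ewas_result`.
#' @param ... Unused.
#' @return One-row tibble: probes, samples, covariates, nSV, lambda,
#'   threshold, hits.
#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$results),
    n_samples = x$n_samples,
    covariates = paste(x$covariates, collapse = "+"),
    n_sv = x$n_sv,
    lambda = x$lambda,
    threshold = x$threshold,
    n_hits = length(select_hits(x))
  )
}

#' QQ plot of a scan's p-values
#'
#' @param object An `ewas_result`.
#' @param ... Unused.
#' @return A ggplot: observed vs expected -log10 p with the identity line
#'   and the genomic inflation factor in the subtitle.
#' @method autoplot ewas_result
#' @export
autoplot.ewas_result <- function(object, ...) {
  dat <- qq_data(object$results$p[!is.na(object$results$p)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda = %.3f", object$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of an association battery
#'
#' Odds ratios with 95% CIs on a log scale, unadjusted and adjusted models
#' side by side; omitted exposures are dropped.
#'
#' @param associations Tibble from [run_battery()].
#' @return A ggplot.
#' @export
plot_forest <- function(associations) {
  dat <- associations[!associations$omitted, ]
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$odds_ratio, y = .data$exposure,
                 colour = .data$model)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
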