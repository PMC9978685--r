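#' Instrument scatter plot for a harmonized set
#'
#' Variant-outcome effects against variant-exposure effects with error
#' bars, plus the fixed-effect IVW slope through the origin — the standard
#' diagnostic view of a two-sample MR instrument set.
#'
#' @param object An `mr_harmonized` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_harmonized <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  slope <- mr_ivw(wald_ratios(object))$beta
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta_exposure,
                                    y = .data$beta_outcome)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - Z95 * .data$se_outcome,
                   ymax = .data$beta_outcome + Z95 * .data$se_outcome),
      width = 0, colour = "grey50"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exposure - Z95 * .data$se_exposure,
                   xmax = .data$beta_exposure + Z95 * .data$se_exposure),
      height = 0, colour = "grey50"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = slope,
                         linetype = "dashed") +
    ggplot2::labs(
      x = paste0("Effect on ", attr(object, "exposure_name") %||%
                   "exposure"),
      y = paste0("Effect on ", attr(object, "outcome_name") %||% "outcome")
    ) +
    ggplot2::theme_minimal()
}

#' Bar view of a mediation decomposition
#'
#' @param object An `mr_mediation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_mediation <- function(object, ...) {
  dat <- tibble::tibble(
    component = factor(c("total", "indirect (via mediator)", "direct"),
                       levels = c("total", "indirect (via mediator)",
                                  "direct")),
    beta = c(object$total$beta, object$indirect_beta,
             object$total$beta - object$indirect_beta)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$component, y = .data$beta)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Effect (log odds)") +
    ggplot2::theme_minimal()
}
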