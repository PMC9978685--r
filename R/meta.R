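#' Convert a published odds ratio and confidence interval to log scale
#'
#' Recovers the log-odds point estimate and its standard error from a
#' printed odds ratio with a symmetric-on-log-scale confidence interval:
#' `beta = log(or)`, `se = (log(ci_high) - log(ci_low)) / (2 z)` with
#' `z = 1.96` at the default 95% level.
#'
#' @param or_point,ci_low,ci_high Positive odds-ratio point estimate and
#'   confidence bounds, `ci_low <= or_point <= ci_high`.
#' @param level Confidence level of the interval (default 0.95, which uses
#'   the conventional 1.96; other levels use the exact normal quantile).
#' @return A tibble with columns `beta` and `se`.
#' @export
or_ci_to_log <- function(or_point, ci_low, ci_high, level = 0.95) {
  if (any(or_point <= 0 | ci_low <= 0 | ci_high <= 0)) {
    abort("odds ratios and confidence bounds must be positive",
          class = "tidymr_domain_error")
  }
  if (any(ci_low > or_point | or_point > ci_high)) {
    abort("require ci_low <= or_point <= ci_high",
          class = "tidymr_domain_error")
  }
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1)",
                                      class = "tidymr_domain_error")
  z <- if (isTRUE(all.equal(level, 0.95))) Z95 else qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    beta = log(or_point),
    se = (log(ci_high) - log(ci_low)) / (2 * z)
  )
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools study estimates with the moment-based DerSimonian-Laird
#' between-study variance: with fixed-effect weights `w = se^-2` and
#' Cochran's `Q` over the studies,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; random-effects
#' weights are `1/(se^2 + tau2)` and the pooled estimate is their weighted
#' mean with standard error `1/sqrt(sum(w*))`. When `Q <= k-1` the
#' between-study variance truncates to zero and the result coincides with
#' fixed-effect pooling. Heterogeneity is always reported alongside,
#' never used to suppress pooling.
#'
#' @param estimates A tibble (or data frame) with columns `beta` and `se`,
#'   optionally `study`; at least two rows.
#' @return An object of class `mr_meta` with the pooled estimate, `tau2`,
#'   `q`, `q_df`, `q_pvalue`, and the per-study inputs. `tidy()` returns
#'   per-study rows plus the pooled row; `glance()` the one-row summary.
#' @export
meta_dl <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  k <- nrow(estimates)
  if (k < 2) {
    abort("meta-analysis needs at least two study estimates",
          class = "tidymr_degrees_of_freedom_error")
  }
  if (!all(c("beta", "se") %in% names(estimates))) {
    abort("estimates must have columns beta and se",
          class = "tidymr_domain_error")
  }
  if (!"study" %in% names(estimates)) {
    estimates$study <- paste0("study_", seq_len(k))
  }
  beta <- estimates$beta
  se <- estimates$se
  w <- se^-2
  m_fixed <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - m_fixed)^2)
  q_df <- k - 1L
  tau2 <- max(0, (q - q_df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  pooled_beta <- sum(w_star * beta) / sum(w_star)
  pooled_se <- sqrt(1 / sum(w_star))
  structure(
    list(
      pooled_beta = pooled_beta,
      pooled_se = pooled_se,
      ci_low = pooled_beta - Z95 * pooled_se,
      ci_high = pooled_beta + Z95 * pooled_se,
      pvalue = norm_pvalue(pooled_beta, pooled_se),
      tau2 = tau2,
      q = q,
      q_df = q_df,
      q_pvalue = pchisq(q, df = q_df, lower.tail = FALSE),
      study_estimates = estimates[, c("study", "beta", "se")]
    ),
    class = "mr_meta"
  )
}

#' @export
print.mr_meta <- function(x, ...) {
  cat("<mr_meta> DerSimonian-Laird random-effects,",
      nrow(x$study_estimates), "studies\n")
  cat(sprintf(
    "  pooled beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
    x$pooled_beta, x$pooled_se, x$ci_low, x$ci_high, x$pvalue
  ))
  cat(sprintf("  tau^2 = %.4g, Q = %.3f on %d df (p = %.3g)\n",
              x$tau2, x$q, x$q_df, x$q_pvalue))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_meta <- function(x, exponentiate = FALSE, ...) {
  out <- dplyr::bind_rows(
    x$study_estimates |>
      dplyr::mutate(
        conf.low = .data$beta - Z95 * .data$se,
        conf.high = .data$beta + Z95 * .data$se,
        pooled = FALSE
      ),
    tibble::tibble(
      study = "pooled", beta = x$pooled_beta, se = x$pooled_se,
      conf.low = x$ci_low, conf.high = x$ci_high, pooled = TRUE
    )
  ) |>
    dplyr::rename(estimate = "beta", std.error = "se")
  if (exponentiate) {
    out <- out |>
      dplyr::mutate(dplyr::across(c("estimate", "conf.low", "conf.high"),
                                  exp))
  }
  out
}

#' @exportS3Method generics::glance
glance.mr_meta <- function(x, ...) {
  tibble::tibble(
    pooled_beta = x$pooled_beta, pooled_se = x$pooled_se,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    tau2 = x$tau2, q = x$q, q_df = x$q_df, q_pvalue = x$q_pvalue,
    n_studies = nrow(x$study_estimates)
  )
}

#' Forest-plot data for a meta-analysis
#'
#' One row per study plus a pooled row, on the odds-ratio scale
#' (exp-transformed), in the layout used for forest-plot figures and their
#' tabular export.
#'
#' @param x An `mr_meta` object.
#' @param path Optional path; when given the table is written
#'   tab-separated.
#' @return A tibble with columns `study`, `or`, `ci_low`, `ci_high`,
#'   `pooled`.
#' @export
forest_data <- function(x, path = NULL) {
  stopifnot(inherits(x, "mr_meta"))
  tab <- tidy(x, exponentiate = TRUE) |>
    dplyr::select("study", or = "estimate", ci_low = "conf.low",
                  ci_high = "conf.high", "pooled")
  if (!is.null(path)) {
    readr::write_tsv(tab, path)
    return(invisible(tab))
  }
  tab
}

#' Forest plot of a meta-analysis
#'
#' @param object An `mr_meta` object.
#' @param exponentiate Plot on the odds-ratio scale (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_meta <- function(object, exponentiate = TRUE, ...) {
  dat <- tidy(object, exponentiate = exponentiate) |>
    dplyr::mutate(study = factor(.data$study,
                                 levels = rev(unique(.data$study))))
  ref <- if (exponentiate) 1 else 0
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$study)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled), size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::labs(
      x = if (exponentiate) "Odds ratio (95% CI)" else "Estimate (95% CI)",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
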