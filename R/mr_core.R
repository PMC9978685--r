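#' Per-variant Wald ratio
#'
#' The ratio estimate of the causal effect from a single instrument:
#' the variant-outcome effect divided by the variant-exposure effect.
#' The first-order (default) standard error is `se_Gamma / |gamma|`; the
#' second-order delta-method error additionally propagates the exposure-side
#' uncertainty: `sqrt(se_Gamma^2/gamma^2 + Gamma^2 se_gamma^2 / gamma^4)`.
#'
#' @param gamma,se_gamma Variant-exposure effect and its standard error.
#' @param Gamma,se_Gamma Variant-outcome effect and its standard error.
#' @param order `"first"` (default) or `"second"` standard-error formula.
#' @param variant_id Optional variant label(s).
#' @return A tibble with columns `variant_id`, `theta`, `se_theta`,
#'   `weight` (= `se_theta^-2`). Vectorized over its inputs.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       order = c("first", "second"),
                       variant_id = NULL) {
  order <- match.arg(order)
  if (any(gamma == 0)) {
    abort("gamma = 0: instrument has no exposure effect, Wald ratio undefined",
          class = "tidymr_weak_instrument_error")
  }
  if (any(se_gamma <= 0) || any(se_Gamma <= 0)) {
    abort("standard errors must be positive", class = "tidymr_domain_error")
  }
  theta <- Gamma / gamma
  se_theta <- switch(order,
    first = se_Gamma / abs(gamma),
    second = sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  )
  tibble::tibble(
    variant_id = variant_id %||% paste0("snp_", seq_along(theta)),
    theta = theta,
    se_theta = se_theta,
    weight = se_theta^-2
  )
}

#' Wald ratios for a harmonized instrument set
#'
#' @param h An `mr_harmonized` table from [harmonize_pair()], or any tibble
#'   with columns `variant_id`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @param order Standard-error order, as in [wald_ratio()].
#' @return A tibble of per-variant ratios (`variant_id`, `theta`,
#'   `se_theta`, `weight`).
#' @export
wald_ratios <- function(h, order = c("first", "second")) {
  wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome,
             order = match.arg(order), variant_id = h$variant_id)
}

as_ratio_tbl <- function(x, order = "first") {
  if (all(c("beta_exposure", "beta_outcome") %in% names(x))) {
    wald_ratios(x, order = order)
  } else if (all(c("theta", "se_theta") %in% names(x))) {
    x
  } else {
    abort("expected a harmonized instrument set or a Wald-ratio table",
          class = "tidymr_domain_error")
  }
}

#' Inverse-variance weighted causal estimate
#'
#' Combines per-variant Wald ratios by their inverse squared standard
#' errors: `beta = sum(w theta) / sum(w)` with `w = se_theta^-2`. Under the
#' fixed-effect model the standard error is `1/sqrt(sum(w))`; under the
#' multiplicative random-effects model it is inflated by
#' `max(1, sqrt(Q/(k-1)))` where `Q` is Cochran's heterogeneity statistic
#' over the ratios. `Q` and its chi-square p-value (k-1 degrees of freedom)
#' are attached whenever at least two instruments are present.
#'
#' @param ratios A Wald-ratio table (from [wald_ratios()]) or a harmonized
#'   instrument set, in which case first-order ratios are computed.
#' @param model `"fixed"` (default) or `"random"` (multiplicative).
#' @return An `mr_estimate` object; see [tidy.mr_estimate()].
#' @export
mr_ivw <- function(ratios, model = c("fixed", "random")) {
  model <- match.arg(model)
  r <- as_ratio_tbl(ratios)
  k <- nrow(r)
  if (k < 1) abort("at least one ratio is required",
                   class = "tidymr_estimation_error")
  w <- r$se_theta^-2
  beta <- sum(w * r$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- NA_real_
  q_p <- NA_real_
  if (k >= 2) {
    q <- sum(w * (r$theta - beta)^2)
    q_p <- pchisq(q, df = k - 1, lower.tail = FALSE)
    if (model == "random") se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate(
    method = if (model == "fixed") "ivw_fixed" else "ivw_random",
    beta = beta, se = se, n_snps = k, q = q, q_pvalue = q_p
  )
}

#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of a set of estimates from their
#' fixed-effect pooled mean, with weights equal to inverse squared standard
#' errors; chi-square distributed with k-1 degrees of freedom under
#' homogeneity.
#'
#' @param beta,se Numeric vectors of estimates and standard errors (at
#'   least two).
#' @return A tibble with columns `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(beta, se) {
  if (length(beta) < 2) {
    abort("Cochran's Q needs at least two estimates",
          class = "tidymr_degrees_of_freedom_error")
  }
  w <- se^-2
  m <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - m)^2)
  df <- length(beta) - 1L
  tibble::tibble(q = q, df = df,
                 pvalue = pchisq(q, df = df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the variant-outcome effects on the
#' variant-exposure effects with an intercept, weights `1/se_outcome^2`,
#' after orienting every instrument so its exposure effect is non-negative
#' (flipping both signs together). The slope estimates the causal effect;
#' the intercept estimates average directional pleiotropy. Standard errors
#' come from the weighted regression with the residual standard deviation
#' bounded below by 1, so they are never smaller than the fixed-effect
#' (known-error) standard errors.
#'
#' @param h A harmonized instrument set with at least three instruments.
#' @param t_dist Use t-distribution (k-2 df) p-values and CIs instead of
#'   the default normal rule.
#' @return An object of class `mr_egger_fit` with elements `slope` and
#'   `intercept`, both `mr_estimate`s; `tidy()` returns both as rows.
#' @export
mr_egger <- function(h, t_dist = FALSE) {
  k <- nrow(h)
  if (k < 3) {
    abort(paste0(
      "MR-Egger requires at least three instruments (", k, " supplied)"
    ), class = "tidymr_instrument_count_error")
  }
  sgn <- ifelse(h$beta_exposure < 0, -1, 1)
  x <- h$beta_exposure * sgn
  y <- h$beta_outcome * sgn
  w <- h$se_outcome^-2

  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  # residual SD under weights 1/se^2 has expectation 1 when the model holds
  # and the reported SEs are correct; bound below by 1 so over-dispersion
  # inflates the SEs but under-dispersion never shrinks them
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / (k - 2))
  design <- cbind(1, x)
  xtx_inv <- solve(crossprod(design, w * design))
  ses <- unname(max(1, sigma) * sqrt(diag(xtx_inv)))

  crit <- if (t_dist) stats::qt(0.975, df = k - 2) else Z95
  pfun <- function(b, s) {
    if (t_dist) 2 * stats::pt(-abs(b / s), df = k - 2) else norm_pvalue(b, s)
  }
  mk <- function(method, b, s) {
    est <- new_mr_estimate(method, b, s, n_snps = k)
    est$ci_low <- b - crit * s
    est$ci_high <- b + crit * s
    est$pvalue <- pfun(b, s)
    est
  }
  structure(
    list(
      slope = mk("egger_slope", unname(cf[2]), ses[2]),
      intercept = mk("egger_intercept", unname(cf[1]), ses[1]),
      residual_sd = sigma
    ),
    class = "mr_egger_fit"
  )
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat("<mr_egger_fit>\n")
  print(x$slope)
  print(x$intercept)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_egger_fit <- function(x, ...) {
  dplyr::bind_rows(tidy(x$slope), tidy(x$intercept))
}

#' @exportS3Method generics::glance
glance.mr_egger_fit <- function(x, ...) {
  tibble::tibble(n_snps = x$slope$n_snps, residual_sd = x$residual_sd)
}

# weighted-median point estimate: cumulative-midpoint interpolation at 0.5
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  wn <- w[o] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (p[1] >= 0.5) return(theta[1])
  k <- length(theta)
  if (p[k] <= 0.5) return(theta[k])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

# parametric-bootstrap SE shared by the median and mode estimators:
# resample each ratio from Normal(theta_j, se_j), recompute, take the SD
ratio_bootstrap_se <- function(theta, se, w, n_boot, seed, point_fun) {
  withr::with_seed(seed, {
    k <- length(theta)
    draws <- matrix(rnorm(k * n_boot, mean = theta, sd = se), nrow = k)
    ests <- vapply(seq_len(n_boot), function(j) point_fun(draws[, j], w),
                   numeric(1))
    sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' Orders the Wald ratios, forms cumulative weight midpoints, and linearly
#' interpolates the ratio at cumulative weight 0.5. Consistent when valid
#' instruments carry more than half of the total weight. The standard error
#' is obtained by parametric bootstrap: each ratio is resampled from a
#' normal distribution with its own standard error, the weighted median is
#' recomputed, and the standard deviation across replicates is taken.
#'
#' @param ratios A Wald-ratio table or harmonized instrument set (at least
#'   three instruments).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required for
#'   reproducibility).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = 1) {
  if (n_boot < 1) abort("n_boot must be positive",
                        class = "tidymr_config_error")
  r <- as_ratio_tbl(ratios)
  if (nrow(r) < 3) {
    abort("weighted median requires at least three instruments",
          class = "tidymr_instrument_count_error")
  }
  w <- r$se_theta^-2
  beta <- weighted_median_point(r$theta, w)
  se <- ratio_bootstrap_se(r$theta, r$se_theta, w, n_boot, seed,
                           weighted_median_point)
  new_mr_estimate("weighted_median", beta, se, n_snps = nrow(r))
}

# modified Silverman bandwidth on the ratios
silverman_bw <- function(theta) {
  k <- length(theta)
  s <- sd(theta)
  iqr <- stats::IQR(theta) / 1.349
  spread <- min(s, if (iqr > 0) iqr else s)
  0.9 * spread * k^(-1 / 5)
}

# weighted normal-kernel density argmax over a grid
weighted_mode_point <- function(theta, w, bandwidth_factor = 1,
                                grid_n = 512) {
  if (diff(range(theta)) == 0) return(theta[1])
  h <- bandwidth_factor * silverman_bw(theta)
  if (h <= 0) {
    abort("degenerate density: zero spread and zero bandwidth",
          class = "tidymr_degenerate_density_error")
  }
  wn <- w / sum(w)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = grid_n)
  dens <- vapply(grid,
                 function(x) sum(wn * stats::dnorm((x - theta) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode causal estimate
#'
#' Takes the mode of a weighted normal-kernel density over the Wald ratios
#' (weights proportional to inverse-variance weights), with bandwidth equal
#' to `bandwidth_factor` times a modified Silverman rule on the ratios, the
#' argmax located on a 512-point grid spanning the ratio range extended by
#' three bandwidths. Consistent when the largest cluster of instruments is
#' valid. Standard error by the same parametric bootstrap as
#' [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the Silverman bandwidth
#'   (default 1).
#' @param grid_n Number of grid points for the density scan (default 512).
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(ratios, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1, grid_n = 512) {
  if (n_boot < 1) abort("n_boot must be positive",
                        class = "tidymr_config_error")
  if (bandwidth_factor <= 0) abort("bandwidth_factor must be positive",
                                   class = "tidymr_config_error")
  r <- as_ratio_tbl(ratios)
  if (nrow(r) < 3) {
    abort("weighted mode requires at least three instruments",
          class = "tidymr_instrument_count_error")
  }
  w <- r$se_theta^-2
  point <- function(theta, w) {
    weighted_mode_point(theta, w, bandwidth_factor, grid_n)
  }
  beta <- point(r$theta, w)
  se <- ratio_bootstrap_se(r$theta, r$se_theta, w, n_boot, seed, point)
  new_mr_estimate("weighted_mode", beta, se, n_snps = nrow(r))
}

#' Classify p-values against a Bonferroni-corrected threshold
#'
#' With threshold `t = alpha / n_outcomes`: p-values below `t` are
#' `"significant"`, p-values in `[t, alpha)` are `"suggestive"`, and
#' everything at or above `alpha` is `"null"` (strict inequalities at both
#' boundaries' lower ends).
#'
#' @param pvalue Numeric vector of p-values.
#' @param n_outcomes Number of outcomes tested (default 8).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A character vector in `{"significant", "suggestive", "null"}`.
#' @export
classify_significance <- function(pvalue, n_outcomes = 8, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)",
                                      class = "tidymr_config_error")
  if (n_outcomes < 1) abort("n_outcomes must be positive",
                            class = "tidymr_config_error")
  threshold <- alpha / n_outcomes
  dplyr::case_when(
    pvalue < threshold ~ "significant",
    pvalue < alpha ~ "suggestive",
    .default = "null"
  )
}

#' Export MR estimates as a tab-separated table
#'
#' @param estimates A list of `mr_estimate` objects (or a single one).
#' @param path Output path; when `NULL` the tibble is returned without
#'   writing.
#' @param outcome Outcome label attached to every row.
#' @param n_outcomes,alpha Passed to [classify_significance()].
#' @return The exported tibble, invisibly when written.
#' @export
export_estimates <- function(estimates, path = NULL, outcome = NA_character_,
                             n_outcomes = 8, alpha = 0.05) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  tab <- purrr::map_dfr(estimates, function(e) {
    tibble::tibble(
      outcome = outcome, method = e$method, n_snps = e$n_snps,
      beta = e$beta, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
      pvalue = e$pvalue, q = e$q, q_pvalue = e$q_pvalue,
      significance = classify_significance(e$pvalue, n_outcomes, alpha)
    )
  })
  if (!is.null(path)) {
    readr::write_tsv(tab, path)
    return(invisible(tab))
  }
  tab
}
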