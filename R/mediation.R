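new_mediation_result <- function(total, step1, step2, indirect_se = NA_real_,
                                 proportion_ci = c(NA_real_, NA_real_),
                                 n_boot = NA_integer_, seed = NA_integer_,
                                 n_rejected = 0L) {
  indirect <- step1$beta * step2$beta
  proportion <- if (total$beta != 0) indirect / total$beta else NA_real_
  structure(
    list(
      total = total, step1 = step1, step2 = step2,
      indirect_beta = indirect, indirect_se = indirect_se,
      proportion_mediated = proportion, proportion_ci = proportion_ci,
      n_boot = n_boot, seed = seed, n_rejected = n_rejected
    ),
    class = "mr_mediation"
  )
}

check_leg <- function(leg, name) {
  if (!is.list(leg) || !all(c("beta", "se") %in% names(leg))) {
    abort(paste0(name, " must be a list with elements beta and se"),
          class = "tidymr_domain_error")
  }
  if (leg$se < 0) abort(paste0(name, " must have a nonnegative se"),
                        class = "tidymr_domain_error")
  leg[c("beta", "se")]
}

#' Two-step network MR mediation (point estimates)
#'
#' Decomposes a total exposure-outcome causal effect into a mediated
#' component, the product of the exposure-mediator effect (step 1) and the
#' mediator-outcome effect (step 2), and reports the proportion mediated
#' `indirect / total`. All effects stay on the scale of their inputs
#' (log-odds for binary outcome legs, SD units for continuous legs).
#'
#' @param total,step1,step2 Each a list with elements `beta` and `se`:
#'   the exposure-outcome, exposure-mediator and mediator-outcome
#'   estimates.
#' @return An `mr_mediation` object (no bootstrap uncertainty; see
#'   [bootstrap_mediation()]). When `total$beta` is zero the proportion is
#'   `NA` with a warning; the indirect effect is still returned.
#' @export
two_step_mediation <- function(total, step1, step2) {
  total <- check_leg(total, "total")
  step1 <- check_leg(step1, "step1")
  step2 <- check_leg(step2, "step2")
  if (total$beta == 0) {
    warn("total effect is zero: proportion mediated is undefined (NA)")
  }
  new_mediation_result(total, step1, step2)
}

#' Two-step mediation with parametric bootstrap uncertainty
#'
#' Per iteration, each of the three effect estimates is drawn independently
#' from a normal distribution centred at its point estimate with its
#' standard error (the three legs come from non-overlapping two-sample
#' contributions, so independence is the working assumption); the indirect
#' effect and proportion mediated are recomputed. The indirect-effect
#' standard error is the standard deviation of the indirect draws; the
#' proportion interval is the 2.5th/97.5th percentile of the proportion
#' draws (a normal-approximation interval is available via
#' `ci_type = "normal"`). Draws with `|total| < 1e-10` would make the
#' proportion unstable and are rejected and redrawn; the count is recorded
#' in `n_rejected`.
#'
#' @inheritParams two_step_mediation
#' @param n_boot Number of bootstrap iterations (default 100000).
#' @param seed Integer seed; identical seeds give identical results.
#' @param ci_type `"percentile"` (default) or `"normal"` interval for the
#'   proportion mediated.
#' @return An `mr_mediation` object with `indirect_se`, `proportion_ci`,
#'   `n_boot`, `seed`, `n_rejected` filled in.
#' @export
bootstrap_mediation <- function(total, step1, step2, n_boot = 100000,
                                seed = 1,
                                ci_type = c("percentile", "normal")) {
  ci_type <- match.arg(ci_type)
  if (n_boot < 1) abort("n_boot must be positive",
                        class = "tidymr_config_error")
  res <- two_step_mediation(total, step1, step2)
  total <- res$total
  step1 <- res$step1
  step2 <- res$step2

  draws <- withr::with_seed(seed, {
    t_draw <- rnorm(n_boot, total$beta, total$se)
    b1_draw <- rnorm(n_boot, step1$beta, step1$se)
    b2_draw <- rnorm(n_boot, step2$beta, step2$se)
    n_rejected <- 0L
    repeat {
      bad <- which(abs(t_draw) < 1e-10)
      if (length(bad) == 0) break
      n_rejected <- n_rejected + length(bad)
      t_draw[bad] <- rnorm(length(bad), total$beta, total$se)
    }
    list(indirect = b1_draw * b2_draw,
         proportion = (b1_draw * b2_draw) / t_draw,
         n_rejected = n_rejected)
  })

  res$indirect_se <- sd(draws$indirect)
  res$proportion_ci <- if (ci_type == "percentile") {
    unname(quantile(draws$proportion, c(0.025, 0.975)))
  } else {
    p_hat <- res$proportion_mediated
    p_se <- sd(draws$proportion)
    c(p_hat - Z95 * p_se, p_hat + Z95 * p_se)
  }
  res$n_boot <- as.integer(n_boot)
  res$seed <- as.integer(seed)
  res$n_rejected <- draws$n_rejected
  res
}

#' Mediator-outcome effect by weighted median
#'
#' The pipeline's default step-2 (mediator to outcome) estimator: the
#' weighted median over the mediator's instrument set, chosen for its
#' robustness to pleiotropy among the typically numerous mediator
#' instruments when inverse-variance weighting shows heterogeneity.
#'
#' @param instruments A harmonized mediator-outcome instrument set (at
#'   least three instruments).
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
estimate_step2_weighted_median <- function(instruments, n_boot = 1000,
                                           seed = 1) {
  mr_weighted_median(instruments, n_boot = n_boot, seed = seed)
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("<mr_mediation> two-step network MR\n")
  cat(sprintf("  total    beta = %.4f (SE %.4f)\n", x$total$beta, x$total$se))
  cat(sprintf("  step 1   beta = %.4f (SE %.4f)  exposure -> mediator\n",
              x$step1$beta, x$step1$se))
  cat(sprintf("  step 2   beta = %.4f (SE %.4f)  mediator -> outcome\n",
              x$step2$beta, x$step2$se))
  cat(sprintf("  indirect beta = %.4f%s\n", x$indirect_beta,
              if (is.na(x$indirect_se)) "" else
                sprintf(" (SE %.4f)", x$indirect_se)))
  if (!is.na(x$proportion_mediated)) {
    ci <- if (all(is.na(x$proportion_ci))) "" else
      sprintf(" (95%% CI %.1f%% to %.1f%%)",
              100 * x$proportion_ci[1], 100 * x$proportion_ci[2])
    cat(sprintf("  proportion mediated = %.1f%%%s\n",
                100 * x$proportion_mediated, ci))
  }
  if (!is.na(x$n_boot)) {
    cat(sprintf("  bootstrap: %d iterations, seed %d, %d rejected draws\n",
                x$n_boot, x$seed, x$n_rejected))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_mediation <- function(x, ...) {
  tibble::tibble(
    term = c("total", "step1", "step2", "indirect", "proportion_mediated"),
    estimate = c(x$total$beta, x$step1$beta, x$step2$beta, x$indirect_beta,
                 x$proportion_mediated),
    std.error = c(x$total$se, x$step1$se, x$step2$se, x$indirect_se,
                  NA_real_),
    conf.low = c(rep(NA_real_, 4), x$proportion_ci[1]),
    conf.high = c(rep(NA_real_, 4), x$proportion_ci[2])
  )
}

#' @exportS3Method generics::glance
glance.mr_mediation <- function(x, ...) {
  tibble::tibble(
    indirect_beta = x$indirect_beta, indirect_se = x$indirect_se,
    proportion_mediated = x$proportion_mediated,
    proportion_ci_low = x$proportion_ci[1],
    proportion_ci_high = x$proportion_ci[2],
    n_boot = x$n_boot, seed = x$seed, n_rejected = x$n_rejected
  )
}

#' Export a mediation report table
#'
#' A small table mirroring the usual mediation-figure layout: the total
#' effect, the mediated (indirect) effect, and the proportion mediated,
#' with available intervals, on both the log-odds and odds-ratio scales
#' for the outcome legs.
#'
#' @param x An `mr_mediation` object.
#' @param path Optional path for a tab-separated export.
#' @return A tibble.
#' @export
mediation_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "mr_mediation"))
  tab <- tibble::tibble(
    quantity = c("total effect", "mediated effect", "proportion mediated"),
    beta = c(x$total$beta, x$indirect_beta, x$proportion_mediated),
    se = c(x$total$se, x$indirect_se, NA_real_),
    or = c(exp(x$total$beta), exp(x$indirect_beta), NA_real_),
    ci_low = c(rep(NA_real_, 2), x$proportion_ci[1]),
    ci_high = c(rep(NA_real_, 2), x$proportion_ci[2])
  )
  if (!is.null(path)) {
    readr::write_tsv(tab, path)
    return(invisible(tab))
  }
  tab
}
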