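#' Simulation configuration for two-sample summary statistics
#'
#' Defines the generating model for synthetic GWAS summary statistics: true
#' instrument-exposure effects are drawn from a normal distribution, the
#' observed exposure and outcome associations are the true values plus
#' independent estimation noise, and the outcome association of variant `j`
#' is `theta * gamma_j + alpha_j` where `alpha_j` is an optional pleiotropic
#' effect drawn independently of `gamma_j` (so the InSIDE condition holds by
#' construction). The generic defaults describe a well-powered exposure GWAS
#' (mean per-allele effect 0.15 SD with reported SE 0.005, instrument F
#' around 900), the strong-instrument regime in which the first-order Wald
#' standard errors the estimators report are well calibrated; see
#' [sim_config_caffeine()] for a two-instrument preset with
#' moderate-strength instruments (F around 80) matching a caffeine-scale
#' exposure GWAS, where first-order intervals undercover slightly.
#'
#' @param n_snps Number of instruments (default 2).
#' @param gamma_mean,gamma_sd Mean and SD of the true instrument-exposure
#'   effects, SD units per effect allele (defaults 0.15 and 0.03).
#' @param se_gamma Exposure-side estimation noise / reported SE
#'   (default 0.005).
#' @param se_Gamma Outcome-side estimation noise / reported SE
#'   (default 0.01, log-odds scale for binary outcomes).
#' @param theta True causal effect of exposure on outcome (default 0).
#' @param pleiotropy One of `"none"`, `"balanced"` (zero-mean direct
#'   effects) or `"directional"` (mean `pleiotropy_mag`, SD
#'   `pleiotropy_mag / 2`).
#' @param pleiotropy_mag Pleiotropy magnitude: the SD of balanced effects or
#'   the mean of directional effects.
#' @param pleiotropy_frac Fraction of instruments carrying a pleiotropic
#'   effect (default 1 when pleiotropy is not `"none"`).
#' @param eaf_range Range from which effect-allele frequencies are drawn
#'   uniformly (default 0.1-0.9).
#' @param n_exposure,n_outcome Study sample sizes written into the tables.
#' @param flip_fraction Fraction of outcome rows emitted with swapped
#'   alleles (beta negated, frequency complemented) so that harmonization
#'   is exercised (default 0.3).
#' @param mediation Optional mediation block, a list with `beta1`
#'   (exposure to mediator), `beta2` (mediator to outcome), `direct`
#'   (unmediated exposure-outcome effect), and optionally `n_snps_mediator`
#'   (default 483), `mediator_gamma_mean`/`mediator_gamma_sd` (instrument
#'   strengths for the mediator GWAS, defaults 0.025/0.008),
#'   `se_mediator_instrument` (default 0.003), `se_mediator` (noise on the
#'   exposure-instrument to mediator associations, default 0.002) and
#'   `se_outcome_mediator` (noise on the mediator-instrument to outcome
#'   associations, default 0.015).
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2,
                       gamma_mean = 0.15, gamma_sd = 0.03,
                       se_gamma = 0.005, se_Gamma = 0.01,
                       theta = 0,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mag = 0, pleiotropy_frac = 1,
                       eaf_range = c(0.1, 0.9),
                       n_exposure = 10000, n_outcome = 300000,
                       flip_fraction = 0.3,
                       mediation = NULL,
                       seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  if (n_snps < 1) abort("n_snps must be at least 1",
                        class = "tidymr_config_error")
  if (se_gamma <= 0 || se_Gamma <= 0 || gamma_sd < 0) {
    abort("noise scales must be positive", class = "tidymr_config_error")
  }
  if (pleiotropy != "none" && pleiotropy_mag <= 0) {
    abort("pleiotropy_mag must be positive when pleiotropy is requested",
          class = "tidymr_config_error")
  }
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    abort("pleiotropy_frac must lie in [0, 1]",
          class = "tidymr_config_error")
  }
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] >= eaf_range[2]) {
    abort("eaf_range must be an increasing pair inside (0, 1)",
          class = "tidymr_config_error")
  }
  if (flip_fraction < 0 || flip_fraction > 1) {
    abort("flip_fraction must lie in [0, 1]", class = "tidymr_config_error")
  }
  if (!is.null(mediation)) {
    if (!all(c("beta1", "beta2", "direct") %in% names(mediation))) {
      abort("mediation block needs beta1, beta2 and direct",
            class = "tidymr_config_error")
    }
    defaults <- list(
      n_snps_mediator = 483,
      mediator_gamma_mean = 0.025, mediator_gamma_sd = 0.008,
      se_mediator_instrument = 0.003,
      se_mediator = 0.002, se_outcome_mediator = 0.015
    )
    mediation <- utils::modifyList(defaults, mediation)
  }
  structure(
    list(
      n_snps = as.integer(n_snps),
      gamma_mean = gamma_mean, gamma_sd = gamma_sd,
      se_gamma = se_gamma, se_Gamma = se_Gamma,
      theta = theta,
      pleiotropy = pleiotropy, pleiotropy_mag = pleiotropy_mag,
      pleiotropy_frac = pleiotropy_frac,
      eaf_range = eaf_range,
      n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
      flip_fraction = flip_fraction,
      mediation = mediation,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Caffeine-like simulation preset
#'
#' Two moderate-strength instruments (mean per-allele effect 0.14 SD with
#' reported SE 0.016, instrument F around 80, as for variants regulating a
#' plasma metabolite measured in ~10,000 individuals) for a continuous
#' exposure in SD units; a large binary-outcome GWAS on the log-odds scale
#' with a protective causal effect (`theta = log(0.81)`); and a mediation
#' block in which the exposure lowers the mediator (`beta1 = -0.08` SD),
#' the mediator raises outcome risk (`beta2 = 1.18` log-odds per mediator
#' SD), and the direct effect makes up the remainder of the total.
#'
#' @param seed Integer seed.
#' @param theta Total causal effect (default `log(0.81)`).
#' @return A `sim_config`.
#' @export
sim_config_caffeine <- function(seed = 1, theta = log(0.81)) {
  beta1 <- -0.08
  beta2 <- 1.18
  sim_config(
    n_snps = 2, gamma_mean = 0.14, gamma_sd = 0.03,
    se_gamma = 0.016, se_Gamma = 0.01,
    theta = theta,
    mediation = list(beta1 = beta1, beta2 = beta2,
                     direct = theta - beta1 * beta2),
    seed = seed
  )
}

# reported p-values can underflow to 0 at GWAS-scale z statistics; floor at
# the smallest normalized double so emitted tables satisfy p in (0, 1]
reported_pvalue <- function(beta, se) {
  pmax(norm_pvalue(beta, se), .Machine$double.xmin)
}

NONPALINDROMIC_PAIRS <- {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  pairs[ALLELE_COMPLEMENT[pairs$ea] != pairs$oa, ]
}

# true per-variant quantities shared by every table a variant appears in;
# alleles are sampled from non-palindromic pairs so harmonization never
# discards simulated instruments for frequency ambiguity
draw_instrument_truth <- function(n_snps, gamma_mean, gamma_sd, eaf_range,
                                  id_prefix = "rs1") {
  idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), n_snps, replace = TRUE)
  tibble::tibble(
    variant_id = sprintf("%s%06d", id_prefix, seq_len(n_snps)),
    effect_allele = NONPALINDROMIC_PAIRS$ea[idx],
    other_allele = NONPALINDROMIC_PAIRS$oa[idx],
    eaf = runif(n_snps, eaf_range[1], eaf_range[2]),
    gamma_true = rnorm(n_snps, gamma_mean, gamma_sd)
  )
}

observe_exposure <- function(truth, se_gamma, n_sample) {
  beta <- truth$gamma_true + rnorm(nrow(truth), 0, se_gamma)
  tibble::tibble(
    variant_id = truth$variant_id,
    effect_allele = truth$effect_allele,
    other_allele = truth$other_allele,
    eaf = truth$eaf,
    beta = beta,
    se = se_gamma,
    pvalue = reported_pvalue(beta, se_gamma),
    n = n_sample,
    z = beta / se_gamma,
    locus = truth$variant_id
  )
}

draw_pleiotropy <- function(n_snps, type, mag, frac) {
  alpha <- numeric(n_snps)
  if (type == "none" || frac == 0) return(alpha)
  n_pleio <- round(frac * n_snps)
  which_pleio <- if (n_pleio >= n_snps) seq_len(n_snps) else
    sample.int(n_snps, n_pleio)
  alpha[which_pleio] <- switch(type,
    balanced = rnorm(n_pleio, 0, mag),
    directional = rnorm(n_pleio, mag, mag / 2)
  )
  alpha
}

observe_outcome <- function(truth, theta, se_Gamma, n_sample,
                            pleiotropy, pleiotropy_mag, pleiotropy_frac,
                            flip_fraction) {
  n_snps <- nrow(truth)
  alpha <- draw_pleiotropy(n_snps, pleiotropy, pleiotropy_mag,
                           pleiotropy_frac)
  beta <- theta * truth$gamma_true + alpha + rnorm(n_snps, 0, se_Gamma)
  flip <- runif(n_snps) < flip_fraction
  beta_reported <- ifelse(flip, -beta, beta)
  tbl <- tibble::tibble(
    variant_id = truth$variant_id,
    effect_allele = ifelse(flip, truth$other_allele, truth$effect_allele),
    other_allele = ifelse(flip, truth$effect_allele, truth$other_allele),
    eaf = ifelse(flip, 1 - truth$eaf, truth$eaf),
    beta = beta_reported,
    se = se_Gamma,
    pvalue = reported_pvalue(beta_reported, se_Gamma),
    n = n_sample,
    z = beta_reported / se_Gamma,
    locus = truth$variant_id
  )
  attr(tbl, "alpha") <- alpha
  tbl
}

#' Simulate a two-sample summary-statistic pair
#'
#' Generates one exposure and one outcome association table under the
#' generating model of [sim_config()]. The two studies are given
#' independent seeded noise streams (derived from `config$seed`), matching
#' the non-overlapping-samples assumption of the two-sample design;
#' identical configurations yield byte-identical tables.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (tibbles in the
#'   standard association format) and `truth` (a tibble with the true
#'   per-variant effects and pleiotropy, plus attributes carrying the
#'   generating `theta`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- withr::with_seed(config$seed, {
    draw_instrument_truth(config$n_snps, config$gamma_mean, config$gamma_sd,
                          config$eaf_range)
  })
  exposure <- withr::with_seed(config$seed + 1L, {
    observe_exposure(truth, config$se_gamma, config$n_exposure)
  })
  outcome <- withr::with_seed(config$seed + 2L, {
    observe_outcome(truth, config$theta, config$se_Gamma, config$n_outcome,
                    config$pleiotropy, config$pleiotropy_mag,
                    config$pleiotropy_frac, config$flip_fraction)
  })
  truth$alpha <- attr(outcome, "alpha")
  attr(outcome, "alpha") <- NULL
  attr(truth, "theta") <- config$theta
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate one exposure against several outcome studies
#'
#' Shares a single set of instrument truths and one observed exposure table
#' across several outcome tables, each with its own causal effect and its
#' own noise stream — the layout of a multi-outcome two-sample MR study.
#'
#' @param config A [sim_config()]; its `theta` is ignored in favour of
#'   `outcome_thetas`.
#' @param outcome_thetas Named numeric vector of true causal effects, one
#'   per outcome study.
#' @return A list with `exposure` (tibble), `outcomes` (named list of
#'   tibbles) and `truth`.
#' @export
simulate_study <- function(config, outcome_thetas) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(outcome_thetas)) || any(names(outcome_thetas) == "")) {
    abort("outcome_thetas must be a named vector",
          class = "tidymr_config_error")
  }
  truth <- withr::with_seed(config$seed, {
    draw_instrument_truth(config$n_snps, config$gamma_mean, config$gamma_sd,
                          config$eaf_range)
  })
  exposure <- withr::with_seed(config$seed + 1L, {
    observe_exposure(truth, config$se_gamma, config$n_exposure)
  })
  outcomes <- purrr::imap(
    as.list(outcome_thetas),
    function(theta, nm) {
      offset <- 2L + match(nm, names(outcome_thetas))
      out <- withr::with_seed(config$seed + offset, {
        observe_outcome(truth, theta, config$se_Gamma, config$n_outcome,
                        config$pleiotropy, config$pleiotropy_mag,
                        config$pleiotropy_frac, config$flip_fraction)
      })
      attr(out, "alpha") <- NULL
      out
    }
  )
  list(exposure = exposure, outcomes = outcomes, truth = truth)
}

#' Simulate a mediation network of summary statistics
#'
#' Emits three internally consistent two-sample table pairs under the
#' causal chain exposure -> mediator -> outcome plus a direct
#' exposure -> outcome path: the exposure instruments' mediator
#' associations encode `beta1`, the mediator instruments' outcome
#' associations encode `beta2`, and the exposure instruments' outcome
#' associations encode the total effect `beta1 * beta2 + direct`. Each leg
#' has its own noise stream, so the three estimated legs have independent
#' errors, matching the bootstrap's independence assumption.
#'
#' @param config A [sim_config()] with a `mediation` block.
#' @return A list with elements `exposure_mediator`, `mediator_outcome`,
#'   `exposure_outcome` (each a list of `exposure` and `outcome` tibbles)
#'   and `truth` (beta1, beta2, direct, total, proportion_mediated).
#' @export
simulate_mediation_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  med <- config$mediation
  if (is.null(med)) {
    abort("config$mediation must be set for a mediation network",
          class = "tidymr_config_error")
  }
  total <- med$beta1 * med$beta2 + med$direct
  seed <- config$seed

  truth_x <- withr::with_seed(seed, {
    draw_instrument_truth(config$n_snps, config$gamma_mean, config$gamma_sd,
                          config$eaf_range, id_prefix = "rs1")
  })
  exposure_a <- withr::with_seed(seed + 1L, {
    observe_exposure(truth_x, config$se_gamma, config$n_exposure)
  })
  mediator_a <- withr::with_seed(seed + 2L, {
    observe_outcome(truth_x, med$beta1, med$se_mediator, config$n_outcome,
                    "none", 0, 0, config$flip_fraction)
  })
  exposure_c <- withr::with_seed(seed + 3L, {
    observe_exposure(truth_x, config$se_gamma, config$n_exposure)
  })
  outcome_c <- withr::with_seed(seed + 4L, {
    observe_outcome(truth_x, total, config$se_Gamma, config$n_outcome,
                    config$pleiotropy, config$pleiotropy_mag,
                    config$pleiotropy_frac, config$flip_fraction)
  })
  truth_m <- withr::with_seed(seed + 5L, {
    draw_instrument_truth(med$n_snps_mediator, med$mediator_gamma_mean,
                          med$mediator_gamma_sd, config$eaf_range,
                          id_prefix = "rs2")
  })
  mediator_b <- withr::with_seed(seed + 6L, {
    observe_exposure(truth_m, med$se_mediator_instrument, config$n_outcome)
  })
  outcome_b <- withr::with_seed(seed + 7L, {
    observe_outcome(truth_m, med$beta2, med$se_outcome_mediator,
                    config$n_outcome,
                    config$pleiotropy, config$pleiotropy_mag,
                    config$pleiotropy_frac, config$flip_fraction)
  })

  attr(mediator_a, "alpha") <- NULL
  attr(outcome_c, "alpha") <- NULL
  attr(outcome_b, "alpha") <- NULL
  list(
    exposure_mediator = list(exposure = exposure_a, outcome = mediator_a),
    mediator_outcome = list(exposure = mediator_b, outcome = outcome_b),
    exposure_outcome = list(exposure = exposure_c, outcome = outcome_c),
    truth = list(
      beta1 = med$beta1, beta2 = med$beta2, direct = med$direct,
      total = total, proportion_mediated = med$beta1 * med$beta2 / total
    )
  )
}

#' Write simulated tables in the standard summary-statistic format
#'
#' @param tables A named list of tibbles (e.g. the `exposure`/`outcome`
#'   elements of [simulate_two_sample()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tbl, nm) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, path)
    path
  })
  invisible(paths)
}
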