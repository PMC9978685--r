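test_that("wald_ratio matches the delta-method formulas", {
  # null numerator
  r0 <- wald_ratio(0.2, 0.02, 0, 0.01)
  expect_equal(r0$theta, 0)
  expect_equal(r0$se_theta, 0.01 / 0.2)

  # first order
  r1 <- wald_ratio(0.2, 0.02, -0.04, 0.01)
  expect_equal(r1$theta, -0.2)
  expect_equal(r1$se_theta, 0.05)
  expect_equal(r1$weight, r1$se_theta^-2)

  # second order, against a direct evaluation of the formula
  r2 <- wald_ratio(0.2, 0.02, -0.04, 0.01, order = "second")
  oracle <- sqrt(0.01^2 / 0.2^2 + (-0.04)^2 * 0.02^2 / 0.2^4)
  expect_equal(r2$se_theta, oracle)
  expect_equal(r2$se_theta, 0.05385, tolerance = 1e-4)

  # zero exposure effect is a weak-instrument error, not a ratio
  expect_error(wald_ratio(0, 0.02, 0.1, 0.01),
               class = "tidymr_weak_instrument_error")
})

test_that("mr_ivw is the inverse-variance weighted mean with correct SE and Q", {
  one <- wald_ratio(0.2, 0.02, -0.04, 0.01)
  e1 <- mr_ivw(one)
  expect_equal(e1$beta, one$theta)
  expect_equal(e1$se, one$se_theta)
  expect_equal(e1$n_snps, 1L)
  expect_true(is.na(e1$q))

  sym <- tibble::tibble(variant_id = c("a", "b"), theta = c(-0.2, -0.1),
                        se_theta = c(0.05, 0.05), weight = 400)
  e2 <- mr_ivw(sym)
  expect_equal(e2$beta, -0.15)
  expect_equal(e2$se, 0.05 / sqrt(2))

  asym <- tibble::tibble(variant_id = c("a", "b"), theta = c(-0.2, -0.1),
                         se_theta = c(0.05, 0.1), weight = c(400, 100))
  e3 <- mr_ivw(asym)
  expect_equal(e3$beta, -0.18)
  expect_equal(e3$se, 1 / sqrt(500))
  expect_equal(e3$q, 400 * (-0.02)^2 + 100 * (0.08)^2)
  expect_equal(e3$q_pvalue, pchisq(e3$q, 1, lower.tail = FALSE))

  # multiplicative random-effects inflates the SE by max(1, sqrt(Q/(k-1)))
  e4 <- mr_ivw(asym, model = "random")
  expect_equal(e4$se, e3$se * max(1, sqrt(e3$q / 1)))
  # and never deflates it under low heterogeneity
  low <- tibble::tibble(theta = c(0.1, 0.1001), se_theta = c(0.05, 0.05))
  expect_equal(mr_ivw(low, model = "random")$se, mr_ivw(low)$se)

  expect_error(mr_ivw(tibble::tibble(theta = numeric(),
                                     se_theta = numeric())),
               class = "tidymr_estimation_error")
})

test_that("fixed-effect IVW equals weighted through-origin regression", {
  withr::with_seed(101, {
    for (i in 1:100) {
      k <- sample(2:30, 1)
      gamma <- rnorm(k, 0.2, 0.05)
      Gamma <- rnorm(k, 0.1 * gamma, 0.02)
      se_g <- runif(k, 0.001, 0.01)
      se_G <- runif(k, 0.005, 0.05)
      h <- tibble::tibble(variant_id = paste0("rs", 1:k),
                          beta_exposure = gamma, se_exposure = se_g,
                          beta_outcome = Gamma, se_outcome = se_G)
      est <- mr_ivw(wald_ratios(h))
      fit <- stats::lm(Gamma ~ gamma - 1, weights = se_G^-2)
      expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-8)
    }
  })
})

test_that("cochran_q matches hand arithmetic and is scale invariant", {
  # identical estimates: no heterogeneity
  same <- cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.1))
  expect_equal(same$q, 0)
  expect_equal(same$pvalue, 1)

  # from the printed type 2 diabetes confidence intervals; the publication
  # quotes Q = 2.39 from unrounded internals, the rounded inputs give ~1.89
  est <- t2d_printed_estimates()
  got <- cochran_q(est$beta, est$se)
  expect_equal(got$q, 1.89, tolerance = 0.01)
  expect_equal(got$df, 1L)

  # common rescaling of betas and SEs leaves Q unchanged
  expect_equal(cochran_q(3.7 * est$beta, 3.7 * est$se)$q, got$q)

  expect_error(cochran_q(0.3, 0.1),
               class = "tidymr_degrees_of_freedom_error")
})

test_that("mr_egger recovers exact lines and matches a WLS oracle", {
  mk_h <- function(g, G, se_G = 0.05) {
    tibble::tibble(variant_id = paste0("rs", seq_along(g)),
                   beta_exposure = g, se_exposure = 0.01,
                   beta_outcome = G, se_outcome = se_G)
  }
  # collinear points: slope 1, intercept 0.5, exactly
  fit <- mr_egger(mk_h(c(1, 2, 3), c(1.5, 2.5, 3.5)))
  expect_equal(fit$slope$beta, 1)
  expect_equal(fit$intercept$beta, 0.5)

  # through-origin line: slope 2, intercept 0
  fit2 <- mr_egger(mk_h(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(fit2$slope$beta, 2)
  expect_equal(fit2$intercept$beta, 0, tolerance = 1e-12)

  # random 20-instrument set against an independent weighted LS solve
  withr::with_seed(7, {
    g <- rnorm(20, 0.2, 0.05)
    G <- 0.3 * g + 0.02 + rnorm(20, 0, 0.03)
    se_G <- runif(20, 0.02, 0.06)
  })
  h <- mk_h(g, G, se_G)
  fit3 <- mr_egger(h)
  sgn <- sign(g)
  x <- cbind(1, g * sgn)
  y <- G * sgn
  W <- diag(se_G^-2)
  bhat <- solve(t(x) %*% W %*% x, t(x) %*% W %*% y)
  resid <- y - x %*% bhat
  sigma2 <- sum(se_G^-2 * resid^2) / (20 - 2)
  vc <- max(1, sigma2) * solve(t(x) %*% W %*% x)
  expect_equal(fit3$slope$beta, bhat[2, 1], tolerance = 1e-8)
  expect_equal(fit3$intercept$beta, bhat[1, 1], tolerance = 1e-8)
  expect_equal(fit3$slope$se, sqrt(vc[2, 2]), tolerance = 1e-8)
  expect_equal(fit3$intercept$se, sqrt(vc[1, 1]), tolerance = 1e-8)

  # fewer than three instruments is surfaced as an instrument-count error
  expect_error(mr_egger(mk_h(c(1, 2), c(1, 2))),
               class = "tidymr_instrument_count_error")
})

test_that("weighted median interpolates cumulative weight midpoints", {
  eq <- tibble::tibble(theta = c(1, 2, 3), se_theta = 1)
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 2)

  # hand interpolation: weights (1,1,2)/4 -> midpoints (.125,.375,.75)
  uneq <- tibble::tibble(theta = c(1, 2, 10),
                         se_theta = c(1, 1, 1 / sqrt(2)))
  est <- mr_weighted_median(uneq, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2 + 8 * (0.5 - 0.375) / (0.75 - 0.375))

  # permutation invariance of the point estimate
  perm <- uneq[c(3, 1, 2), ]
  expect_equal(mr_weighted_median(perm, n_boot = 50, seed = 1)$beta,
               est$beta)

  # seeded reproducibility of the bootstrap SE
  a <- mr_weighted_median(uneq, n_boot = 200, seed = 99)
  b <- mr_weighted_median(uneq, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)

  expect_error(mr_weighted_median(eq, n_boot = 0, seed = 1),
               class = "tidymr_config_error")
})

test_that("weighted mode finds the dominant ratio cluster", {
  # point mass
  pm <- tibble::tibble(theta = c(1.3, 1.3, 1.3), se_theta = 1)
  expect_equal(mr_weighted_mode(pm, n_boot = 10, seed = 1)$beta, 1.3)

  # robust to a single outlier
  out <- tibble::tibble(theta = c(1.0, 1.1, 0.9, 5.0), se_theta = 1)
  est <- mr_weighted_mode(out, n_boot = 50, seed = 1)
  expect_lt(abs(est$beta - 1), 0.2)

  # the 512-point grid argmax matches a 10x finer brute-force scan to
  # within one coarse grid step
  withr::with_seed(21, {
    theta <- c(rnorm(15, 0.5, 0.1), rnorm(5, 2, 0.1))
    w <- runif(20, 0.5, 2)
  })
  h <- 0.9 * min(sd(theta), stats::IQR(theta) / 1.349) * 20^(-1 / 5)
  grid_coarse <- seq(min(theta) - 3 * h, max(theta) + 3 * h,
                     length.out = 512)
  grid_fine <- seq(min(theta) - 3 * h, max(theta) + 3 * h,
                   length.out = 5120)
  dens <- function(xs) {
    vapply(xs, function(x) sum((w / sum(w)) * dnorm((x - theta) / h)),
           numeric(1))
  }
  brute <- grid_fine[which.max(dens(grid_fine))]
  rt <- tibble::tibble(theta = theta, se_theta = 1 / sqrt(w))
  est2 <- mr_weighted_mode(rt, n_boot = 10, seed = 1)
  expect_lt(abs(est2$beta - brute), diff(grid_coarse[1:2]))
})

test_that("all estimators are equivariant under negating the exposure coding", {
  sim <- simulate_two_sample(sim_config(n_snps = 25, theta = 0.3,
                                        flip_fraction = 0, seed = 5))
  h <- harmonize_pair(sim$exposure, sim$outcome)
  neg <- h
  neg$beta_exposure <- -neg$beta_exposure

  expect_equal(mr_ivw(wald_ratios(neg))$beta, -mr_ivw(wald_ratios(h))$beta)
  expect_equal(mr_weighted_median(neg, n_boot = 50, seed = 3)$beta,
               -mr_weighted_median(h, n_boot = 50, seed = 3)$beta)
  expect_equal(mr_weighted_mode(neg, n_boot = 10, seed = 3)$beta,
               -mr_weighted_mode(h, n_boot = 10, seed = 3)$beta,
               tolerance = 1e-10)
  expect_equal(mr_egger(neg)$slope$beta, -mr_egger(h)$slope$beta)
})

test_that("significance classification applies the Bonferroni threshold strictly", {
  expect_equal(classify_significance(0.004, n_outcomes = 8), "significant")
  expect_equal(classify_significance(0.03, n_outcomes = 8), "suggestive")
  expect_equal(classify_significance(0.05, n_outcomes = 8), "null")
  expect_equal(classify_significance(0.00625, n_outcomes = 8), "suggestive")
  expect_equal(
    classify_significance(c(1e-5, 0.02, 0.9), n_outcomes = 8),
    c("significant", "suggestive", "null")
  )
  expect_error(classify_significance(0.01, alpha = 1.5),
               class = "tidymr_config_error")
})

test_that("estimate export table carries methods, CIs and significance classes", {
  sim <- simulate_two_sample(sim_config(n_snps = 10, theta = 0.2, seed = 3))
  h <- harmonize_pair(sim$exposure, sim$outcome)
  ests <- list(mr_ivw(wald_ratios(h)),
               mr_weighted_median(h, n_boot = 50, seed = 1))
  tab <- export_estimates(ests, outcome = "sim_outcome")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$method, c("ivw_fixed", "weighted_median"))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  path <- file.path(withr::local_tempdir(), "est.tsv")
  export_estimates(ests, path = path, outcome = "sim_outcome")
  expect_true(file.exists(path))
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 2)
})
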