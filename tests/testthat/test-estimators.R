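test_that("Wald ratio and its delta-method standard errors are exact", {
  # null numerator
  est <- wald_ratio(0.5, 0.05, 0, 0.1)
  expect_equal(est$beta, 0)
  expect_equal(est$se, 0.1 / 0.5)
  # identity instrument
  est <- wald_ratio(1, 0, 0.3, 0.07)
  expect_equal(est$beta, 0.3)
  expect_equal(est$se, 0.07)
  # delta-method oracle evaluated independently
  bx <- 0.5; sx <- 0.05; by <- 0.2; sy <- 0.1
  first <- wald_ratio(bx, sx, by, sy)
  second <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
  expect_equal(first$beta, by / bx)
  expect_equal(first$se, sy / abs(bx), tolerance = 1e-15)
  expect_equal(second$se, sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4),
               tolerance = 1e-15)
  expect_error(wald_ratio(0, 0.1, 0.2, 0.1), "zero")
})

test_that("every estimate's odds-ratio fields equal exp of the beta fields", {
  h <- random_harmonized(6, seed = 1, correlated = TRUE)
  for (est in list(mr_ivw(h), mr_ivw(h, "multiplicative_random"),
                   mr_ivw_correlated(h), mr_egger(h)$slope, mr_raps(h),
                   wald_ratio(0.2, 0.01, 0.1, 0.02))) {
    expect_identical(est$odds_ratio, exp(est$beta))
    expect_identical(est$or_ci_low, exp(est$ci_low))
    expect_identical(est$or_ci_high, exp(est$ci_high))
    expect_lt(est$ci_low, est$ci_high)
    expect_gt(est$pvalue, 0)
    expect_lte(est$pvalue, 1)
  }
})

test_that("correlated IVW with one instrument is the Wald ratio", {
  h <- harmonized_dataset(0.12, 0.015, 0.04, 0.03)
  est <- mr_ivw_correlated(h)
  wald <- wald_ratio(0.12, 0.015, 0.04, 0.03)
  expect_equal(est$beta, wald$beta, tolerance = 1e-12)
  expect_equal(est$se, wald$se, tolerance = 1e-12)
})

test_that("correlated IVW equals independent fixed-effect IVW under identity LD", {
  for (seed in 1:10) {
    h <- random_harmonized(5, seed = seed)
    a <- mr_ivw_correlated(h)
    b <- mr_ivw(h)
    expect_equal(a$beta, b$beta, tolerance = 1e-10)
    expect_equal(a$se, b$se, tolerance = 1e-10)
  }
})

test_that("correlated IVW matches explicit cofactor matrix algebra at K = 3", {
  bx <- c(0.10, 0.15, 0.08)
  sx <- c(0.01, 0.012, 0.011)
  by <- c(0.02, 0.05, 0.01)
  sy <- c(0.03, 0.04, 0.025)
  rho <- matrix(0.5, 3, 3); diag(rho) <- 1
  h <- harmonized_dataset(bx, sx, by, sy, ld = rho)
  est <- mr_ivw_correlated(h)
  # oracle: Omega inverse by the adjugate / determinant, no solve()
  omega <- outer(sy, sy) * rho
  cof <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    minor <- omega[-i, -j, drop = FALSE]
    cof[i, j] <- (-1)^(i + j) * (minor[1, 1] * minor[2, 2] -
                                   minor[1, 2] * minor[2, 1])
  }
  det3 <- sum(omega[1, ] * cof[1, ])
  oinv <- t(cof) / det3
  prec <- drop(t(bx) %*% oinv %*% bx)
  beta_oracle <- drop(t(bx) %*% oinv %*% by) / prec
  expect_equal(est$beta, beta_oracle, tolerance = 1e-10)
  expect_equal(est$se, sqrt(1 / prec), tolerance = 1e-10)
})

test_that("independent IVW reduces correctly for replicated instruments", {
  k <- 4
  h <- harmonized_dataset(rep(0.1, k), rep(0.01, k), rep(0.03, k),
                          rep(0.02, k))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.03 / 0.1, tolerance = 1e-12)
  expect_equal(est$se, (0.02 / 0.1) / sqrt(k), tolerance = 1e-12)
})

test_that("multiplicative random effects never deflate below the fixed-effect SE", {
  # perfectly proportional: Q = 0 <= K - 1, so RE equals FE
  bx <- c(0.1, 0.2, 0.15); sy <- c(0.02, 0.03, 0.025)
  h <- harmonized_dataset(bx, rep(0.01, 3), 0.3 * bx, sy)
  expect_equal(mr_ivw(h, "multiplicative_random")$se, mr_ivw(h)$se,
               tolerance = 1e-12)
  # overdispersed toys inflate
  h2 <- random_harmonized(8, seed = 3)
  h2$data$beta_outcome <- h2$data$beta_outcome + rnorm(8, 0, 0.2)
  expect_gte(mr_ivw(h2, "multiplicative_random")$se, mr_ivw(h2)$se)
  expect_error(mr_ivw(harmonized_dataset(0.1, 0.01, 0.02, 0.01),
                      "multiplicative_random"), "at least 2")
})

test_that("independent IVW equals the weighted mean of Wald ratios", {
  for (seed in 1:10) {
    h <- random_harmonized(7, seed = 100 + seed)
    d <- h$data
    ratios <- d$beta_outcome / d$beta_exposure
    w <- d$beta_exposure^2 / d$se_outcome^2
    expect_equal(mr_ivw(h)$beta, sum(w * ratios) / sum(w), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers a noiseless line and matches the normal equations", {
  # exact line: intercept and slope recovered to machine precision
  bx <- c(0.05, 0.1, 0.15, 0.2)
  a <- 0.01; slope <- 0.4
  h <- harmonized_dataset(bx, rep(0.01, 4), a + slope * bx, rep(0.02, 4))
  fit <- mr_egger(h)
  expect_equal(fit$slope$beta, slope, tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, a, tolerance = 1e-10)

  # weighted normal equations solved by hand on a 4-point toy
  by <- c(0.03, 0.02, 0.09, 0.07)
  sy <- c(0.02, 0.03, 0.04, 0.025)
  h2 <- harmonized_dataset(bx, rep(0.01, 4), by, sy)
  fit2 <- mr_egger(h2)
  w <- 1 / sy^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope_oracle <- (sw * swxy - swx * swy) / det
  int_oracle <- (swxx * swy - swx * swxy) / det
  expect_equal(fit2$slope$beta, slope_oracle, tolerance = 1e-10)
  expect_equal(fit2$intercept$estimate, int_oracle, tolerance = 1e-10)

  expect_error(mr_egger(harmonized_dataset(bx[1:2], rep(0.01, 2), by[1:2],
                                           sy[1:2])), "at least 3")
})

test_that("MR-Egger is invariant to flipping any instrument's sign pair", {
  h <- random_harmonized(6, seed = 4)
  base <- mr_egger(h)
  for (i in c(1, 3, 6)) {
    flipped <- h
    flipped$data$beta_exposure[i] <- -h$data$beta_exposure[i]
    flipped$data$beta_outcome[i] <- -h$data$beta_outcome[i]
    fit <- mr_egger(flipped)
    expect_equal(fit$slope$beta, base$slope$beta, tolerance = 1e-12)
    expect_equal(fit$intercept$estimate, base$intercept$estimate,
                 tolerance = 1e-12)
    expect_equal(fit$intercept$se, base$intercept$se, tolerance = 1e-12)
  }
})

test_that("heterogeneity is zero for proportional effects and matches a hand sum", {
  bx <- c(0.1, 0.2, 0.15); sy <- c(0.02, 0.03, 0.025)
  h <- harmonized_dataset(bx, rep(0.01, 3), 0.25 * bx, sy)
  het <- mr_heterogeneity(h)
  expect_equal(het$Q, 0, tolerance = 1e-20)
  expect_equal(het$i_squared, 0)
  expect_equal(het$df, 2L)

  # K = 2 hand-computable residual sum around a supplied estimate
  h2 <- harmonized_dataset(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.04),
                           c(0.02, 0.03))
  pooled <- mr_ivw(h2)
  het2 <- mr_heterogeneity(h2, pooled)
  q_hand <- (0.05 - pooled$beta * 0.1)^2 / 0.02^2 +
    (0.04 - pooled$beta * 0.2)^2 / 0.03^2
  expect_equal(het2$Q, q_hand, tolerance = 1e-12)
  expect_equal(het2$pvalue, pchisq(q_hand, 1, lower.tail = FALSE))
  expect_error(mr_heterogeneity(harmonized_dataset(0.1, 0.01, 0.02, 0.01)),
               "at least 2")
})

test_that("leave-one-out reduces to the retained SNP's ratio at K = 2", {
  h <- harmonized_dataset(c(0.1, 0.2), c(0.01, 0.012), c(0.05, 0.04),
                          c(0.02, 0.03))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 2L)
  # omitting SNP 1 leaves SNP 2's Wald ratio, and vice versa
  expect_equal(loo$beta[loo$snp_id == "snp01"], 0.04 / 0.2, tolerance = 1e-12)
  expect_equal(loo$beta[loo$snp_id == "snp02"], 0.05 / 0.1, tolerance = 1e-12)
})

test_that("leave-one-out is flat for exchangeable instruments and matches subsets", {
  k <- 5
  h <- harmonized_dataset(rep(0.1, k), rep(0.01, k), rep(0.03, k),
                          rep(0.02, k))
  loo <- mr_leave_one_out(h)
  full <- mr_ivw(h)
  expect_true(all(abs(loo$beta - full$beta) < 1e-12))

  # correlated K = 5 toy: each row equals the estimator on the explicit subset
  h2 <- random_harmonized(5, seed = 6, correlated = TRUE)
  loo2 <- mr_leave_one_out(h2)
  for (i in 1:5) {
    keep <- setdiff(1:5, i)
    sub <- harmonized_dataset(h2$data$beta_exposure[keep],
                              h2$data$se_exposure[keep],
                              h2$data$beta_outcome[keep],
                              h2$data$se_outcome[keep],
                              ld = h2$ld[keep, keep])
    expect_equal(loo2$beta[i], mr_ivw_correlated(sub)$beta, tolerance = 1e-12)
    expect_equal(loo2$se[i], mr_ivw_correlated(sub)$se, tolerance = 1e-12)
  }
})

test_that("RAPS equals fixed-effect IVW when exposure-side noise vanishes", {
  h <- random_harmonized(6, seed = 7)
  h$data$se_exposure <- rep(1e-12, 6)  # effectively zero
  raps <- mr_raps(h)
  ivw <- mr_ivw(h)
  expect_equal(raps$beta, ivw$beta, tolerance = 1e-6)
  expect_equal(raps$se, ivw$se, tolerance = 1e-6)
  expect_error(mr_raps(harmonized_dataset(c(0.1, 0.2), c(0.01, 0.01),
                                          c(0.02, 0.03), c(0.01, 0.01))),
               "at least 3")
})

test_that("RAPS is consistent for the causal effect over simulated replicates", {
  # summary-level generative model with exposure-side noise
  set.seed(11)
  truth <- 0.25
  reps <- 300
  k <- 15
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    bx0 <- runif(k, 0.05, 0.2)
    sx <- rep(0.02, k); sy <- rep(0.03, k)
    bx <- bx0 + rnorm(k, 0, sx)
    by <- truth * bx0 + rnorm(k, 0, sy)
    est[r] <- mr_raps(harmonized_dataset(bx, sx, by, sy))$beta
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - truth), 4 * mc_se + 0.005)
})

test_that("pooled estimators are equivariant to rescaling the exposure", {
  for (seed in 1:5) {
    h <- random_harmonized(6, seed = 200 + seed, correlated = TRUE)
    for (c in c(0.5, 2, 10)) {
      hs <- h
      hs$data$beta_exposure <- c * h$data$beta_exposure
      hs$data$se_exposure <- c * h$data$se_exposure
      expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c, tolerance = 1e-10)
      expect_equal(mr_ivw_correlated(hs)$beta, mr_ivw_correlated(h)$beta / c,
                   tolerance = 1e-10)
      expect_equal(mr_egger(hs)$slope$beta, mr_egger(h)$slope$beta / c,
                   tolerance = 1e-10)
      expect_equal(mr_raps(hs)$beta, mr_raps(h)$beta / c, tolerance = 1e-5)
    }
  }
})
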