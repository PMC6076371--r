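# Outcome transform, scaling, deletion, fitting, and fit statistics.

test_that("YMRS log transform matches the published transformed values", {
  expect_equal(log_transform_ymrs(0), 0)
  expect_equal(round(log_transform_ymrs(20), 3), 3.045)
  expect_equal(log_transform_ymrs(7), log(8))
  expect_equal(log_transform_ymrs(7), 2.0794, tolerance = 1e-4)
  expect_error(log_transform_ymrs(-1), "nonnegative")
})

test_that("bias-corrected sample skewness matches an independent computation", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_gt(sample_skewness(c(0, 0, 0, 10)), 0)
  # frozen from an independent implementation of the adjusted
  # Fisher-Pearson formula (scipy.stats.skew, bias = False)
  expect_equal(sample_skewness(c(1, 2, 3, 4, 100)), 2.232395911636458,
    tolerance = 1e-12
  )
  expect_error(sample_skewness(c(1, 2)), "at least 3")
  expect_error(sample_skewness(c(2, 2, 2)), "zero-variance")
})

make_frame <- function(n = 64, seed = 1, n_subj = 8, beta = NULL, sd_e = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, mood_predictors()))
  beta <- beta %||% rnorm(7)
  out <- tibble::as_tibble(as.data.frame(X))
  out$subject_id <- rep_len(sprintf("s%d", seq_len(n_subj)), n)
  out$outcome <- 2 + as.numeric(X %*% beta) + rnorm(n, 0, sd_e)
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("predictor scaling centres, scales, and is location/scale invariant", {
  fr <- make_frame()
  sc <- scale_predictors(fr)
  for (p in mood_predictors()) {
    expect_equal(mean(sc$data[[p]]), 0, tolerance = 1e-12)
    expect_equal(sd(sc$data[[p]]), 1, tolerance = 1e-12)
    # two-pass brute-force recompute
    expect_equal(
      sc$data[[p]], (fr[[p]] - mean(fr[[p]])) / sd(fr[[p]]),
      tolerance = 1e-12
    )
  }
  # constant shift leaves the scaled column identical
  fr2 <- fr
  fr2$session_count <- fr2$session_count + 100
  sc2 <- scale_predictors(fr2)
  expect_equal(sc2$data$session_count, sc$data$session_count, tolerance = 1e-12)
  # positive rescaling of a raw predictor too
  fr3 <- fr
  fr3$backspace_ratio <- fr3$backspace_ratio * 37.5
  sc3 <- scale_predictors(fr3)
  expect_equal(sc3$data$backspace_ratio, sc$data$backspace_ratio, tolerance = 1e-12)

  fr4 <- fr
  fr4$autocorrect_rate <- 0.1
  expect_error(scale_predictors(fr4), "autocorrect_rate")
})

test_that("pairwise deletion drops exactly the rows missing model variables", {
  fr <- make_frame(72)
  spec <- model_spec("HDRS17_RAW")
  expect_equal(nrow(apply_pairwise_deletion(fr, spec)), 72)

  fr$circadian_similarity[5] <- NA
  kept <- apply_pairwise_deletion(fr, spec)
  expect_equal(nrow(kept), 71)
  expect_equal(attr(kept, "n_dropped"), 1L)

  # 9 x 8 cohort with 8 induced missing rows retains n = 64
  fr2 <- make_frame(72)
  fr2$avg_interkey_delay[c(1, 10, 20, 30, 40, 50, 60, 70)] <- NA
  expect_equal(nrow(apply_pairwise_deletion(fr2, spec)), 64)

  fr3 <- make_frame(5)
  fr3$outcome <- NA
  expect_error(apply_pairwise_deletion(fr3, spec), "zero observations")
})

test_that("noiseless data recover the generating coefficients exactly", {
  beta <- c(1.5, -2, 0.5, 0, 3, -1, 0.25)
  fr <- make_frame(64, seed = 3, beta = beta, sd_e = 0)
  spec <- model_spec("HDRS17_RAW")
  # perfect fits legitimately trip lme4/summary.lm numeric heuristics
  fit <- suppressWarnings(suppressMessages(fit_mixed_model(fr, spec)))
  expect_equal(fit$coefficients$estimate[-1], beta, tolerance = 1e-6)
  ols <- suppressWarnings(
    fit_ols(fr, model_spec("HDRS17_RAW", include_random_intercept = FALSE))
  )
  expect_equal(ols$coefficients$estimate[-1], beta, tolerance = 1e-9)
  expect_equal(ols$multiple_r2, 1, tolerance = 1e-12)
})

test_that("OLS matches an independent pseudo-inverse solution and null R2 is small", {
  fr <- make_frame(200, seed = 9, sd_e = 2)
  spec <- model_spec("HDRS17_RAW", include_random_intercept = FALSE)
  fit <- fit_ols(fr, spec)
  X <- cbind(1, as.matrix(fr[, mood_predictors()]))
  beta_pinv <- solve(t(X) %*% X, t(X) %*% fr$outcome)
  expect_equal(fit$coefficients$estimate, as.numeric(beta_pinv), tolerance = 1e-9)

  # base-R cross-check of the likelihood/F machinery
  lmfit <- lm(reformulate(mood_predictors(), "outcome"), data = fr)
  expect_equal(fit$log_likelihood, as.numeric(logLik(lmfit)), tolerance = 1e-9)
  expect_equal(fit$aic, AIC(lmfit), tolerance = 1e-9)
  expect_equal(fit$bic, BIC(lmfit), tolerance = 1e-9)
  expect_equal(
    fit$f_statistic, summary(lmfit)$fstatistic[["value"]],
    tolerance = 1e-9
  )
  expect_equal(fit$adjusted_r2, summary(lmfit)$adj.r.squared, tolerance = 1e-12)

  # outcome independent of predictors -> R2 near 0
  fr0 <- make_frame(2000, seed = 10, beta = rep(0, 7), sd_e = 1)
  fit0 <- fit_ols(fr0, spec)
  expect_lt(fit0$multiple_r2, 0.02)

  fr_colin <- fr
  fr_colin$autocorrect_rate <- fr_colin$backspace_ratio
  expect_error(fit_ols(fr_colin, spec), "collinear")
})

test_that("mixed model recovers variance components and matches lme4 bookkeeping", {
  set.seed(21)
  n_subj <- 30
  nw <- 10
  u <- rnorm(n_subj, 0, 2)
  fr <- make_frame(n_subj * nw, seed = 22, n_subj = n_subj, sd_e = 1)
  fr$outcome <- fr$outcome + u[as.integer(factor(fr$subject_id))]
  spec <- model_spec("HDRS17_RAW")
  fit <- fit_mixed_model(fr, spec)
  expect_gt(fit$sigma_u2, 1)
  expect_lt(abs(sqrt(fit$sigma_e2) - 1), 0.3)
  # AIC/BIC under the ML parameter count k = p + 1 + 2 agree with lme4
  lfit <- lme4::lmer(
    reformulate(c(mood_predictors(), "(1 | subject_id)"), "outcome"),
    data = fr, REML = FALSE
  )
  expect_equal(fit$log_likelihood, as.numeric(logLik(lfit)), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(lfit), tolerance = 1e-8)
  expect_equal(fit$bic, BIC(lfit), tolerance = 1e-8)
  expect_equal(fit$n_parameters, 10L)
  expect_true(fit$marginal_r2 <= fit$conditional_r2)
  expect_lte(fit$conditional_r2, 1)
  expect_error(
    fit_mixed_model(dplyr::mutate(fr, subject_id = "s1"), spec),
    "2 subjects"
  )
})

test_that("likelihood ratio test reproduces the published arithmetic", {
  fake <- function(ll, k, n = 64) {
    structure(
      list(log_likelihood = ll, n_parameters = k, n_observations = n),
      class = "keymood_fit"
    )
  }
  same <- likelihood_ratio_test(fake(-100, 3), fake(-100, 10))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)

  lrt <- likelihood_ratio_test(fake(-188.45, 3), fake(-179.65, 10))
  expect_equal(lrt$chi_square, 17.6, tolerance = 1e-12)
  expect_equal(lrt$df, 7)
  expect_equal(lrt$p_value, pchisq(17.6, 7, lower.tail = FALSE))

  expect_error(likelihood_ratio_test(fake(-100, 10), fake(-99, 3)), "more parameters")
  expect_error(likelihood_ratio_test(fake(-100, 3, n = 60), fake(-99, 10)), "identical")
  # numerically lower full-model likelihood clamps at zero
  expect_equal(likelihood_ratio_test(fake(-100, 3), fake(-100.001, 10))$chi_square, 0)
})

test_that("Nakagawa-Schielzeth decomposition follows the variance-share formulas", {
  r2 <- nakagawa_schielzeth_r2(2, 1, 1)
  expect_equal(r2$marginal, 0.5)
  expect_equal(r2$conditional, 0.75)

  b <- nakagawa_schielzeth_r2(2, 0, 1)
  expect_equal(b$marginal, b$conditional)

  z <- nakagawa_schielzeth_r2(0, 1, 1)
  expect_equal(z$marginal, 0)

  set.seed(3)
  for (i in 1:50) {
    comp <- runif(3, 0.01, 5)
    r <- nakagawa_schielzeth_r2(comp[1], comp[2], comp[3])
    expect_lte(r$marginal, r$conditional)
    expect_lte(r$conditional, 1)
  }
})

test_that("Wald chi-square tests equal squared-z tests", {
  w0 <- wald_chisq_tests(0, 1)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  w <- wald_chisq_tests(1.96, 1)
  expect_equal(w$p_value, 0.05, tolerance = 1e-3)

  set.seed(8)
  est <- rnorm(20)
  se <- runif(20, 0.5, 2)
  w2 <- wald_chisq_tests(est, se)
  expect_equal(w2$p_value, 2 * pnorm(abs(est / se), lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_true(all(w2$ci_lower < est & est < w2$ci_upper))
})

test_that("information criteria reproduce the published model-comparison values", {
  mixed <- information_criteria(-64.621, k = 10, n = 64)
  expect_equal(round(mixed$aic, 2), 149.24)
  expect_equal(round(mixed$bic, 2), 170.83)
  ols <- information_criteria(-64.621, k = 9, n = 64)
  expect_equal(round(ols$aic, 2), 147.24)
  expect_equal(round(ols$bic, 2), 166.67)
  flat <- information_criteria(0, k = 1, n = 1)
  expect_equal(flat$aic, 2)
  expect_equal(flat$bic, 0)
})

test_that("Spearman S statistic handles ties via midranks like cor.test", {
  conc <- spearman_total_keys(1:9, (1:9) * 10)
  expect_equal(conc$S, 0)
  expect_equal(conc$rho, 1)

  disc <- spearman_total_keys(1:9, 9:1)
  expect_equal(disc$rho, -1)

  set.seed(12)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5) # ties present
  y <- rnorm(9)
  ours <- spearman_total_keys(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ours$S, sum((rank(x) - rank(y))^2), tolerance = 1e-12)

  expect_error(spearman_total_keys(1:2, 2:1), "at least 3")
  expect_error(spearman_total_keys(1:9, rep(1, 9)), "constant")
})

test_that("auto model selection falls back to OLS at the zero-variance boundary", {
  # outcome with a real subject effect -> mixed retained
  set.seed(31)
  fr <- make_frame(72, seed = 31, n_subj = 9, sd_e = 1)
  fr$outcome <- fr$outcome + rnorm(9, 0, 3)[as.integer(factor(fr$subject_id))]
  feats <- fr
  feats$scale <- "HDRS17"
  feats$score <- round(pmin(pmax(fr$outcome + 12, 0), 52))
  auto <- suppressMessages(fit_mood_model(feats, "hdrs17", model = "auto"))
  expect_s3_class(auto, "keymood_auto")
  expect_equal(auto$selected, "mixed")
})
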