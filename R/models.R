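# Outcome transforms, predictor scaling, random-intercept mixed-effects and
# OLS fitting, and the fit statistics reported alongside them. Mixed models
# are fitted by maximum likelihood (not REML): the likelihood-ratio test
# compares models differing in fixed effects, and the mixed-vs-OLS AIC
# comparison only reproduces under ML with parameter counts p+1+2 vs p+1+1.

#' Natural-log transform of YMRS scores
#'
#' The YMRS distribution is right-skewed, so modelling uses ln(score + 1);
#' the +1 keeps a score of 0 at 0.
#'
#' @param score Nonnegative numeric score(s).
#' @return ln(score + 1).
#' @export
#' @examples
#' log_transform_ymrs(20) # 3.045
log_transform_ymrs <- function(score) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("YMRS score must be nonnegative", call. = FALSE)
  }
  log(score + 1)
}

#' Bias-corrected sample skewness
#'
#' Adjusted Fisher-Pearson coefficient
#' G1 = g1 * sqrt(n (n - 1)) / (n - 2), with g1 = m3 / m2^(3/2).
#'
#' @param values Numeric vector, at least 3 values with nonzero variance.
#' @return Skewness coefficient.
#' @export
sample_skewness <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) {
    stop("skewness requires at least 3 values", call. = FALSE)
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    stop("skewness undefined for zero-variance input", call. = FALSE)
  }
  g1 <- mean((values - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Specify a severity regression model
#'
#' @param outcome `"HDRS17_RAW"` (raw 17-item depression score) or
#'   `"LOG_YMRS"` (ln(YMRS + 1) mania score).
#' @param predictors Ordered, duplicate-free character vector of feature
#'   columns used as fixed effects.
#' @param grouping Column identifying subjects (random-intercept grouping).
#' @param include_random_intercept Whether the model carries a per-subject
#'   random intercept.
#' @return A `keymood_spec` list.
#' @export
model_spec <- function(outcome = c("HDRS17_RAW", "LOG_YMRS"),
                       predictors = mood_predictors(),
                       grouping = "subject_id",
                       include_random_intercept = TRUE) {
  outcome <- match.arg(outcome)
  if (length(predictors) == 0 || anyDuplicated(predictors) > 0) {
    stop("predictors must be non-empty and duplicate-free", call. = FALSE)
  }
  structure(
    list(
      outcome = outcome, predictors = predictors, grouping = grouping,
      include_random_intercept = isTRUE(include_random_intercept)
    ),
    class = "keymood_spec"
  )
}

#' Assemble the model frame for one outcome
#'
#' Selects the feature rows of the requested scale and attaches the modelled
#' outcome: the raw score for HDRS-17, ln(score + 1) for YMRS.
#'
#' @param features Feature table from [build_feature_table()].
#' @param outcome `"hdrs17"` or `"ymrs"`.
#' @return Tibble with `subject_id`, `outcome`, and the predictor columns.
#' @export
prepare_model_frame <- function(features, outcome = c("hdrs17", "ymrs")) {
  outcome <- match.arg(outcome)
  scale_name <- if (outcome == "hdrs17") "HDRS17" else "YMRS"
  rows <- features[features$scale == scale_name, , drop = FALSE]
  rows$outcome <- if (outcome == "hdrs17") {
    as.numeric(rows$score)
  } else {
    log_transform_ymrs(rows$score)
  }
  rows[, c("subject_id", "outcome", intersect(mood_predictors(), names(rows)))]
}

#' Pairwise deletion of incomplete observations
#'
#' Drops rows missing the outcome or any predictor the model uses; rows are
#' only removed for variables this model actually needs.
#'
#' @param frame Model frame from [prepare_model_frame()] (an `outcome`
#'   column plus predictors).
#' @param spec A [model_spec()].
#' @return The retained tibble, with attribute `n_dropped`.
#' @export
apply_pairwise_deletion <- function(frame, spec) {
  needed <- c("outcome", spec$predictors)
  missing_cols <- setdiff(needed, names(frame))
  if (length(missing_cols) > 0) {
    stop(
      "model frame lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- complete.cases(frame[, needed, drop = FALSE])
  out <- frame[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("pairwise deletion retained zero observations", call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Standardize predictors to pooled mean 0, SD 1
#'
#' Each predictor is centred by its pooled mean and divided by its pooled
#' sample SD across the supplied (retained) observations, so coefficients are
#' in outcome units per predictor SD.
#'
#' @param frame Tibble containing the predictor columns.
#' @param predictors Columns to scale (default all seven).
#' @return List with `data` (scaled tibble) and `scaling` (tibble of
#'   `predictor`, `center`, `scale` for the inverse transform).
#' @export
scale_predictors <- function(frame, predictors = mood_predictors()) {
  scaling <- lapply(predictors, function(p) {
    v <- frame[[p]]
    if (is.null(v)) stop("no such predictor column: ", p, call. = FALSE)
    mu <- mean(v, na.rm = TRUE)
    sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv < 1e-12) {
      stop("predictor '", p, "' has zero variance; cannot scale", call. = FALSE)
    }
    tibble::tibble(predictor = p, center = mu, scale = sdv)
  })
  scaling <- dplyr::bind_rows(scaling)
  data <- frame
  for (i in seq_len(nrow(scaling))) {
    p <- scaling$predictor[i]
    data[[p]] <- (data[[p]] - scaling$center[i]) / scaling$scale[i]
  }
  list(data = data, scaling = scaling)
}

new_fit_result <- function(x) structure(x, class = "keymood_fit")

#' Wald chi-square tests and normal 95% confidence intervals
#'
#' statistic = (estimate / se)^2, compared to chi-square with 1 df
#' (equivalently z^2); CI = estimate +/- 1.96 se.
#'
#' @param estimate,se Numeric vectors of coefficients and standard errors.
#' @return Tibble with `statistic`, `p_value`, `ci_lower`, `ci_upper`.
#' @export
wald_chisq_tests <- function(estimate, se) {
  stat <- (estimate / se)^2
  tibble::tibble(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    ci_lower = estimate - 1.96 * se,
    ci_upper = estimate + 1.96 * se
  )
}

#' Akaike and Bayesian information criteria
#'
#' AIC = 2k - 2ll; BIC = k ln(n) - 2ll, with k the full ML parameter count
#' (fixed coefficients including the intercept, plus 2 variance parameters
#' for a random-intercept mixed model or 1 residual variance for OLS).
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Parameter count (>= 1).
#' @param n Number of observations (>= 1).
#' @return List with `aic` and `bic`.
#' @export
#' @examples
#' information_criteria(-64.621, k = 10, n = 64) # AIC 149.24, BIC 170.83
information_criteria <- function(log_likelihood, k, n) {
  stopifnot(k >= 1, n >= 1)
  list(
    aic = 2 * k - 2 * log_likelihood,
    bic = k * log(n) - 2 * log_likelihood
  )
}

#' Nakagawa-Schielzeth variance decomposition
#'
#' marginal R2 = sigma_f^2 / (sigma_f^2 + sigma_u^2 + sigma_e^2) — variance
#' explained by the fixed effects alone; conditional R2 adds the random
#' intercept variance to the numerator. `sigma_f2` is the population
#' variance (divide by n) of the fixed-effects linear predictor.
#'
#' @param sigma_f2 Variance of the fixed-effects predicted values, or a
#'   `keymood_fit` from [fit_mixed_model()].
#' @param sigma_u2 Random-intercept variance.
#' @param sigma_e2 Residual variance.
#' @return List with `marginal` and `conditional`.
#' @export
#' @examples
#' nakagawa_schielzeth_r2(2, 1, 1) # marginal 0.5, conditional 0.75
nakagawa_schielzeth_r2 <- function(sigma_f2, sigma_u2 = NULL, sigma_e2 = NULL) {
  if (inherits(sigma_f2, "keymood_fit")) {
    fit <- sigma_f2
    sigma_f2 <- fit$sigma_f2
    sigma_u2 <- fit$sigma_u2
    sigma_e2 <- fit$sigma_e2
  }
  tot <- sigma_f2 + sigma_u2 + sigma_e2
  list(
    marginal = sigma_f2 / tot,
    conditional = (sigma_f2 + sigma_u2) / tot
  )
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Fit the random-intercept mixed-effects severity model
#'
#' Maximum-likelihood fit of
#' `outcome = b0 + sum_k b_k x_k + u_i + e`, `u_i ~ N(0, sigma_u^2)`,
#' `e ~ N(0, sigma_e^2)`, via `lme4::lmer(REML = FALSE)`. A boundary
#' estimate sigma_u^2 = 0 is permitted and flagged (`singular = TRUE`);
#' at that boundary the log-likelihood coincides with the OLS fit on the
#' same data.
#'
#' @param data Scaled model frame (an `outcome` column, the predictors, and
#'   the grouping column), already pairwise-deleted.
#' @param spec A [model_spec()] with `include_random_intercept = TRUE`.
#' @return A `keymood_fit` with coefficients (Wald chi-square tests, normal
#'   95% CIs), log-likelihood, AIC/BIC (k = p + 1 + 2), variance components
#'   `sigma_u2`, `sigma_e2`, `sigma_f2`, and marginal/conditional R2.
#' @export
fit_mixed_model <- function(data, spec) {
  stopifnot(inherits(spec, "keymood_spec"), spec$include_random_intercept)
  if (length(unique(data[[spec$grouping]])) < 2) {
    stop("mixed model requires at least 2 subjects", call. = FALSE)
  }
  fml <- as.formula(paste(
    "outcome ~", paste(spec$predictors, collapse = " + "),
    "+ (1 |", spec$grouping, ")"
  ))
  fit <- tryCatch(
    lme4::lmer(fml, data = data, REML = FALSE),
    error = function(e) {
      stop("mixed-model fit failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tests <- wald_chisq_tests(beta, se)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == spec$grouping][1]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"][1]
  X <- stats::model.matrix(fit)
  sigma_f2 <- pop_var(as.numeric(X %*% beta))
  n <- nrow(data)
  k <- length(beta) + 2L
  ll <- as.numeric(logLik(fit))
  ic <- information_criteria(ll, k, n)
  r2 <- nakagawa_schielzeth_r2(sigma_f2, sigma_u2, sigma_e2)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    message("fit_mixed_model: random-intercept variance estimated at the 0 boundary")
  }
  new_fit_result(list(
    model = "mixed", outcome = spec$outcome,
    coefficients = tibble::tibble(
      term = names(beta), estimate = unname(beta), se = unname(se), tests
    ),
    log_likelihood = ll, aic = ic$aic, bic = ic$bic,
    n_observations = n, n_parameters = k,
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, sigma_f2 = sigma_f2,
    marginal_r2 = r2$marginal, conditional_r2 = r2$conditional,
    singular = singular,
    n_dropped = attr(data, "n_dropped") %||% NA_integer_
  ))
}

#' Fit the null mixed model (subject-level effect only)
#'
#' ML fit of `outcome ~ 1 + (1 | grouping)` — the comparison model of the
#' overall likelihood-ratio test, which asks whether the seven metadata
#' features jointly improve on a model with nothing but per-subject mood
#' levels.
#'
#' @param data Model frame with `outcome` and the grouping column.
#' @param grouping Subject identifier column.
#' @return A `keymood_fit` with k = 3 parameters (intercept + 2 variances).
#' @export
fit_null_mixed <- function(data, grouping = "subject_id") {
  fml <- as.formula(paste("outcome ~ 1 + (1 |", grouping, ")"))
  fit <- lme4::lmer(fml, data = data, REML = FALSE)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- as.numeric(logLik(fit))
  n <- nrow(data)
  ic <- information_criteria(ll, 3L, n)
  new_fit_result(list(
    model = "mixed_null", outcome = NA_character_,
    coefficients = tibble::tibble(
      term = names(beta), estimate = unname(beta), se = unname(se),
      wald_chisq_tests(beta, se)
    ),
    log_likelihood = ll, aic = ic$aic, bic = ic$bic,
    n_observations = n, n_parameters = 3L,
    sigma_u2 = vc$vcov[vc$grp == grouping][1],
    sigma_e2 = vc$vcov[vc$grp == "Residual"][1],
    sigma_f2 = 0, singular = lme4::isSingular(fit, tol = 1e-5)
  ))
}

#' Fit the fixed-effects OLS severity model
#'
#' Least-squares fit used when the random-intercept variance collapses to
#' zero. Reports multiple and adjusted R2, RMSE = sqrt(RSS/n), residual
#' standard error sqrt(RSS/(n-p-1)), the overall F statistic with
#' (p, n-p-1) df, per-coefficient t tests, and ML log-likelihood/AIC/BIC
#' with k = p + 1 + 1.
#'
#' @param data Scaled model frame, already pairwise-deleted.
#' @param spec A [model_spec()] with `include_random_intercept = FALSE`.
#' @return A `keymood_fit`.
#' @export
fit_ols <- function(data, spec) {
  stopifnot(inherits(spec, "keymood_spec"), !spec$include_random_intercept)
  fml <- as.formula(paste("outcome ~", paste(spec$predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  if (fit$rank < length(spec$predictors) + 1L) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    stop(
      "rank-deficient design; collinear predictor(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  n <- nrow(data)
  p <- length(spec$predictors)
  df_res <- n - p - 1L
  tstat <- beta / se
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((data$outcome - mean(data$outcome))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  fstat <- (r2 / p) / ((1 - r2) / df_res)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- p + 1L + 1L
  ic <- information_criteria(ll, k, n)
  sigma_f2 <- pop_var(as.numeric(stats::fitted(fit)))
  new_fit_result(list(
    model = "ols", outcome = spec$outcome,
    coefficients = tibble::tibble(
      term = names(beta), estimate = unname(beta), se = unname(se),
      statistic = unname(tstat),
      p_value = 2 * pt(abs(tstat), df = df_res, lower.tail = FALSE),
      ci_lower = unname(beta) - 1.96 * se,
      ci_upper = unname(beta) + 1.96 * se
    ),
    log_likelihood = ll, aic = ic$aic, bic = ic$bic,
    n_observations = n, n_parameters = k,
    multiple_r2 = r2, adjusted_r2 = adj_r2,
    rmse = sqrt(rss / n), residual_se = sqrt(rss / df_res),
    f_statistic = fstat, f_df1 = p, f_df2 = df_res,
    f_p_value = pf(fstat, p, df_res, lower.tail = FALSE),
    sigma_f2 = sigma_f2, sigma_e2 = rss / n,
    n_dropped = attr(data, "n_dropped") %||% NA_integer_
  ))
}

#' Likelihood-ratio test between nested ML fits
#'
#' statistic = 2 (ll_full - ll_null), clamped at 0; df = difference in ML
#' parameter counts; p from the upper chi-square tail. Both fits must be on
#' the same observations.
#'
#' @param null_fit,full_fit `keymood_fit` objects (null nested in full).
#' @return A `keymood_lrt` list with `chi_square`, `df`, `p_value`, and both
#'   log-likelihoods.
#' @export
likelihood_ratio_test <- function(null_fit, full_fit) {
  if (null_fit$n_observations != full_fit$n_observations) {
    stop("LRT requires fits on identical observation sets", call. = FALSE)
  }
  df <- full_fit$n_parameters - null_fit$n_parameters
  if (df <= 0) {
    stop("full model must have more parameters than the null", call. = FALSE)
  }
  stat <- max(0, 2 * (full_fit$log_likelihood - null_fit$log_likelihood))
  structure(
    list(
      chi_square = stat, df = df,
      p_value = pchisq(stat, df = df, lower.tail = FALSE),
      log_likelihood_null = null_fit$log_likelihood,
      log_likelihood_full = full_fit$log_likelihood
    ),
    class = "keymood_lrt"
  )
}

#' Spearman rank correlation via the S statistic
#'
#' Computes S = sum of squared rank differences with midranks for ties, the
#' corresponding rho (1 - 6S/(n(n^2-1)) for untied data, Pearson correlation
#' of midranks otherwise), and a t-approximation p-value — the check used to
#' relate per-subject total key counts to demographics.
#'
#' @param totals,covariate Numeric vectors (one value per subject, >= 3).
#' @return List with `S`, `rho`, `p_value`, `n`.
#' @export
spearman_total_keys <- function(totals, covariate) {
  n <- length(totals)
  stopifnot(length(covariate) == n)
  if (n < 3) {
    stop("Spearman correlation requires at least 3 subjects", call. = FALSE)
  }
  if (sd(totals) == 0 || sd(covariate) == 0) {
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  }
  rx <- rank(totals)
  ry <- rank(covariate)
  S <- sum((rx - ry)^2)
  tied <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  rho <- if (tied) {
    stats::cor(rx, ry)
  } else {
    1 - 6 * S / (n * (n^2 - 1))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(
    S = S, rho = rho,
    p_value = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE),
    n = n
  )
}

#' Fit a severity model from the feature table
#'
#' High-level wrapper: assembles the model frame for the outcome, applies
#' pairwise deletion, scales the predictors, and fits. `model = "auto"`
#' reproduces the published fallback logic: fit the mixed model; if the
#' random-intercept variance is estimated at the zero boundary, also fit OLS
#' on the same data and select it (its AIC is lower by 2 at the boundary).
#'
#' @param features Feature table from [build_feature_table()].
#' @param outcome `"hdrs17"` or `"ymrs"`.
#' @param model `"mixed"`, `"ols"`, or `"auto"`.
#' @param predictors Fixed-effect feature columns.
#' @return For `"mixed"`/`"ols"`, a `keymood_fit`. For `"auto"`, a
#'   `keymood_auto` list with `mixed`, possibly `ols`, and `selected`.
#' @export
fit_mood_model <- function(features, outcome = c("hdrs17", "ymrs"),
                           model = c("auto", "mixed", "ols"),
                           predictors = mood_predictors()) {
  outcome <- match.arg(outcome)
  model <- match.arg(model)
  out_enum <- if (outcome == "hdrs17") "HDRS17_RAW" else "LOG_YMRS"
  frame <- prepare_model_frame(features, outcome)
  spec_mixed <- model_spec(out_enum, predictors, include_random_intercept = TRUE)
  spec_ols <- model_spec(out_enum, predictors, include_random_intercept = FALSE)
  frame <- apply_pairwise_deletion(frame, spec_mixed)
  n_dropped <- attr(frame, "n_dropped")
  scaled <- scale_predictors(frame, predictors)
  data <- scaled$data
  attr(data, "n_dropped") <- n_dropped
  if (model == "ols") {
    fit <- fit_ols(data, spec_ols)
    fit$scaling <- scaled$scaling
    return(fit)
  }
  mixed <- fit_mixed_model(data, spec_mixed)
  mixed$scaling <- scaled$scaling
  if (model == "mixed") {
    return(mixed)
  }
  if (isTRUE(mixed$singular)) {
    ols <- fit_ols(data, spec_ols)
    ols$scaling <- scaled$scaling
    structure(list(mixed = mixed, ols = ols, selected = "ols"),
      class = "keymood_auto"
    )
  } else {
    structure(list(mixed = mixed, selected = "mixed"), class = "keymood_auto")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.keymood_fit <- function(x, ...) {
  cat(sprintf(
    "%s model (%s), n = %d\n",
    if (x$model == "mixed") "Linear mixed-effects" else "Ordinary least squares",
    x$outcome, x$n_observations
  ))
  co <- x$coefficients
  cat(sprintf(
    "  %-24s %8s (%7s to %7s)  p\n", "term", "est", "lo", "hi"
  ))
  for (i in seq_len(nrow(co))) {
    cat(sprintf(
      "  %-24s %8.2f (%7.2f to %7.2f)  %.3g\n",
      co$term[i], co$estimate[i], co$ci_lower[i], co$ci_upper[i], co$p_value[i]
    ))
  }
  cat(sprintf(
    "  logLik %.3f  AIC %.2f  BIC %.2f\n", x$log_likelihood, x$aic, x$bic
  ))
  if (x$model == "mixed") {
    cat(sprintf(
      "  sigma_u2 %.3f  sigma_e2 %.3f  marginal R2 %.2f  conditional R2 %.2f%s\n",
      x$sigma_u2, x$sigma_e2, x$marginal_r2, x$conditional_r2,
      if (isTRUE(x$singular)) "  [boundary: sigma_u2 = 0]" else ""
    ))
  } else {
    cat(sprintf(
      "  multiple R2 %.2f  adjusted R2 %.2f  RMSE %.2f  F(%d,%d) = %.2f, p = %.3g\n",
      x$multiple_r2, x$adjusted_r2, x$rmse, x$f_df1, x$f_df2,
      x$f_statistic, x$f_p_value
    ))
  }
  invisible(x)
}

#' @export
print.keymood_lrt <- function(x, ...) {
  cat(sprintf(
    "Likelihood ratio test: chi-square(%d) = %.2f, p = %.3g\n",
    x$df, x$chi_square, x$p_value
  ))
  invisible(x)
}

#' @export
print.keymood_auto <- function(x, ...) {
  cat("Automatic model selection (mixed with OLS fallback)\n")
  cat("selected:", x$selected, "\n\n")
  print(x$mixed)
  if (!is.null(x$ols)) {
    cat("\n")
    print(x$ols)
  }
  invisible(x)
}
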