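# Mood-modulated synthetic cohort with known ground truth. The generator
# states a world matching the study design: 9 subjects followed for 8 weeks,
# ~10^4 keypresses and ~10^5 keystroke-triggered accelerometer readings per
# subject-week, weekly HDRS-17 and YMRS ratings at the end of each week. A
# latent per-subject-week mood-disturbance score modulates the behavioural
# generation channels; observed ratings are then drawn from the realized
# weekly features through a linear model with per-subject random intercepts.

# local-time study epoch: a Monday at local midnight
STUDY_START_LOCAL_S <- 1767571200 # 2026-01-05T00:00:00

#' Default generator parameter sets
#'
#' `default_circadian_profile()` is a normalised 24-hour weight vector for
#' session start hours (quiet overnight, evening peak);
#' `default_outcome_params()` holds the generating outcome coefficients and
#' variance components per scale; `default_mood_feature_links()` holds the
#' latent-mood link slopes per generation channel.
#'
#' @return A numeric vector (profile, links) or nested list (outcomes).
#' @name sim-defaults
NULL

#' @rdname sim-defaults
#' @export
default_circadian_profile <- function() {
  # plausible waking-hours typing profile: quiet overnight, evening peak
  w <- c(
    0.4, 0.2, 0.1, 0.1, 0.1, 0.3, # 00-05
    0.8, 1.5, 2.2, 2.6, 2.8, 3.0, # 06-11
    3.2, 3.0, 2.8, 2.8, 3.0, 3.4, # 12-17
    3.8, 4.0, 3.6, 2.8, 1.8, 1.0 # 18-23
  )
  w / sum(w)
}

#' @rdname sim-defaults
#' @export
default_outcome_params <- function() {
  # Generating coefficients are the published fitted models: HDRS-17 on the
  # raw scale (mixed effects), YMRS on the ln(Y+1) scale (OLS, zero
  # random-intercept variance). Variance components follow the printed
  # variance shares: HDRS conditional - marginal R2 = 0.22 of total var
  # ~6.29^2 gives sigma_u ~2.95, residual share 0.37 gives sigma_e ~3.83;
  # YMRS ML residual sd = 0.71 * sqrt(56/64) ~0.66.
  list(
    hdrs17 = list(
      fixed_effects = c(
        intercept = 11.77, avg_interkey_delay = 2.88, backspace_ratio = -0.01,
        autocorrect_rate = 2.67, circadian_similarity = 0.34,
        avg_accel_displacement = 3.20, avg_session_length = -1.16,
        session_count = 2.18
      ),
      random_intercept_sd = 2.95, residual_sd = 3.83
    ),
    ymrs = list(
      fixed_effects = c(
        intercept = 1.60, avg_interkey_delay = 0.13, backspace_ratio = -0.30,
        autocorrect_rate = 0.06, circadian_similarity = 0.03,
        avg_accel_displacement = 0.39, avg_session_length = -0.04,
        session_count = -0.04
      ),
      random_intercept_sd = 0, residual_sd = 0.66
    )
  )
}

#' @rdname sim-defaults
#' @export
default_mood_feature_links <- function() {
  # Link slopes from the latent mood-disturbance score to each generation
  # channel, on the channel's natural transformed scale (log for rates and
  # delays, logit for probabilities). Signs follow the behavioural
  # hypotheses: disturbance slows and destabilises typing, raises error
  # rates and device motion, and disrupts the diurnal pattern.
  c(
    interkey_delay = 0.15, accel_noise = 0.30, backspace = 0.15,
    autocorrect = 0.15, session_rate = 0.10, session_length = -0.10,
    circadian_disruption = 0.15
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults state the study-scale world: 9 subjects, 8 weeks, an expected
#' `sessions_per_day_mean * 7 * keypresses_per_session_mean` ~9780 keypresses
#' per subject-week, and restart-style accelerometer emission at
#' `accel_sample_rate` (10/s) giving ~10^5 readings per subject-week.
#'
#' @param n_subjects,n_weeks Cohort design (defaults 9 and 8).
#' @param seed Integer seed; per-subject substreams are derived from it, so
#'   adding a subject does not perturb the streams of existing ones.
#' @param sessions_per_day_mean Poisson mean of daily typing sessions.
#' @param keypresses_per_session_mean Mean keypresses per session
#'   (1 + Poisson(mean - 1), so every session has at least one keypress).
#' @param interkey_delay_log_mean,interkey_delay_log_sd Lognormal interkey
#'   delay parameters in log-seconds; delays are truncated below the session
#'   gap threshold (5 s) so sessions never self-split.
#' @param backspace_prob,autocorrect_prob,space_prob Per-keypress
#'   probabilities of a backspace label, an accompanying autocorrect event,
#'   and a space label among non-backspaces.
#' @param circadian_profile 24 nonnegative weights (normalised internally)
#'   for session start hours.
#' @param accel_sample_rate Accelerometer samples per second; each keystroke
#'   restarts the 5-s collection window.
#' @param gravity Gravitational magnitude in m/s^2.
#' @param accel_noise_sd SD of the zero-mean per-component accelerometer
#'   noise, scaled by the latent agitation term.
#' @param utc_offset_s Subject-local UTC offset in seconds (default -18000,
#'   UTC-5).
#' @param outcomes Per-scale outcome parameters: for each of `hdrs17` and
#'   `ymrs`, `fixed_effects` (intercept plus one coefficient per predictor,
#'   outcome units per predictor SD), `random_intercept_sd`, `residual_sd`.
#' @param mood_feature_links Named slopes from the latent mood score to the
#'   generation channels (see [default_mood_feature_links()]).
#' @param feature_jitter_sd SD of independent per-feature-week variation on
#'   the link scale, preventing degenerate collinearity between features.
#' @param circadian_disruption Baseline weight of the uniform component mixed
#'   into the weekly hour profile.
#' @param round_scores Round and clip generated scores to the integer scale
#'   range (set `FALSE` only for noiseless identification checks).
#' @param gap_threshold_s Session gap threshold used for the realized
#'   features.
#' @return A validated `keymood_sim_config` list.
#' @export
simulation_config <- function(n_subjects = 9, n_weeks = 8, seed = 1,
                              sessions_per_day_mean = 34.4,
                              keypresses_per_session_mean = 40.6,
                              interkey_delay_log_mean = log(0.45),
                              interkey_delay_log_sd = 1.0,
                              backspace_prob = 0.093,
                              autocorrect_prob = 0.10,
                              space_prob = 0.15,
                              circadian_profile = default_circadian_profile(),
                              accel_sample_rate = 10,
                              gravity = 9.81,
                              accel_noise_sd = 1.0,
                              utc_offset_s = -18000L,
                              outcomes = default_outcome_params(),
                              mood_feature_links = default_mood_feature_links(),
                              feature_jitter_sd = 0.25,
                              circadian_disruption = 0.1,
                              round_scores = TRUE,
                              gap_threshold_s = 5) {
  cfg <- structure(
    list(
      n_subjects = n_subjects, n_weeks = n_weeks, seed = seed,
      sessions_per_day_mean = sessions_per_day_mean,
      keypresses_per_session_mean = keypresses_per_session_mean,
      interkey_delay_log_mean = interkey_delay_log_mean,
      interkey_delay_log_sd = interkey_delay_log_sd,
      backspace_prob = backspace_prob, autocorrect_prob = autocorrect_prob,
      space_prob = space_prob, circadian_profile = circadian_profile,
      accel_sample_rate = accel_sample_rate, gravity = gravity,
      accel_noise_sd = accel_noise_sd, utc_offset_s = as.integer(utc_offset_s),
      outcomes = outcomes, mood_feature_links = mood_feature_links,
      feature_jitter_sd = feature_jitter_sd,
      circadian_disruption = circadian_disruption,
      round_scores = isTRUE(round_scores), gap_threshold_s = gap_threshold_s
    ),
    class = "keymood_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$n_subjects < 1 || cfg$n_weeks < 1) fail("need >= 1 subject and week")
  if (cfg$sessions_per_day_mean <= 0) fail("sessions_per_day_mean must be > 0")
  if (cfg$keypresses_per_session_mean < 1) {
    fail("keypresses_per_session_mean must be >= 1")
  }
  for (p in c("backspace_prob", "autocorrect_prob", "space_prob", "circadian_disruption")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(p, " must lie in [0, 1]")
  }
  if (length(cfg$circadian_profile) != 24 || any(cfg$circadian_profile < 0) ||
    sum(cfg$circadian_profile) <= 0) {
    fail("circadian_profile needs 24 nonnegative weights with positive sum")
  }
  if (cfg$accel_sample_rate <= 0) fail("accel_sample_rate must be > 0")
  if (cfg$accel_noise_sd < 0 || cfg$feature_jitter_sd < 0) {
    fail("noise SDs must be nonnegative")
  }
  if (cfg$interkey_delay_log_sd <= 0) fail("interkey_delay_log_sd must be > 0")
  for (oc in c("hdrs17", "ymrs")) {
    o <- cfg$outcomes[[oc]]
    if (is.null(o)) fail("outcomes must contain '", oc, "'")
    needed <- c("intercept", mood_predictors())
    if (!all(needed %in% names(o$fixed_effects))) {
      fail("outcomes$", oc, "$fixed_effects must name intercept and all 7 predictors")
    }
    if (o$random_intercept_sd < 0 || o$residual_sd < 0) {
      fail("outcome SDs must be nonnegative")
    }
  }
  invisible(cfg)
}

# Deterministic 31-bit substream seed from (seed, key).
derive_seed <- function(seed, key) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  k <- as.numeric(key) %% 2147483647
  as.integer((s * 48271 + k * 16807 + 12345) %% 2147483647)
}

# mean-preserving lognormal modulation factor: E[exp(s*z - s^2/2)] = 1
ln_mod <- function(effect, total_var) exp(effect - total_var / 2)

# truncated-below-5s lognormal interkey delays via inverse CDF
draw_delays <- function(n, meanlog, sdlog, cap) {
  if (n == 0) {
    return(numeric())
  }
  p_cap <- plnorm(cap, meanlog, sdlog)
  qlnorm(runif(n) * p_cap, meanlog, sdlog)
}

simulate_subject_week <- function(cfg, z, xi, week_start_local) {
  links <- cfg$mood_feature_links
  j <- cfg$feature_jitter_sd
  eff <- function(channel) links[[channel]] * z + j * xi[[channel]]
  var_of <- function(channel) links[[channel]]^2 + j^2

  lam <- 7 * cfg$sessions_per_day_mean *
    ln_mod(eff("session_rate"), var_of("session_rate"))
  n_sess <- rpois(1, lam)
  if (n_sess == 0) {
    return(NULL)
  }

  d_w <- plogis(qlogis(cfg$circadian_disruption) + eff("circadian_disruption"))
  profile_w <- (1 - d_w) * cfg$circadian_profile / sum(cfg$circadian_profile) +
    d_w / 24

  day <- sample(0:6, n_sess, replace = TRUE)
  hour <- sample(0:23, n_sess, replace = TRUE, prob = profile_w)
  sess_start <- week_start_local + day * 86400 + hour * 3600 + runif(n_sess) * 3600

  kp_extra_mean <- (cfg$keypresses_per_session_mean - 1) *
    ln_mod(eff("session_length"), var_of("session_length"))
  k <- 1L + rpois(n_sess, kp_extra_mean)

  meanlog_w <- cfg$interkey_delay_log_mean + eff("interkey_delay")
  delays <- draw_delays(
    sum(k - 1L), meanlog_w, cfg$interkey_delay_log_sd,
    cfg$gap_threshold_s
  )

  sess_id <- rep.int(seq_len(n_sess), k)
  # keypress times: session start plus cumulative within-session delays
  offs <- numeric(length(sess_id))
  first <- !duplicated(sess_id)
  offs[!first] <- delays
  t_kp <- rep.int(sess_start, k) + ave_cumsum(offs, sess_id)

  bp_w <- plogis(qlogis(cfg$backspace_prob) + eff("backspace"))
  ac_w <- plogis(qlogis(cfg$autocorrect_prob) + eff("autocorrect"))
  u <- runif(length(t_kp))
  cls <- ifelse(u < bp_w, "BACKSPACE",
    ifelse(u < bp_w + (1 - bp_w) * cfg$space_prob, "SPACE", "REGULAR")
  )
  auto <- runif(length(t_kp)) < ac_w

  # accelerometer: each keystroke restarts the 5-s collection window, so a
  # session is sampled continuously from first keypress to last + 5 s
  rate <- cfg$accel_sample_rate
  last <- c(sess_id[-1] != sess_id[-length(sess_id)], TRUE)
  horizon <- numeric(length(t_kp))
  horizon[!last] <- t_kp[which(!last) + 1L] - t_kp[!last]
  horizon[last] <- cfg$gap_threshold_s
  n_samp <- integer(length(t_kp))
  n_samp[!last] <- pmax(1L, ceiling(horizon[!last] * rate - 1e-9))
  n_samp[last] <- floor(cfg$gap_threshold_s * rate + 1e-9) + 1L
  t_ac <- rep.int(t_kp, n_samp) + (sequence(n_samp) - 1) / rate

  sd_w <- cfg$accel_noise_sd * exp(eff("accel_noise"))
  n_ac <- length(t_ac)
  dir <- matrix(rnorm(3 * n_ac), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  acc <- cfg$gravity * dir + matrix(rnorm(3 * n_ac, sd = sd_w), ncol = 3)

  ev_t <- c(t_kp, t_kp[auto])
  ev_c <- c(cls, rep("AUTOCORRECT", sum(auto)))
  list(
    events = data.table::data.table(local_s = ev_t, event_class = ev_c),
    accel = data.table::data.table(
      local_s = t_ac, x = acc[, 1], y = acc[, 2], z = acc[, 3]
    )
  )
}

# Generation-side standardization. Unlike the analysis-side
# scale_predictors(), a degenerate (constant or single-row) feature is not an
# error here: it is centred to zero so it contributes to the outcome only
# through the intercept (e.g. backspace_ratio when backspace_prob = 0).
scale_for_generation <- function(frame, predictors) {
  scaling <- dplyr::bind_rows(lapply(predictors, function(p) {
    v <- frame[[p]]
    mu <- mean(v)
    sdv <- sd(v)
    degenerate <- !is.finite(sdv) || sdv < 1e-12
    tibble::tibble(
      predictor = p, center = mu, scale = if (degenerate) 1 else sdv,
      degenerate = degenerate
    )
  }))
  data <- frame
  for (i in seq_len(nrow(scaling))) {
    p <- scaling$predictor[i]
    data[[p]] <- (data[[p]] - scaling$center[i]) / scaling$scale[i]
  }
  list(data = data, scaling = scaling)
}

# grouped cumulative sum (groups are contiguous)
ave_cumsum <- function(x, g) {
  cs <- cumsum(x)
  first <- !duplicated(g)
  base <- cs[first] - x[first]
  cs - base[cumsum(first)]
}

#' Simulate a mood-modulated keystroke cohort
#'
#' Generates keypress events, keystroke-triggered accelerometer samples, and
#' weekly HDRS-17/YMRS assessments for `n_subjects * n_weeks` subject-weeks.
#' Per subject-week: a latent mood-disturbance score modulates session rate,
#' session size, interkey delays, key-class probabilities, accelerometer
#' noise, and diurnal regularity; the weekly features realized in the stream
#' are then standardized (pooled mean/SD) and mood scores are drawn as
#' `intercept + sum(beta * feature_scaled) + u_subject + noise`, rounded and
#' clipped to the scale range. Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return List with `events`, `accel`, `assessments` (tibbles in the
#'   on-disk schemas) and `truth`, a ground-truth list holding the per-subject
#'   random intercepts, latent weekly mood scores, realized weekly features,
#'   the scaling parameters, and the generating coefficient vectors.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  off <- config$utc_offset_s
  subj_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  ev_list <- list()
  ac_list <- list()
  u_h <- numeric(config$n_subjects)
  u_y <- numeric(config$n_subjects)
  zmat <- matrix(0, config$n_subjects, config$n_weeks)
  eps_h <- matrix(0, config$n_subjects, config$n_weeks)
  eps_y <- matrix(0, config$n_subjects, config$n_weeks)
  channels <- c(
    "interkey_delay", "accel_noise", "backspace", "autocorrect",
    "session_rate", "session_length", "circadian_disruption"
  )
  for (i in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, i))
    u_h[i] <- rnorm(1, 0, config$outcomes$hdrs17$random_intercept_sd)
    u_y[i] <- rnorm(1, 0, config$outcomes$ymrs$random_intercept_sd)
    eps_h[i, ] <- rnorm(config$n_weeks, 0, config$outcomes$hdrs17$residual_sd)
    eps_y[i, ] <- rnorm(config$n_weeks, 0, config$outcomes$ymrs$residual_sd)
    for (w in seq_len(config$n_weeks)) {
      z <- rnorm(1)
      zmat[i, w] <- z
      xi <- as.list(setNames(rnorm(length(channels)), channels))
      wk <- simulate_subject_week(
        config, z, xi, STUDY_START_LOCAL_S + (w - 1) * 7 * 86400
      )
      if (!is.null(wk)) {
        wk$events$subject_id <- subj_ids[i]
        wk$accel$subject_id <- subj_ids[i]
        ev_list[[length(ev_list) + 1L]] <- wk$events
        ac_list[[length(ac_list) + 1L]] <- wk$accel
      }
    }
  }
  ev <- data.table::rbindlist(ev_list)
  ac <- data.table::rbindlist(ac_list)
  events <- tibble::tibble(
    subject_id = ev$subject_id,
    timestamp = as.POSIXct(ev$local_s - off, origin = "1970-01-01", tz = "UTC"),
    utc_offset_s = rep(off, nrow(ev)),
    event_class = ev$event_class
  )
  events <- sort_stream(events, "timestamp")
  accel <- tibble::tibble(
    subject_id = ac$subject_id,
    timestamp = as.POSIXct(ac$local_s - off, origin = "1970-01-01", tz = "UTC"),
    utc_offset_s = rep(off, nrow(ac)),
    x = ac$x, y = ac$y, z = ac$z
  )
  accel <- sort_stream(accel, "timestamp")

  # assessments at the local midnight closing each week; features first
  grid <- expand.grid(
    subject_id = subj_ids, week = seq_len(config$n_weeks),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  skeleton <- tibble::tibble(
    subject_id = grid$subject_id,
    assessed_at = as.POSIXct(
      STUDY_START_LOCAL_S + grid$week * 7 * 86400 - off,
      origin = "1970-01-01", tz = "UTC"
    ),
    utc_offset_s = rep(off, nrow(grid)),
    scale = "HDRS17",
    score = NA_integer_,
    week = grid$week
  )
  feats <- suppressMessages(build_feature_table(
    events, accel, skeleton[, 1:5],
    gap_threshold_s = config$gap_threshold_s
  ))
  feats$week <- skeleton$week
  complete <- complete.cases(feats[, mood_predictors()])
  if (!all(complete)) {
    message(
      "simulate_cohort: ", sum(!complete),
      " subject-week(s) with incomplete features; assessments skipped"
    )
  }
  feats_c <- feats[complete, , drop = FALSE]
  scaled <- scale_for_generation(feats_c, mood_predictors())
  X <- as.matrix(scaled$data[, mood_predictors()])
  subj_idx <- match(feats_c$subject_id, subj_ids)
  wk_idx <- feats_c$week
  lin_pred <- function(beta) {
    as.numeric(beta[["intercept"]] + X %*% beta[mood_predictors()])
  }
  bh <- config$outcomes$hdrs17$fixed_effects
  by <- config$outcomes$ymrs$fixed_effects
  eta_h <- lin_pred(bh) + u_h[subj_idx] + eps_h[cbind(subj_idx, wk_idx)]
  eta_y <- lin_pred(by) + u_y[subj_idx] + eps_y[cbind(subj_idx, wk_idx)]
  y_raw <- exp(eta_y) - 1
  if (config$round_scores) {
    score_h <- pmin(pmax(round(eta_h), 0), 52)
    score_y <- pmin(pmax(round(y_raw), 0), 60)
  } else {
    score_h <- eta_h
    score_y <- pmax(y_raw, 0)
  }
  assessments <- dplyr::bind_rows(
    tibble::tibble(
      subject_id = feats_c$subject_id, assessed_at = feats_c$assessed_at,
      utc_offset_s = feats_c$utc_offset_s, scale = "HDRS17", score = score_h
    ),
    tibble::tibble(
      subject_id = feats_c$subject_id, assessed_at = feats_c$assessed_at,
      utc_offset_s = feats_c$utc_offset_s, scale = "YMRS", score = score_y
    )
  )
  if (config$round_scores) assessments$score <- as.integer(assessments$score)
  assessments <- sort_stream(assessments, "assessed_at")

  truth <- list(
    beta = list(hdrs17 = bh, ymrs = by),
    random_intercepts = tibble::tibble(
      subject_id = subj_ids, u_hdrs17 = u_h, u_ymrs = u_y
    ),
    latent_mood = tibble::tibble(
      subject_id = rep(subj_ids, config$n_weeks),
      week = rep(seq_len(config$n_weeks), each = config$n_subjects),
      z = as.numeric(zmat[cbind(
        rep(seq_len(config$n_subjects), config$n_weeks),
        rep(seq_len(config$n_weeks), each = config$n_subjects)
      )])
    ),
    features = feats_c[, setdiff(names(feats_c), c("scale", "score"))],
    scaling = scaled$scaling,
    config = config
  )
  list(events = events, accel = accel, assessments = assessments, truth = truth)
}

#' Parameter-recovery experiment over simulated cohorts
#'
#' For each replicate: simulate a cohort, re-extract the weekly features from
#' the raw streams, fit the random-intercept mixed model by ML, and compare
#' the estimated fixed effects to the generating coefficients. Replicates
#' whose fit fails are reported, not dropped silently.
#'
#' @param config A [simulation_config()]; replicate seeds are derived from
#'   `config$seed`.
#' @param n_replicates Number of replicates (>= 2).
#' @param outcome Which fitted model to assess (`"hdrs17"` or `"ymrs"`).
#' @return List with `per_coefficient` (tibble of truth, mean estimate, bias,
#'   RMSE, and 95% Wald CI coverage per fixed effect), `n_replicates`,
#'   `n_failed`, and `failures` (replicate index + message).
#' @export
recovery_experiment <- function(config, n_replicates, outcome = c("hdrs17", "ymrs")) {
  outcome <- match.arg(outcome)
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    stop("n_replicates must be at least 2", call. = FALSE)
  }
  truth_beta <- config$outcomes[[outcome]]$fixed_effects
  terms <- c("(Intercept)", mood_predictors())
  truth <- setNames(
    truth_beta[c("intercept", mood_predictors())], terms
  )
  est <- matrix(NA_real_, n_replicates, length(terms),
    dimnames = list(NULL, terms)
  )
  cover <- matrix(NA, n_replicates, length(terms), dimnames = list(NULL, terms))
  failures <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, 100000 + r)
    res <- tryCatch(
      {
        sim <- suppressMessages(simulate_cohort(cfg_r))
        feats <- suppressMessages(build_feature_table(
          sim$events, sim$accel, sim$assessments, config$gap_threshold_s
        ))
        suppressMessages(fit_mood_model(feats, outcome, model = "mixed"))
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        replicate = r, message = conditionMessage(res)
      )
      next
    }
    co <- res$coefficients
    idx <- match(co$term, terms)
    est[r, idx] <- co$estimate
    cover[r, idx] <- co$ci_lower <= truth[idx] & truth[idx] <= co$ci_upper
  }
  per_coef <- tibble::tibble(
    term = terms,
    truth = unname(truth),
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(truth),
    rmse = sqrt(colMeans((est - rep(truth, each = n_replicates))^2, na.rm = TRUE)),
    coverage = colMeans(cover, na.rm = TRUE)
  )
  list(
    per_coefficient = per_coef, n_replicates = n_replicates,
    n_failed = length(failures),
    failures = if (length(failures)) dplyr::bind_rows(failures) else NULL
  )
}
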