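# shared fixtures, built in code

# minimal hand-written trial table: n subjects, all required columns,
# two numeric covariates unless overridden
tiny_trial_df <- function(n = 6) {
  stopifnot(n >= 2)
  arm <- rep(c("intervention", "control"), length.out = n)
  d <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    arm = arm,
    enrolled = ifelse(arm == "intervention",
                      rep(c("yes", "yes", "no", "no"), length.out = n),
                      NA_character_),
    stringsAsFactors = FALSE)
  for (p in c("baseline", "fu1", "fu2")) {
    d[[paste0("exposure_", p)]] <- 12
    for (oc in c("admissions", "inpatient_days", "ed_visits", "ambulatory_visits")) {
      d[[paste0(oc, "_", p)]] <- seq_len(n) %% 3
    }
    d[[paste0("cost_", p)]] <- 100 * seq_len(n)
  }
  d$age <- 40 + seq_len(n)
  d$riskscore <- seq_len(n) / n
  d
}

# trial generated fresh under a fixed seed; cached per session for speed
default_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic_trial(synthetic_trial_config(seed = 20191206))
    }
    cache
  }
})

# reduced stage-one settings so boosted fits stay fast in tests
fast_fit <- function(trial, seed = 5, ...) {
  fit_participation_model(trial, folds = 5, max_trees = 300,
                          learning_rate = 0.05, seed = seed, ...)
}

# plain score table for distillation tests
score_table_of <- function(ids, scores) {
  data.frame(subject_id = ids, score = scores, stringsAsFactors = FALSE)
}

# build a trial_dataset directly from the two-period Poisson DiD law, with a
# subject-level normal random intercept, for parameter-recovery tests;
# only the `admissions` outcome carries the law, other columns are filler
did_law_trial <- function(n, tau, beta0 = log(0.2), beta_t = 0.1,
                          sigma_re = 0.4, exposure = 12) {
  arm <- rep(c("intervention", "control"), n / 2)
  b <- rnorm(n, beta0, sigma_re)
  eta_base <- b
  eta_post <- b + beta_t + tau * (arm == "intervention")
  d <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    arm = arm,
    enrolled = ifelse(arm == "intervention", "yes", NA_character_),
    stringsAsFactors = FALSE)
  for (p in c("baseline", "fu1", "fu2")) {
    d[[paste0("exposure_", p)]] <- exposure
    eta <- if (p == "baseline") eta_base else eta_post
    d[[paste0("admissions_", p)]] <- rpois(n, exp(eta) * exposure)
    for (oc in c("inpatient_days", "ed_visits", "ambulatory_visits")) {
      d[[paste0(oc, "_", p)]] <- 0L
    }
    d[[paste0("cost_", p)]] <- 1
  }
  d$x1 <- rnorm(n)
  trial_dataset(d)
}
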