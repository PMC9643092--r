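# internal helpers shared across modules

# round-half-away-from-zero; base round() is banker's rounding, which would
# make retained-subject counts platform/value dependent at exact .5 ties
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, open_left = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single number")
  }
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!lo_ok || x > 1) stop_field(field, "must lie in (0, 1]")
  x
}

# derive a 32-bit-safe stream seed from a base seed and a counter so that
# individual simulation cells/replicates are reproducible independently
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483587 + 104729 * as.numeric(counter)) %% 2147483587 + 1)
}

OUTCOME_COUNTS <- c("admissions", "inpatient_days", "ed_visits", "ambulatory_visits")
OUTCOMES_ALL <- c(OUTCOME_COUNTS, "cost")
PERIODS <- c("baseline", "fu1", "fu2")
FOLLOWUPS <- c("fu1", "fu2")
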