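#' Construct a trial dataset object
#'
#' Bundles a subject-level table from a two-arm randomized trial with its
#' covariate schema. One row per subject, with the randomization arm, the
#' enrollment indicator (intervention arm only; `NA` marks not-applicable for
#' control subjects), baseline covariates, and per-period exposure months,
#' utilization counts and costs for a baseline year and two follow-up years.
#'
#' @param data data.frame with columns `subject_id`, `arm`
#'   (`"intervention"`/`"control"`), `enrolled` (`"yes"`/`"no"`, `NA` for
#'   control subjects), `exposure_<period>`, `<outcome>_<period>` for the
#'   count outcomes `admissions`, `inpatient_days`, `ed_visits`,
#'   `ambulatory_visits`, and `cost_<period>`, for periods `baseline`, `fu1`,
#'   `fu2`, plus one column per baseline covariate.
#' @param covariate_schema data.frame with columns `name` and `kind`
#'   (`"real"` or `"categorical"`). If `NULL`, inferred: every non-required
#'   column is a covariate, numeric columns are `"real"`.
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return An object of class `trial_dataset`: a list with elements `data`
#'   and `covariate_schema`.
#' @seealso [generate_synthetic_trial()], [validate_trial()],
#'   [read_trial_table()]
#' @export
trial_dataset <- function(data, covariate_schema = NULL, validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- required_columns()
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data$subject_id <- as.character(data$subject_id)
  if (is.null(covariate_schema)) {
    cov_names <- setdiff(names(data), req)
    covariate_schema <- data.frame(
      name = cov_names,
      kind = ifelse(vapply(data[cov_names], is.numeric, logical(1)),
                    "real", "categorical"),
      stringsAsFactors = FALSE
    )
  }
  covariate_schema <- as.data.frame(covariate_schema, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kind") %in% names(covariate_schema)))
  bad_kind <- setdiff(covariate_schema$kind, c("real", "categorical"))
  if (length(bad_kind)) stop("unknown covariate kind: ", bad_kind[1], call. = FALSE)
  obj <- structure(list(data = data, covariate_schema = covariate_schema),
                   class = "trial_dataset")
  if (validate) {
    viol <- validate_trial(obj)
    if (nrow(viol)) {
      stop("invalid trial dataset: ", viol$rule[1],
           if (!is.na(viol$subject_id[1])) paste0(" (subject ", viol$subject_id[1], ")"),
           if (nrow(viol) > 1L) sprintf(" [and %d more violation(s)]", nrow(viol) - 1L),
           call. = FALSE)
    }
  }
  obj
}

required_columns <- function() {
  c("subject_id", "arm", "enrolled",
    paste0("exposure_", PERIODS),
    as.vector(outer(OUTCOME_COUNTS, PERIODS, paste, sep = "_")),
    paste0("cost_", PERIODS))
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- x$data
  n_i <- sum(d$arm == "intervention")
  n_c <- sum(d$arm == "control")
  enr <- mean(d$enrolled[d$arm == "intervention"] == "yes", na.rm = TRUE)
  cat("Two-arm randomized trial dataset\n")
  cat(sprintf("  subjects: %d (%d intervention, %d control)\n", nrow(d), n_i, n_c))
  cat(sprintf("  intervention-arm enrollment: %.1f%%\n", 100 * enr))
  cat(sprintf("  covariates: %d (%d real, %d categorical)\n",
              nrow(x$covariate_schema),
              sum(x$covariate_schema$kind == "real"),
              sum(x$covariate_schema$kind == "categorical")))
  invisible(x)
}

#' @export
summary.trial_dataset <- function(object, ...) {
  d <- object$data
  out <- list(
    n = nrow(d),
    n_by_arm = table(d$arm),
    enrollment_rate = mean(d$enrolled[d$arm == "intervention"] == "yes", na.rm = TRUE),
    covariates = object$covariate_schema,
    outcome_means = sapply(c(as.vector(outer(OUTCOME_COUNTS, PERIODS, paste, sep = "_")),
                             paste0("cost_", PERIODS)),
                           function(cl) mean(d[[cl]]))
  )
  class(out) <- "summary.trial_dataset"
  out
}

#' @export
print.summary.trial_dataset <- function(x, ...) {
  cat("Trial dataset:", x$n, "subjects\n")
  print(x$n_by_arm)
  cat(sprintf("Intervention-arm enrollment rate: %.3f\n", x$enrollment_rate))
  cat("Per-period outcome means:\n")
  print(round(x$outcome_means, 3))
  invisible(x)
}

#' Validate a trial dataset
#'
#' Checks every dataset invariant and returns the violations as data, not
#' errors: unique subject ids, both arms nonempty, enrollment defined exactly
#' for the intervention arm, exposure months within \[0, 12\], nonnegative
#' integer counts, nonnegative costs, and complete covariate columns.
#'
#' @param dataset a [trial_dataset()] (or a bare list with the same shape).
#' @return data.frame with columns `subject_id` (`NA` for dataset-level
#'   rules) and `rule`; zero rows when the dataset is valid.
#' @export
validate_trial <- function(dataset) {
  d <- dataset$data
  schema <- dataset$covariate_schema
  v <- list()
  add <- function(ids, rule) {
    if (length(ids)) v[[length(v) + 1L]] <<- data.frame(
      subject_id = as.character(ids), rule = rule, stringsAsFactors = FALSE)
  }
  dup <- d$subject_id[duplicated(d$subject_id)]
  add(unique(dup), "duplicate subject_id")
  if (!any(d$arm == "intervention")) add(NA_character_, "intervention arm empty")
  if (!any(d$arm == "control")) add(NA_character_, "control arm empty")
  add(d$subject_id[!d$arm %in% c("intervention", "control")], "unknown arm")
  add(d$subject_id[d$arm == "control" & !is.na(d$enrolled)],
      "enrolled defined for control arm")
  add(d$subject_id[d$arm == "intervention" & !d$enrolled %in% c("yes", "no")],
      "enrolled missing or invalid for intervention arm")
  for (p in PERIODS) {
    e <- d[[paste0("exposure_", p)]]
    add(d$subject_id[is.na(e) | e < 0 | e > 12],
        sprintf("exposure_%s outside [0, 12]", p))
    for (oc in OUTCOME_COUNTS) {
      y <- d[[paste0(oc, "_", p)]]
      add(d$subject_id[is.na(y) | y < 0 | y != round_half_up(y)],
          sprintf("%s_%s not a nonnegative integer", oc, p))
    }
    cst <- d[[paste0("cost_", p)]]
    add(d$subject_id[is.na(cst) | cst < 0], sprintf("cost_%s negative or missing", p))
  }
  miss_cov <- setdiff(schema$name, names(d))
  for (nm in miss_cov) add(NA_character_, sprintf("covariate column '%s' absent", nm))
  if (length(v)) do.call(rbind, v) else
    data.frame(subject_id = character(), rule = character(), stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-trial generator
#'
#' Defaults mirror the dimensions of a pilot complex-care-management trial:
#' 404 intervention and 401 control subjects with a 64.6% intervention-arm
#' enrollment rate, a baseline year and two follow-up years of utilization
#' and cost outcomes, and baseline covariates predictive of enrollment.
#'
#' @param n_intervention,n_control arm sizes.
#' @param enrollment_rate target marginal enrollment probability in the
#'   intervention arm; the propensity-model intercept is solved numerically
#'   so the mean enrollment propensity equals this value.
#' @param n_covariates number of baseline covariates (60% standard-normal
#'   continuous, the rest Bernoulli(0.3) binary).
#' @param covariate_enrollment_signal strength (>= 0) of the association
#'   between the covariate linear score and the enrollment propensity on the
#'   logit scale; 0 makes enrollment independent of covariates.
#' @param responder_fraction fraction of subjects who benefit from treatment.
#' @param responder_propensity_cor latent correlation between responder
#'   status and the enrollment-propensity score.
#' @param effect_size_log_scale multiplicative treatment effect, log scale,
#'   applied to follow-up outcome rates/costs of treated-and-enrolled
#'   responders (negative = reduction).
#' @param baseline_rates named list: annual Poisson rates for the four count
#'   outcomes, plus `cost_mean` and `cost_shape` for the gamma cost model.
#' @param frailty_sd standard deviation (log scale) of the subject-level
#'   frailty shared across periods, inducing within-person correlation.
#' @param seed integer seed; the generator is fully reproducible given the
#'   configuration.
#' @return An object of class `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(n_intervention = 404L,
                                   n_control = 401L,
                                   enrollment_rate = 0.646,
                                   n_covariates = 10L,
                                   covariate_enrollment_signal = 2.5,
                                   responder_fraction = 0.40,
                                   responder_propensity_cor = 0.30,
                                   effect_size_log_scale = -0.30,
                                   baseline_rates = list(
                                     admissions = 0.9,
                                     inpatient_days = 4.5,
                                     ed_visits = 2.2,
                                     ambulatory_visits = 18,
                                     cost_mean = 30000,
                                     cost_shape = 1.2),
                                   frailty_sd = 0.5,
                                   seed = 1L) {
  if (!is.numeric(n_intervention) || n_intervention < 1) {
    stop_field("n_intervention", "must be a positive integer")
  }
  if (!is.numeric(n_control) || n_control < 1) {
    stop_field("n_control", "must be a positive integer")
  }
  if (!is.numeric(enrollment_rate) || enrollment_rate <= 0 || enrollment_rate >= 1) {
    stop_field("enrollment_rate", "must lie in (0, 1)")
  }
  check_fraction(responder_fraction, "responder_fraction")
  if (!is.numeric(covariate_enrollment_signal) || covariate_enrollment_signal < 0) {
    stop_field("covariate_enrollment_signal", "must be >= 0")
  }
  if (abs(responder_propensity_cor) > 1) {
    stop_field("responder_propensity_cor", "must lie in [-1, 1]")
  }
  if (n_covariates < 1) stop_field("n_covariates", "must be >= 1")
  for (nm in c(OUTCOME_COUNTS, "cost_mean", "cost_shape")) {
    val <- baseline_rates[[nm]]
    if (is.null(val) || !is.numeric(val) || val <= 0) {
      stop_field(paste0("baseline_rates$", nm), "must be a positive number")
    }
  }
  if (frailty_sd < 0) stop_field("frailty_sd", "must be >= 0")
  structure(list(
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    enrollment_rate = enrollment_rate,
    n_covariates = as.integer(n_covariates),
    covariate_enrollment_signal = covariate_enrollment_signal,
    responder_fraction = responder_fraction,
    responder_propensity_cor = responder_propensity_cor,
    effect_size_log_scale = effect_size_log_scale,
    baseline_rates = baseline_rates,
    frailty_sd = frailty_sd,
    seed = as.integer(seed)
  ), class = "synthetic_trial_config")
}

#' Generate a synthetic randomized trial
#'
#' Emulates a two-arm trial diluted by partial uptake. A latent enrollment
#' propensity is the inverse-logit of a linear covariate score whose
#' intercept is solved so the mean propensity equals the configured
#' enrollment rate; intervention-arm subjects enroll with that probability.
#' Count outcomes are Poisson and costs gamma, both with a subject-level
#' log-normal frailty shared across the three periods, so repeated
#' measurements within a subject are positively correlated. A multiplicative
#' treatment effect is applied to follow-up outcomes only for
#' intervention-arm subjects who enrolled and are latent "responders";
#' responder status is correlated with the enrollment propensity, which is
#' the structural assumption a distillation analysis exploits. Both arms are
#' generated under an identical law apart from treatment receipt.
#'
#' @param config a [synthetic_trial_config()].
#' @return A [trial_dataset()]. Attribute `truth` carries the latent
#'   per-subject propensity and responder flags for use in validation
#'   studies.
#' @examples
#' trial <- generate_synthetic_trial(synthetic_trial_config(seed = 42))
#' trial
#' @export
generate_synthetic_trial <- function(config = synthetic_trial_config()) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  set.seed(config$seed)
  n <- config$n_intervention + config$n_control
  arm <- rep(c("intervention", "control"),
             c(config$n_intervention, config$n_control))

  k <- config$n_covariates
  k_real <- max(1L, ceiling(0.6 * k))
  k_bin <- k - k_real
  X <- matrix(rnorm(n * k_real), n, k_real)
  if (k_bin > 0) X <- cbind(X, matrix(rbinom(n * k_bin, 1L, 0.3), n, k_bin))
  cov_names <- c(paste0("x", seq_len(k_real)),
                 if (k_bin > 0) paste0("b", seq_len(k_bin)))
  colnames(X) <- cov_names

  # decreasing weights so influence is concentrated in the leading covariates
  w <- 1 / sqrt(seq_len(k))
  w <- w / sqrt(sum(w^2))
  score <- as.vector(X %*% w) * config$covariate_enrollment_signal
  # intercept calibrated so mean propensity equals the target rate
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + score)) - config$enrollment_rate,
    interval = c(-30, 30), tol = 1e-10)$root
  propensity <- stats::plogis(alpha + score)
  enrolled_draw <- stats::rbinom(n, 1L, propensity) == 1L
  enrolled <- ifelse(arm == "intervention",
                     ifelse(enrolled_draw, "yes", "no"), NA_character_)

  # responder latent correlated with the (standardized) propensity score
  rho <- config$responder_propensity_cor
  score_z <- if (stats::sd(score) > 0) as.vector(scale(score)) else rnorm(n)
  resp_latent <- rho * score_z + sqrt(1 - rho^2) * rnorm(n)
  n_resp <- round_half_up(config$responder_fraction * n)
  responder <- rank(-resp_latent, ties.method = "first") <= n_resp

  treated <- arm == "intervention" & enrolled_draw & responder
  mult <- exp(config$effect_size_log_scale)

  exposure <- matrix(12, n, 3, dimnames = list(NULL, PERIODS))
  frailty_count <- exp(rnorm(n, -config$frailty_sd^2 / 2, config$frailty_sd))
  frailty_cost <- exp(rnorm(n, -config$frailty_sd^2 / 2, config$frailty_sd))

  d <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                  arm = arm, enrolled = enrolled,
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(X))
  for (p in PERIODS) d[[paste0("exposure_", p)]] <- exposure[, p]
  for (p in PERIODS) {
    eff <- ifelse(p != "baseline" & treated, mult, 1)
    for (oc in OUTCOME_COUNTS) {
      lam <- config$baseline_rates[[oc]] * frailty_count *
        exposure[, p] / 12 * eff
      d[[paste0(oc, "_", p)]] <- stats::rpois(n, lam)
    }
    mu <- config$baseline_rates$cost_mean * frailty_cost * exposure[, p] / 12 * eff
    shape <- config$baseline_rates$cost_shape
    d[[paste0("cost_", p)]] <- stats::rgamma(n, shape = shape, rate = shape / mu)
  }

  # binary covariates stay numeric 0/1 so boosted trees split them natively
  schema <- data.frame(name = cov_names, kind = "real",
                       stringsAsFactors = FALSE)
  out <- trial_dataset(d, schema)
  attr(out, "truth") <- data.frame(subject_id = d$subject_id,
                                   propensity = propensity,
                                   responder = responder,
                                   treated = treated,
                                   stringsAsFactors = FALSE)
  out
}

#' Read a subject-level trial table
#'
#' Parses a delimited text file (CSV, RFC-4180 quoting) with one row per
#' subject into a validated [trial_dataset()]. Empty fields in covariate
#' columns are the explicit missing marker and become `NA`.
#'
#' @param path file path or connection.
#' @param covariate_schema optional schema data.frame (`name`, `kind`); when
#'   `NULL` the schema is inferred from column types.
#' @param validate stop on invariant violations (default `TRUE`).
#' @return A [trial_dataset()].
#' @export
read_trial_table <- function(path, covariate_schema = NULL, validate = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character"))
  req <- required_columns()
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d$enrolled[!is.na(d$enrolled) & d$enrolled == ""] <- NA_character_
  for (cl in setdiff(req, c("subject_id", "arm", "enrolled"))) {
    if (!is.numeric(d[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cl]]))) & d[[cl]] != "")
      stop(sprintf("non-numeric value in column '%s' at data row %d", cl,
                   if (length(bad)) bad[1] else 1L), call. = FALSE)
    }
  }
  # exposures and costs are real-valued even when whole numbers on disk
  for (cl in c(paste0("exposure_", PERIODS), paste0("cost_", PERIODS))) {
    d[[cl]] <- as.numeric(d[[cl]])
  }
  if (!is.null(covariate_schema)) {
    for (nm in covariate_schema$name[covariate_schema$kind == "real"]) {
      if (nm %in% names(d)) d[[nm]] <- as.numeric(d[[nm]])
    }
  } else {
    for (nm in setdiff(names(d), req)) {
      if (is.numeric(d[[nm]])) d[[nm]] <- as.numeric(d[[nm]])
    }
  }
  if (!is.null(covariate_schema)) {
    for (nm in covariate_schema$name[covariate_schema$kind == "categorical"]) {
      if (nm %in% names(d)) {
        d[[nm]] <- as.character(d[[nm]])
        d[[nm]][d[[nm]] == ""] <- NA_character_
      }
    }
  }
  dup <- d$subject_id[duplicated(d$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id: ", dup[1], call. = FALSE)
  }
  trial_dataset(d, covariate_schema, validate = validate)
}

#' Write a subject-level trial table
#'
#' Writes a [trial_dataset()] as CSV with a deterministic column order
#' (required columns first, then covariates in schema order). Numeric values
#' are written with 17 significant digits so [read_trial_table()] inverts the
#' write bit-exactly.
#'
#' @param dataset a [trial_dataset()].
#' @param path file path or writable connection.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  d <- dataset$data[, c(required_columns(), dataset$covariate_schema$name)]
  for (cl in names(d)) {
    if (is.double(d[[cl]])) {
      d[[cl]] <- ifelse(is.na(d[[cl]]), NA_character_,
                        sprintf("%.17g", d[[cl]]))
    }
  }
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
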