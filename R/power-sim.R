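#' Simulation scenario for the distillation power study
#'
#' Describes the data-generating law of the Monte-Carlo study of power and
#' type-I error under distillation. Three correlated standard normal latents
#' drive each simulated subject: a treatment-effect latent, a participation
#' latent, and a prediction-of-participation latent. Subjects in the top
#' `responder_fraction` of the treatment-effect latent are responders;
#' intervention-arm subjects in the top `enroll_fraction` of the
#' participation latent are enrolled; distillation retains the top fraction
#' of the prediction latent. The continuous outcome is independent standard
#' normal noise plus `taumax` for subjects who are simultaneously randomized
#' to intervention, enrolled, and responders — a normal approximation of a
#' log cost/utilization model, where `taumax = -0.5` corresponds to roughly
#' a 50% reduction for treated responders.
#'
#' The default correlations (treatment effect vs participation 0.30, each
#' vs its prediction 0.80) describe a favorable setting where those likely
#' to take up the intervention also tend to benefit more and participation
#' is predictable.
#'
#' @param taumax vector of nonpositive treatment values for treated
#'   responders (the scenario grid).
#' @param responder_fraction,enroll_fraction fractions of the pooled sample
#'   that are responders / enrolled.
#' @param rho_te_part,rho_te_pred,rho_part_pred correlations among the three
#'   latents; the implied 3x3 matrix must be positive definite.
#' @param n_per_arm subjects per arm (1:1 allocation).
#' @param alpha nominal test level.
#' @param retention_grid retention fractions evaluated for each replicate;
#'   subsets within a replicate are nested.
#' @param reps Monte-Carlo replicates per `taumax` value.
#' @param seed base seed; per-replicate streams are derived from it by a
#'   counter scheme, so individual cells are reproducible independently.
#' @param latent_triple which triple is jointly normal: `"participation"`
#'   (default; the correlated triple is treatment effect, participation,
#'   prediction, and the outcome is independent noise) or `"outcome"` (the
#'   triple is treatment effect, outcome noise, prediction; the
#'   participation slot of the correlation parameters then refers to the
#'   outcome noise, and enrollment thresholds the prediction latent).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(taumax = c(0, -0.1, -0.2, -0.3, -0.4, -0.5),
                         responder_fraction = 0.40,
                         enroll_fraction = 0.40,
                         rho_te_part = 0.30,
                         rho_te_pred = 0.80,
                         rho_part_pred = 0.80,
                         n_per_arm = 1000L,
                         alpha = 0.05,
                         retention_grid = c(1.00, 0.80, 0.60, 0.40, 0.25),
                         reps = 2000L,
                         seed = 1L,
                         latent_triple = c("participation", "outcome")) {
  latent_triple <- match.arg(latent_triple)
  if (!length(taumax)) stop_field("taumax", "must be a nonempty numeric vector")
  if (any(taumax > 0)) stop_field("taumax", "treatment values must be <= 0")
  check_fraction(responder_fraction, "responder_fraction")
  check_fraction(enroll_fraction, "enroll_fraction")
  if (!is.numeric(n_per_arm) || n_per_arm < 2) {
    stop_field("n_per_arm", "must be an integer >= 2")
  }
  check_fraction(alpha, "alpha")
  if (anyDuplicated(retention_grid)) stop_field("retention_grid", "duplicate fractions")
  for (f in retention_grid) check_fraction(f, "retention_grid")
  if (reps < 1) stop_field("reps", "must be >= 1")
  corr <- latent_correlation(rho_te_part, rho_te_pred, rho_part_pred)
  chol_check(corr)  # fails early on a non-PD matrix
  structure(list(
    taumax = taumax,
    responder_fraction = responder_fraction,
    enroll_fraction = enroll_fraction,
    rho_te_part = rho_te_part, rho_te_pred = rho_te_pred,
    rho_part_pred = rho_part_pred,
    corr = corr,
    n_per_arm = as.integer(n_per_arm),
    alpha = alpha,
    retention_grid = sort(retention_grid, decreasing = TRUE),
    reps = as.integer(reps),
    seed = as.integer(seed),
    latent_triple = latent_triple
  ), class = "sim_scenario")
}

latent_correlation <- function(rho_te_part, rho_te_pred, rho_part_pred) {
  matrix(c(1, rho_te_part, rho_te_pred,
           rho_te_part, 1, rho_part_pred,
           rho_te_pred, rho_part_pred, 1), 3, 3,
         dimnames = rep(list(c("te", "part", "pred")), 2))
}

chol_check <- function(corr) {
  if (!isSymmetric(unname(corr)) || any(diag(corr) != 1)) {
    stop("correlation matrix must be symmetric with unit diagonal", call. = FALSE)
  }
  tryCatch(chol(corr),
           error = function(e) stop("correlation matrix not PD", call. = FALSE))
}

#' Draw correlated standard-normal latents
#'
#' Transforms i.i.d. standard normals by the upper-triangular Cholesky
#' factor of the target correlation matrix, giving standard-normal margins
#' with the requested correlations.
#'
#' @param n number of draws.
#' @param corr symmetric positive-definite correlation matrix.
#' @param seed optional seed.
#' @return `n x ncol(corr)` matrix.
#' @export
draw_correlated_latents <- function(n, corr, seed = NULL) {
  L <- chol_check(corr)
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * ncol(corr)), n, ncol(corr), dimnames = list(NULL, colnames(corr))) %*% L
}

#' Simulate one trial replicate
#'
#' Draws the latent triple, allocates arms 1:1, applies exact rank-based
#' thresholds for responder and enrollment status, and builds the outcome.
#'
#' @param scenario a [sim_scenario()]; if `taumax` has several values the
#'   first is used.
#' @param seed optional seed for this replicate.
#' @return data.frame of class `sim_replicate` with columns `arm`
#'   (1 = intervention), `te_latent`, `part_latent`, `pred_latent`,
#'   `responder`, `enrolled`, `outcome`.
#' @export
simulate_trial_replicate <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  taumax <- scenario$taumax[1]
  N <- 2L * scenario$n_per_arm
  Z <- matrix(rnorm(N * 3), N, 3) %*% chol(scenario$corr)
  arm <- sample(rep(c(0L, 1L), scenario$n_per_arm))
  if (scenario$latent_triple == "participation") {
    te <- Z[, 1]; part <- Z[, 2]; pred <- Z[, 3]
    noise <- rnorm(N)
  } else {
    # alternative reading: the outcome noise itself is the second latent
    te <- Z[, 1]; noise <- Z[, 2]; pred <- Z[, 3]
    part <- pred
  }
  responder <- rank(-te, ties.method = "first") <=
    round_half_up(scenario$responder_fraction * N)
  enrolled <- arm == 1L & rank(-part, ties.method = "first") <=
    round_half_up(scenario$enroll_fraction * N)
  outcome <- noise + taumax * (responder & enrolled)
  out <- data.frame(arm = arm, te_latent = te, part_latent = part,
                    pred_latent = pred, responder = responder,
                    enrolled = enrolled, outcome = outcome)
  class(out) <- c("sim_replicate", "data.frame")
  out
}

# Welch two-sample test p-value, plain arithmetic (hot loop)
welch_p <- function(y1, y0) {
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2L || n0 < 2L) return(NA_real_)
  v1 <- stats::var(y1) / n1; v0 <- stats::var(y0) / n0
  se2 <- v1 + v0
  if (se2 <= 0) return(NA_real_)
  tstat <- (mean(y1) - mean(y0)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
  2 * stats::pt(-abs(tstat), df)
}

# rejection indicators for one replicate across the retention grid;
# retained sets are nested because one rank vector is reused
replicate_rejections <- function(rep_data, retention_grid, alpha) {
  N <- nrow(rep_data)
  pred_rank <- rank(-rep_data$pred_latent, ties.method = "first")
  vapply(retention_grid, function(f) {
    keep <- pred_rank <= round_half_up(f * N)
    p <- welch_p(rep_data$outcome[keep & rep_data$arm == 1L],
                 rep_data$outcome[keep & rep_data$arm == 0L])
    if (is.na(p)) NA else p < alpha
  }, logical(1))
}

#' Estimate the power / type-I-error grid
#'
#' For every `taumax` value in the scenario, simulates `reps` trial
#' replicates; within each replicate, distills the pooled sample to every
#' retention fraction by the prediction latent (subsets nested within a
#' replicate) and applies a two-sided Welch two-sample test of the outcome
#' between arms at level `alpha`. At `taumax = 0` the rejection rate
#' estimates the type-I error; otherwise, power.
#'
#' @param scenario a [sim_scenario()] (its `taumax` may be a vector), or a
#'   list of scenarios (each contributing its own `taumax` values).
#' @return data.frame of class `power_grid` with columns `taumax`,
#'   `retention_fraction`, `rejection_rate`, `mc_se`
#'   (`sqrt(r(1-r)/reps)`), `reps`, `n_per_arm`, `n_skipped`.
#' @examples
#' \donttest{
#' sc <- sim_scenario(taumax = c(0, -0.3), n_per_arm = 300, reps = 200)
#' estimate_power_grid(sc)
#' }
#' @export
estimate_power_grid <- function(scenario) {
  scenarios <- if (inherits(scenario, "sim_scenario")) list(scenario) else scenario
  rows <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "sim_scenario"))
    for (ti in seq_along(sc$taumax)) {
      sc1 <- sc
      sc1$taumax <- sc$taumax[ti]
      rej <- matrix(NA, sc$reps, length(sc$retention_grid))
      for (r in seq_len(sc$reps)) {
        rep_seed <- derive_seed(sc$seed + 1000003 * ti, r)
        rd <- simulate_trial_replicate(sc1, seed = rep_seed)
        rej[r, ] <- replicate_rejections(rd, sc$retention_grid, sc$alpha)
      }
      n_skip <- colSums(is.na(rej))
      if (any(n_skip > 0)) {
        warning(sum(n_skip), " replicate cell(s) skipped (retained arm too small)")
      }
      rate <- colMeans(rej, na.rm = TRUE)
      n_eff <- sc$reps - n_skip
      rows[[length(rows) + 1L]] <- data.frame(
        taumax = sc$taumax[ti],
        retention_fraction = sc$retention_grid,
        rejection_rate = rate,
        mc_se = sqrt(rate * (1 - rate) / pmax(n_eff, 1L)),
        reps = n_eff,
        n_per_arm = sc$n_per_arm,
        n_skipped = n_skip)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_grid", "data.frame")
  out
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Distillation power grid (rejection rates)\n")
  wide <- stats::reshape(
    as.data.frame(x)[, c("taumax", "retention_fraction", "rejection_rate")],
    idvar = "taumax", timevar = "retention_fraction", direction = "wide")
  names(wide) <- sub("rejection_rate\\.", "f=", names(wide))
  print(format(wide, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot a power grid
#'
#' Rejection rate against the percentage of the sample retained, one line
#' per `taumax` value; the nominal level is drawn as a reference.
#'
#' @param x a `power_grid`.
#' @param alpha nominal level reference line.
#' @param ... unused.
#' @export
plot.power_grid <- function(x, alpha = 0.05, ...) {
  tv <- sort(unique(x$taumax))
  graphics::plot(NULL, xlim = rev(range(100 * x$retention_fraction)),
                 ylim = c(0, 1), xlab = "% of sample retained",
                 ylab = "power / rejection rate")
  for (i in seq_along(tv)) {
    g <- x[x$taumax == tv[i], ]
    g <- g[order(-g$retention_fraction), ]
    graphics::lines(100 * g$retention_fraction, g$rejection_rate,
                    type = "b", pch = 19, col = i)
  }
  graphics::abline(h = alpha, lty = 3)
  graphics::legend("topleft", legend = sprintf("taumax = %g", tv),
                   col = seq_along(tv), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Write a power grid to CSV
#'
#' @param grid a `power_grid`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_power_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Monte-Carlo bivariate-normal orthant probability
#'
#' Estimates `P(X > z_q, Y > z_q)` for standard bivariate normals with
#' correlation `rho`, where `z_q` is the upper-`q` quantile — the
#' probability that a subject is simultaneously in the top `q` of two
#' correlated latents. Serves as a brute-force oracle for the overlap of
#' responders and enrollees (independence gives `q^2`; comonotone gives
#' `q`).
#'
#' @param rho correlation in (-1, 1).
#' @param q upper-tail fraction in (0, 1).
#' @param n_draws Monte-Carlo sample size.
#' @param seed optional seed.
#' @return estimated probability.
#' @examples
#' joint_top_fraction_probability(0, 0.4, n_draws = 1e5, seed = 1)   # ~0.16
#' joint_top_fraction_probability(1 - 1e-12, 0.4, n_draws = 1e5, seed = 1)  # ~0.40
#' @export
joint_top_fraction_probability <- function(rho, q, n_draws = 1e6, seed = NULL) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  check_fraction(q, "q")
  if (!is.null(seed)) set.seed(seed)
  z <- stats::qnorm(1 - q)
  x <- rnorm(n_draws)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n_draws)
  mean(x > z & y > z)
}

#' Calibrate the per-arm sample size to a target full-sample power
#'
#' Bisection over `n_per_arm` until the Monte-Carlo rejection rate at 100%
#' retention is within `tolerance` of `target_power`. Each evaluation uses
#' at least `reps` replicates; replicate streams are derived from `seed` and
#' the candidate `n`, so the search is deterministic given the seed.
#'
#' @param scenario a [sim_scenario()] template; its first `taumax` value is
#'   used and must be negative (at `taumax = 0` any `n` attains the nominal
#'   level: the lower bound is returned with attribute `degenerate = TRUE`).
#' @param target_power target rejection rate in (0, 1).
#' @param tolerance acceptable absolute deviation of the estimated power.
#' @param reps replicates per evaluation (minimum 1000 enforced).
#' @param n_bounds integer search interval for `n_per_arm`.
#' @param seed seed for the search.
#' @return integer `n_per_arm`, with attributes `achieved_power` and
#'   `evaluations` (the bisection trace).
#' @export
calibrate_sample_size <- function(scenario, target_power, tolerance = 0.02,
                                  reps = 1000L, n_bounds = c(200L, 60000L),
                                  seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (target_power <= 0 || target_power >= 1) {
    stop("target_power must lie in (0, 1)", call. = FALSE)
  }
  reps <- max(as.integer(reps), 1000L)
  taumax <- scenario$taumax[1]
  if (taumax == 0) {
    if (target_power <= scenario$alpha + tolerance) {
      out <- as.integer(n_bounds[1])
      attr(out, "degenerate") <- TRUE
      attr(out, "achieved_power") <- scenario$alpha
      return(out)
    }
    stop("target unreachable: taumax = 0 caps power at the nominal level",
         call. = FALSE)
  }

  pow_at <- function(n) {
    sc <- scenario
    sc$taumax <- taumax
    sc$n_per_arm <- as.integer(n)
    sc$retention_grid <- 1
    sc$reps <- reps
    sc$seed <- derive_seed(seed, n)
    g <- estimate_power_grid(sc)
    g$rejection_rate[1]
  }

  lo <- as.integer(n_bounds[1]); hi <- as.integer(n_bounds[2])
  trace <- data.frame(n = integer(), power = numeric())
  note <- function(n, p) trace[nrow(trace) + 1L, ] <<- list(n, p)
  p_lo <- pow_at(lo); note(lo, p_lo)
  if (p_lo >= target_power) {
    out <- lo
    attr(out, "achieved_power") <- p_lo
    attr(out, "evaluations") <- trace
    return(out)
  }
  p_hi <- pow_at(hi); note(hi, p_hi)
  if (p_hi < target_power) {
    stop(sprintf(
      "target unreachable within n bounds: power(%d) = %.3f, power(%d) = %.3f, target %.3f",
      lo, p_lo, hi, p_hi, target_power), call. = FALSE)
  }
  best <- hi; best_p <- p_hi
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2L)
    p_mid <- pow_at(mid); note(mid, p_mid)
    if (abs(p_mid - target_power) < abs(best_p - target_power)) {
      best <- mid; best_p <- p_mid
    }
    if (abs(p_mid - target_power) <= tolerance) {
      best <- mid; best_p <- p_mid
      break
    }
    if (p_mid < target_power) lo <- mid else hi <- mid
  }
  out <- as.integer(best)
  attr(out, "achieved_power") <- best_p
  attr(out, "evaluations") <- trace
  out
}
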