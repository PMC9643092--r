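#' Three-stage distillation analysis of a diluted randomized trial
#'
#' The umbrella fitting function. Stage one fits the boosted-tree
#' participation model on the intervention arm and scores every randomized
#' subject ([fit_participation_model()], [score_subjects()]); stage two
#' trims both arms to nested high-probability subsets
#' ([nested_distillation()]); stage three re-estimates the treatment effect
#' on each subset with difference-in-differences mixed models
#' ([run_outcome_grid()]). The first column of results (100% retention) is
#' the conventional intent-to-treat analysis; the remaining columns trade
#' sample size for concentration of likely participants. The estimand
#' changes accordingly: each distilled estimate targets the average
#' treatment effect in the subpopulation with high predicted uptake, not the
#' original population.
#'
#' @param dataset a [trial_dataset()].
#' @param fractions retention fractions for stage two.
#' @param outcomes,periods outcome and follow-up grids for stage three.
#' @param folds,max_trees,interaction_depth,min_leaf,learning_rate stage-one
#'   hyperparameters, see [fit_participation_model()].
#' @param out_of_fold score training subjects out-of-fold (see
#'   [score_subjects()]).
#' @param zero_cost_floor see [fit_did_model()].
#' @param seed integer seed for stage one.
#' @return An object of class `distillation`: list with `participation`
#'   (the stage-one fit), `scores`, `ladder`, `effects` (the
#'   `outcome_grid`), and `call`.
#' @examples
#' \donttest{
#' trial <- generate_synthetic_trial(synthetic_trial_config(seed = 7))
#' ans <- distill(trial, max_trees = 200, learning_rate = 0.05,
#'                outcomes = "ed_visits")
#' summary(ans)
#' }
#' @export
distill <- function(dataset,
                    fractions = c(1.00, 0.80, 0.60, 0.40, 0.25),
                    outcomes = OUTCOMES_ALL,
                    periods = FOLLOWUPS,
                    folds = 10L,
                    max_trees = 10000L,
                    interaction_depth = 2L,
                    min_leaf = 8L,
                    learning_rate = 0.001,
                    out_of_fold = FALSE,
                    zero_cost_floor = 1,
                    seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  fit <- fit_participation_model(dataset, folds = folds, max_trees = max_trees,
                                 interaction_depth = interaction_depth,
                                 min_leaf = min_leaf,
                                 learning_rate = learning_rate, seed = seed)
  scores <- score_subjects(fit, dataset, out_of_fold = out_of_fold)
  ladder <- nested_distillation(dataset, scores, fractions = fractions)
  effects <- run_outcome_grid(dataset, ladder, outcomes = outcomes,
                              periods = periods,
                              zero_cost_floor = zero_cost_floor)
  structure(list(participation = fit, scores = scores, ladder = ladder,
                 effects = effects, call = match.call()),
            class = "distillation")
}

#' @export
print.distillation <- function(x, ...) {
  cat("Distillation analysis\n")
  cat(sprintf("  stage 1: boosted-tree uptake model, CV AUC %.3f (%d trees)\n",
              x$participation$auc, x$participation$n_trees_selected))
  cat(sprintf("  stage 2: %d nested levels (%s%% retained)\n",
              length(x$ladder),
              paste(vapply(x$ladder, function(l) sprintf("%g", 100 * l$retention_fraction),
                           character(1)), collapse = ", ")))
  cat(sprintf("  stage 3: %d difference-in-differences fits (%d converged)\n",
              nrow(x$effects), sum(x$effects$converged)))
  invisible(x)
}

#' @export
summary.distillation <- function(object, ...) {
  eff <- as.data.frame(object$effects)
  out <- list(auc = object$participation$auc,
              auc_insample = object$participation$auc_insample,
              top_influence = relative_influence(object$participation,
                                                 min(5L, nrow(object$participation$schema))),
              effects = eff)
  class(out) <- "summary.distillation"
  out
}

#' @export
print.summary.distillation <- function(x, ...) {
  cat(sprintf("Stage-one AUC: %.3f (CV), %.3f (in-sample)\n",
              x$auc, x$auc_insample))
  cat("Top covariates by relative influence:\n")
  print(transform(x$top_influence, influence = round(influence, 2)),
        row.names = FALSE)
  cat("\nTreatment-effect estimates (tau, log scale):\n")
  show <- x$effects[, c("outcome", "period", "retention_fraction", "tau",
                        "ci_low", "ci_high", "p_value", "converged")]
  for (cl in c("tau", "ci_low", "ci_high")) show[[cl]] <- round(show[[cl]], 3)
  show$p_value <- signif(show$p_value, 3)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
coef.distillation <- function(object, ...) {
  eff <- object$effects
  stats::setNames(eff$tau, paste(eff$outcome, eff$period,
                                 sprintf("f=%g", eff$retention_fraction),
                                 sep = "."))
}

#' @export
plot.distillation <- function(x, ...) plot(x$effects, ...)
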