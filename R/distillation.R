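#' Trim both arms to a high-participation subset
#'
#' Stage two of the distillation analysis. Retains exactly
#' `round(retention_fraction * N)` subjects (round half away from zero) with
#' the highest predicted participation probability, over the pooled sample —
#' the score threshold is applied identically to both arms, which preserves
#' the comparability conferred by randomization within the retained
#' subpopulation. Ties are broken deterministically by (score descending,
#' subject_id ascending).
#'
#' @param dataset a [trial_dataset()].
#' @param scores a `score_table` from [score_subjects()] covering every
#'   subject in `dataset`.
#' @param retention_fraction fraction in (0, 1] of the pooled sample to
#'   retain.
#' @return An object of class `distillation_level`: list with
#'   `retention_fraction`, `threshold` (lowest retained score),
#'   `retained_ids`, and `n_retained_by_arm`.
#' @export
distill_subset <- function(dataset, scores, retention_fraction) {
  check_fraction(retention_fraction, "retention_fraction")
  ord <- score_order(dataset, scores)
  level_from_order(dataset, ord, retention_fraction)
}

# shared deterministic ordering: score descending, subject_id ascending
score_order <- function(dataset, scores) {
  stopifnot(inherits(dataset, "trial_dataset"))
  ids <- dataset$data$subject_id
  m <- match(ids, scores$subject_id)
  if (anyNA(m)) {
    stop("missing score for subject ", ids[which(is.na(m))[1]], call. = FALSE)
  }
  s <- scores$score[m]
  list(ids = ids, score = s, rank = order(-s, ids))
}

level_from_order <- function(dataset, ord, f) {
  n <- length(ord$ids)
  k <- as.integer(round_half_up(f * n))
  take <- ord$rank[seq_len(k)]
  retained <- ord$ids[take]
  arm <- dataset$data$arm[take]
  structure(list(
    retention_fraction = f,
    threshold = if (k > 0L) ord$score[take[k]] else NA_real_,
    retained_ids = retained,
    n_retained_by_arm = c(intervention = sum(arm == "intervention"),
                          control = sum(arm == "control"))
  ), class = "distillation_level")
}

#' @export
print.distillation_level <- function(x, ...) {
  cat(sprintf(
    "Distillation level: retain %.0f%% (n = %d; %d intervention, %d control), score threshold %.4f\n",
    100 * x$retention_fraction, length(x$retained_ids),
    x$n_retained_by_arm[["intervention"]], x$n_retained_by_arm[["control"]],
    x$threshold))
  invisible(x)
}

#' Build a nested ladder of distillation levels
#'
#' Applies [distill_subset()] at each retention fraction using one shared
#' score ordering, so the retained sets are nested by construction: the
#' subjects kept at a smaller fraction are a subset of those kept at any
#' larger fraction. The default ladder spans 100% (the conventional
#' intent-to-treat sample) down to 25% of the pooled sample in five levels.
#'
#' @param dataset a [trial_dataset()].
#' @param scores a `score_table` covering every subject.
#' @param fractions distinct retention fractions in (0, 1].
#' @return An object of class `distillation_ladder`: list of
#'   `distillation_level` objects ordered by decreasing retention fraction.
#' @examples
#' \donttest{
#' trial <- generate_synthetic_trial(synthetic_trial_config(seed = 7))
#' fit <- fit_participation_model(trial, max_trees = 200, learning_rate = 0.05)
#' ladder <- nested_distillation(trial, score_subjects(fit, trial))
#' ladder
#' }
#' @export
nested_distillation <- function(dataset, scores,
                                fractions = c(1.00, 0.80, 0.60, 0.40, 0.25)) {
  if (anyDuplicated(fractions)) stop("duplicate retention fractions", call. = FALSE)
  for (f in fractions) check_fraction(f, "fractions")
  fractions <- sort(fractions, decreasing = TRUE)
  ord <- score_order(dataset, scores)
  levels <- lapply(fractions, function(f) level_from_order(dataset, ord, f))
  names(levels) <- sprintf("%g", fractions)
  structure(levels, class = "distillation_ladder")
}

#' @export
print.distillation_ladder <- function(x, ...) {
  cat("Distillation ladder (", length(x), " nested levels)\n", sep = "")
  for (lv in x) {
    cat(sprintf("  %5.0f%%: n = %4d (%d / %d), threshold %.4f\n",
                100 * lv$retention_fraction, length(lv$retained_ids),
                lv$n_retained_by_arm[["intervention"]],
                lv$n_retained_by_arm[["control"]], lv$threshold))
  }
  invisible(x)
}

#' @export
as.data.frame.distillation_ladder <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(lv) {
    data.frame(retention_fraction = lv$retention_fraction,
               threshold = lv$threshold,
               subject_id = lv$retained_ids,
               stringsAsFactors = FALSE)
  }))
}

#' Write a distillation ladder to CSV (long format)
#'
#' One row per retained subject per level, columns `retention_fraction`,
#' `threshold`, `subject_id`.
#'
#' @param ladder a [nested_distillation()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  utils::write.csv(as.data.frame(ladder), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
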