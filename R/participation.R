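#' Fit the stage-one participation model
#'
#' Predicts intervention uptake (enrollment) from baseline covariates with
#' gradient-boosted classification trees, trained only on intervention-arm
#' subjects — the only arm where uptake is observed. The number of trees is
#' selected by k-fold cross-validation up to `max_trees`. Model quality is
#' summarized by the cross-validated AUC (the headline metric, computed from
#' out-of-fold predictions) alongside the in-sample AUC, and by the relative
#' influence of each covariate, normalized to sum to 100.
#'
#' @param dataset a [trial_dataset()]; the intervention arm must contain both
#'   enrolled and non-enrolled subjects.
#' @param folds number of cross-validation folds.
#' @param max_trees maximum boosting iterations; the optimum is chosen by
#'   cross-validation.
#' @param interaction_depth maximum tree depth.
#' @param min_leaf minimum number of observations in a terminal leaf.
#' @param learning_rate boosting shrinkage.
#' @param seed integer seed controlling fold assignment and tree fitting.
#' @return An object of class `participation_fit` with elements `model` (the
#'   fitted booster), `auc` (cross-validated), `auc_insample`,
#'   `n_trees_selected`, `cv_folds`, `relative_influence` (named vector over
#'   all covariates, summing to 100), and `oof` (out-of-fold scores for the
#'   training subjects).
#' @seealso [score_subjects()], [relative_influence()], [compute_auc()]
#' @examples
#' \donttest{
#' trial <- generate_synthetic_trial(synthetic_trial_config(seed = 7))
#' fit <- fit_participation_model(trial, max_trees = 300, learning_rate = 0.05)
#' fit
#' }
#' @export
fit_participation_model <- function(dataset,
                                    folds = 10L,
                                    max_trees = 10000L,
                                    interaction_depth = 2L,
                                    min_leaf = 8L,
                                    learning_rate = 0.001,
                                    seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  schema <- dataset$covariate_schema
  if (nrow(schema) == 0L) stop("covariate schema is empty", call. = FALSE)
  d_int <- dataset$data[dataset$data$arm == "intervention", , drop = FALSE]
  y <- as.integer(d_int$enrolled == "yes")
  if (length(unique(y)) < 2L) {
    stop("no outcome variation: intervention arm has a single enrollment class",
         call. = FALSE)
  }

  design <- build_design(d_int, schema)
  dm <- xgboost::xgb.DMatrix(design$X, label = y)
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    eta = learning_rate,
    max_depth = interaction_depth,
    min_child_weight = min_leaf,
    nthread = 1L,
    seed = as.integer(seed)
  )
  set.seed(seed)
  cv <- xgboost::xgb.cv(params = params, data = dm, nrounds = max_trees,
                        nfold = folds, prediction = TRUE, metrics = "auc",
                        verbose = FALSE)
  log <- as.data.frame(cv$evaluation_log)
  n_trees <- cv$early_stop$best_iteration %||% which.max(log$test_auc_mean)
  oof_score <- as.vector(cv$cv_predict$pred)
  auc_cv <- compute_auc(oof_score, y)

  set.seed(seed)
  model <- xgboost::xgb.train(params = params, data = dm, nrounds = n_trees,
                              verbose = 0)
  insample <- stats::predict(model, dm)
  auc_in <- compute_auc(insample, y)

  imp <- tryCatch(xgboost::xgb.importance(model = model), error = function(e) NULL)
  ri <- stats::setNames(numeric(nrow(schema)), schema$name)
  if (!is.null(imp) && nrow(imp)) {
    by_cov <- tapply(imp$Gain, design$feature_covariate[imp$Feature], sum)
    ri[names(by_cov)] <- by_cov
  }
  if (sum(ri) > 0) ri <- 100 * ri / sum(ri)

  structure(list(
    model = model,
    schema = schema,
    levels = design$levels,
    feature_covariate = design$feature_covariate,
    cv_folds = as.integer(folds),
    n_trees_selected = as.integer(n_trees),
    auc = auc_cv,
    auc_insample = auc_in,
    relative_influence = ri,
    oof = data.frame(subject_id = d_int$subject_id, score = oof_score,
                     stringsAsFactors = FALSE),
    settings = list(folds = folds, max_trees = max_trees,
                    interaction_depth = interaction_depth,
                    min_leaf = min_leaf, learning_rate = learning_rate,
                    seed = seed)
  ), class = "participation_fit")
}

#' @export
print.participation_fit <- function(x, ...) {
  cat("Participation (uptake) model: gradient-boosted trees\n")
  cat(sprintf("  trees selected by %d-fold CV: %d\n", x$cv_folds,
              x$n_trees_selected))
  cat(sprintf("  AUC: %.3f (cross-validated), %.3f (in-sample)\n",
              x$auc, x$auc_insample))
  top <- utils::head(sort(x$relative_influence, decreasing = TRUE), 5L)
  cat("  top relative influence:\n")
  for (nm in names(top)) cat(sprintf("    %-20s %6.2f\n", nm, top[[nm]]))
  invisible(x)
}

# expand the covariate columns of a subject table into a numeric model
# matrix: real covariates pass through (NA = missing, handled natively by
# the trees); categorical covariates become one 0/1 indicator per training
# level, with missing and unseen levels mapped to the all-zero pattern
build_design <- function(d, schema, levels = NULL) {
  cols <- list()
  feature_covariate <- character()
  lv_out <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(d)) stop("covariate column '", nm, "' absent", call. = FALSE)
    if (schema$kind[i] == "real") {
      cols[[nm]] <- as.numeric(d[[nm]])
      feature_covariate[nm] <- nm
    } else {
      v <- as.character(d[[nm]])
      lv <- levels[[nm]] %||% sort(unique(v[!is.na(v)]))
      lv_out[[nm]] <- lv
      for (l in lv) {
        fn <- paste0(nm, "=", l)
        cols[[fn]] <- as.numeric(!is.na(v) & v == l)
        feature_covariate[fn] <- nm
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, levels = lv_out, feature_covariate = feature_covariate)
}

#' Score all randomized subjects
#'
#' Applies a fitted participation model to every subject in both arms,
#' returning the predicted probability of enrollment. Control-arm subjects
#' have no observed uptake but are scored identically to intervention-arm
#' subjects, which is what allows both arms to be trimmed in an equivalent
#' manner. Unseen categorical levels are mapped to the training-time missing
#' pattern rather than raising an error.
#'
#' @param fit a [fit_participation_model()] result.
#' @param dataset a [trial_dataset()] whose covariate schema matches the
#'   training schema.
#' @param out_of_fold if `TRUE`, subjects that were in the training set
#'   receive their cross-validation out-of-fold score instead of the refit
#'   model's score, guarding against in-sample optimism.
#' @return A data.frame of class `score_table` with columns `subject_id` and
#'   `score` (in \[0, 1\]), one row per subject.
#' @export
score_subjects <- function(fit, dataset, out_of_fold = FALSE) {
  stopifnot(inherits(fit, "participation_fit"), inherits(dataset, "trial_dataset"))
  missing_cov <- setdiff(fit$schema$name, names(dataset$data))
  if (length(missing_cov)) {
    stop("dataset lacks training covariate(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  design <- build_design(dataset$data, fit$schema, levels = fit$levels)
  score <- stats::predict(fit$model, xgboost::xgb.DMatrix(design$X))
  out <- data.frame(subject_id = dataset$data$subject_id,
                    score = as.numeric(score), stringsAsFactors = FALSE)
  if (out_of_fold) {
    m <- match(out$subject_id, fit$oof$subject_id)
    hit <- !is.na(m)
    out$score[hit] <- fit$oof$score[m[hit]]
  }
  class(out) <- c("score_table", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' positive case receives a higher score than a uniformly random negative
#' case, with ties counting one half.
#'
#' @param scores numeric vector of scores.
#' @param labels 0/1 (or logical) outcome labels; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L), na.rm = TRUE)) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks give ties weight 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative influence of covariates
#'
#' Returns the `top_k` covariates by boosted-tree variable importance,
#' rescaled so the influences over all covariates sum to 100.
#'
#' @param fit a [fit_participation_model()] result.
#' @param top_k number of covariates to return (default: all).
#' @return data.frame with columns `covariate` and `influence`, ordered by
#'   decreasing influence.
#' @export
relative_influence <- function(fit, top_k = length(fit$relative_influence)) {
  stopifnot(inherits(fit, "participation_fit"))
  if (!is.numeric(top_k) || top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  ri <- sort(fit$relative_influence, decreasing = TRUE)
  ri <- utils::head(ri, top_k)
  data.frame(covariate = names(ri), influence = as.numeric(ri),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a score table to CSV
#'
#' @param scores a `score_table` from [score_subjects()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
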