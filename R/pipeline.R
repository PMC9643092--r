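#' Build or read an analysis configuration
#'
#' Plain-list configuration for [run_analysis()], serializable to/from a
#' YAML key-value file. Unspecified fields take the documented defaults; a
#' run's effective configuration is echoed to its output directory.
#'
#' @param ... fields overriding the defaults: `input` (trial-table CSV
#'   path), `outdir`, `seed`, `retention_fractions`, `outcomes`, `periods`,
#'   `zero_cost_floor`, `out_of_fold`, and the stage-one list `stage_one`
#'   (`folds`, `max_trees`, `interaction_depth`, `min_leaf`,
#'   `learning_rate`).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    input = NULL,
    outdir = "distillation-results",
    seed = 1L,
    retention_fractions = c(1.00, 0.80, 0.60, 0.40, 0.25),
    outcomes = OUTCOMES_ALL,
    periods = FOLLOWUPS,
    zero_cost_floor = 1,
    out_of_fold = FALSE,
    stage_one = list(folds = 10L, max_trees = 10000L, interaction_depth = 2L,
                     min_leaf = 8L, learning_rate = 0.001)
  )
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots))) {
    dots <- dots[[1]]
  }
  bad <- setdiff(names(dots), c(names(cfg)))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(dots)) {
    if (nm == "stage_one") {
      cfg$stage_one[names(dots$stage_one)] <- dots$stage_one
    } else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' @rdname analysis_config
#' @param path YAML file written by [write_analysis_config()] or by hand.
#' @export
read_analysis_config <- function(path) {
  analysis_config(yaml::read_yaml(path))
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_stage <- function(con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full distillation analysis workflow
#'
#' Reads a subject-level trial table, executes the three stages via
#' [distill()], and writes every artifact with deterministic names into the
#' output directory: `scores.csv`, `ladder.csv`, `effects.csv`,
#' `config.yaml` (the effective configuration), `metrics.yaml` (stage-one
#' AUC and fit counts) and `run.log`. Per-cell non-convergence is recorded
#' in the effects table, not raised as an error.
#'
#' @param config an [analysis_config()] (or path to its YAML file).
#' @param input optional trial-table path overriding `config$input`.
#' @return the [distill()] result, invisibly; attribute `outdir` names the
#'   results directory.
#' @export
run_analysis <- function(config = analysis_config(), input = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(input)) config$input <- input
  if (is.null(config$input)) stop("no input trial table configured", call. = FALSE)
  if (!file.exists(config$input)) {
    stop("input file not found: ", config$input, call. = FALSE)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logfile))

  trial <- read_trial_table(config$input)
  log_stage(logfile, "input: %d subjects, %d covariates from %s",
            nrow(trial$data), nrow(trial$covariate_schema), config$input)
  s1 <- config$stage_one
  ans <- distill(trial,
                 fractions = config$retention_fractions,
                 outcomes = config$outcomes,
                 periods = config$periods,
                 folds = s1$folds, max_trees = s1$max_trees,
                 interaction_depth = s1$interaction_depth,
                 min_leaf = s1$min_leaf, learning_rate = s1$learning_rate,
                 out_of_fold = config$out_of_fold,
                 zero_cost_floor = config$zero_cost_floor,
                 seed = config$seed)
  log_stage(logfile, "stage 1: scored %d subjects, CV AUC %.4f, %d trees",
            nrow(ans$scores), ans$participation$auc,
            ans$participation$n_trees_selected)
  log_stage(logfile, "stage 2: %d levels, retained counts %s",
            length(ans$ladder),
            paste(vapply(ans$ladder, function(l) length(l$retained_ids), 1L),
                  collapse = ","))
  log_stage(logfile, "stage 3: %d fits, %d converged, %d fallback",
            nrow(ans$effects), sum(ans$effects$converged),
            sum(ans$effects$fallback_used))

  write_score_table(ans$scores, file.path(config$outdir, "scores.csv"))
  write_ladder(ans$ladder, file.path(config$outdir, "ladder.csv"))
  write_outcome_grid(ans$effects, file.path(config$outdir, "effects.csv"))
  write_analysis_config(config, file.path(config$outdir, "config.yaml"))
  yaml::write_yaml(list(
    auc_cv = ans$participation$auc,
    auc_insample = ans$participation$auc_insample,
    n_trees_selected = ans$participation$n_trees_selected,
    n_fits = nrow(ans$effects),
    n_converged = sum(ans$effects$converged),
    n_fallback = sum(ans$effects$fallback_used)
  ), file.path(config$outdir, "metrics.yaml"))
  attr(ans, "outdir") <- config$outdir
  invisible(ans)
}

#' Run the power-simulation workflow
#'
#' Evaluates a [sim_scenario()] with [estimate_power_grid()] and writes
#' `power_grid.csv`, a reproducibility manifest (`manifest.yaml`: seed,
#' replicates, package and R versions) and, optionally, a static plot.
#'
#' @param scenario a [sim_scenario()], or a YAML file of scenario fields.
#' @param outdir output directory.
#' @param plot also write `power_grid.pdf`.
#' @return the `power_grid`, invisibly.
#' @export
run_simulation <- function(scenario, outdir = "power-results", plot = FALSE) {
  if (is.character(scenario)) {
    fields <- yaml::read_yaml(scenario)
    scenario <- do.call(sim_scenario, fields)
  }
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logfile))
  log_stage(logfile, "simulation: %d taumax value(s) x %d retention level(s), %d reps, n_per_arm %d",
            length(scenario$taumax), length(scenario$retention_grid),
            scenario$reps, scenario$n_per_arm)
  grid <- estimate_power_grid(scenario)
  log_stage(logfile, "grid complete: %d cells, %d skipped replicate cell(s)",
            nrow(grid), sum(grid$n_skipped))
  write_power_grid(grid, file.path(outdir, "power_grid.csv"))
  yaml::write_yaml(list(
    seed = scenario$seed, reps = scenario$reps,
    n_per_arm = scenario$n_per_arm,
    taumax = scenario$taumax,
    retention_grid = scenario$retention_grid,
    correlations = list(te_part = scenario$rho_te_part,
                        te_pred = scenario$rho_te_pred,
                        part_pred = scenario$rho_part_pred),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("rctdistill"))
  ), file.path(outdir, "manifest.yaml"))
  if (plot) {
    grDevices::pdf(file.path(outdir, "power_grid.pdf"), width = 7, height = 5)
    plot(grid, alpha = scenario$alpha)
    grDevices::dev.off()
  }
  invisible(grid)
}
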