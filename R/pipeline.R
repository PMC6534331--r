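## End-to-end orchestration: (optional) STDP validation stage, CBGT
## simulation, striatal feature extraction, DDM fitting / model search,
## condition posteriors, and posterior-predictive simulation.

#' Configuration of a full pipeline run
#'
#' @param n_trials trials per reward condition for the CBGT stage
#' @param scale population-size scale factor
#' @param seed master seed, recorded in all outputs
#' @param stages named logical toggles: `learn`, `simulate`, `features`,
#'   `fit`, `search`, `predictive`
#' @param n_samples,burn MCMC settings for the fitting stages
#' @param stdp_realizations realizations for the learning validation stage
#' @param n_predictive posterior-predictive trials per condition
#' @param out_dir optional directory for CSV outputs
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_trials = 200, scale = 1, seed = 1,
                            stages = c(learn = FALSE, simulate = TRUE,
                                       features = TRUE, fit = TRUE,
                                       search = FALSE, predictive = TRUE),
                            n_samples = 2000, burn = 1200,
                            stdp_realizations = 8, n_predictive = 20000,
                            out_dir = NULL) {
  stopifnot(scale > 0, scale <= 1)
  structure(list(n_trials = n_trials, scale = scale, seed = seed,
                 stages = stages, n_samples = n_samples, burn = burn,
                 stdp_realizations = stdp_realizations,
                 n_predictive = n_predictive, out_dir = out_dir),
            class = "pipeline_config")
}

#' Convert a CBGT experiment into a DDM behaviour table
#'
#' Maps the L choice to the upper boundary and converts RTs to seconds.
#' Undecided trials are dropped. If striatal summaries are supplied their
#' regressor columns are merged in.
#'
#' @param experiment a `cbgt_experiment`
#' @param summaries optional [striatal_summaries()] output
#' @return behaviour table for [ddm_fit()]
#' @export
experiment_to_behavior <- function(experiment, summaries = NULL) {
  trials <- if (inherits(experiment, "cbgt_experiment")) experiment$trials
  else experiment
  d <- trials[!is.na(trials$choice) & trials$choice != "none", ,
              drop = FALSE]
  out <- data.frame(condition = d$condition,
                    response = ifelse(d$choice == "L", "upper", "lower"),
                    rt = d$rt_ms / 1000,
                    stringsAsFactors = FALSE)
  if (!is.null(summaries)) {
    key <- paste(d$condition, d$trial)
    skey <- paste(summaries$condition, summaries$trial)
    idx <- match(key, skey)
    for (cc in c("d_diff", "d_minus_i", "i_diff", "i_all")) {
      out[[cc]] <- summaries[[cc]][idx]
    }
    out <- out[complete.cases(out), , drop = FALSE]
  }
  out
}

#' Run the full multi-level pipeline
#'
#' Stage order: STDP learning validation (optional), CBGT simulation across
#' the three reward conditions, striatal feature extraction, a
#' condition-drift DDM fit (and optionally the stepwise model search),
#' condition posteriors, and posterior-predictive simulation from the
#' fitted model. A stage failure halts the run with a stage-named error;
#' results of completed stages are preserved in the returned report.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_report` with one element per completed
#'   stage plus `seed` and `config`
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config, seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  st <- config$stages
  if (isTRUE(st[["learn"]])) {
    report$learning <- stage("learn", {
      lapply(c(0.65, 0.75, 0.85), function(pl)
        run_learning(p_L = pl, n_realizations = config$stdp_realizations,
                     seed = config$seed))
    })
  }
  if (isTRUE(st[["simulate"]])) {
    report$experiment <- stage("simulate", {
      net <- build_cbgt_network(cbgt_config(scale = config$scale),
                                seed = config$seed)
      run_experiment(net, n_trials = config$n_trials, seed = config$seed)
    })
    report$behavior_summary <- summarize_behavior(report$experiment,
                                                  seed = config$seed)
  }
  if (isTRUE(st[["features"]]) && !is.null(report$experiment)) {
    report$summaries <- stage("features",
                              striatal_summaries(report$experiment))
    report$behavior_regressions <- stage("features",
                                         regress_behavior(report$summaries))
  }
  if (isTRUE(st[["fit"]]) && !is.null(report$experiment)) {
    behavior <- experiment_to_behavior(report$experiment, report$summaries)
    report$drift_fit <- stage("fit", {
      ddm_fit(behavior, ddm_model(free = "v"),
              n_samples = config$n_samples, burn = config$burn,
              seed = config$seed)
    })
    report$condition_drift <-
      posterior_to_condition_params(report$drift_fit)$v$summary
  }
  if (isTRUE(st[["search"]]) && !is.null(report$summaries)) {
    behavior <- experiment_to_behavior(report$experiment, report$summaries)
    report$search <- stage("search", {
      stepwise_search(behavior, n_samples = config$n_samples,
                      burn = config$burn, seed = config$seed)
    })
  }
  if (isTRUE(st[["predictive"]]) && !is.null(report$drift_fit)) {
    report$predictive <- stage("predictive", {
      fit <- report$drift_fit
      cm <- coef(fit)
      conds <- fit$cond_levels
      sims <- lapply(conds, function(cc) {
        v <- cm[sprintf("v[%s]", cc)]
        sim <- simulate_ddm(config$n_predictive, a = cm[["a"]], v = v,
                            z_rel = cm[["z"]], tr = cm[["tr"]],
                            seed = config$seed)
        data.frame(condition = cc,
                   acc_pct = 100 * mean(sim$response == "upper",
                                        na.rm = TRUE),
                   mean_rt_s = mean(sim$rt[sim$response == "upper"],
                                    na.rm = TRUE))
      })
      do.call(rbind, sims)
    })
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$experiment)) {
      write.csv(report$experiment$trials,
                file.path(config$out_dir, "trials.csv"), row.names = FALSE)
    }
    if (!is.null(report$summaries)) {
      write.csv(report$summaries,
                file.path(config$out_dir, "striatal_summaries.csv"),
                row.names = FALSE)
    }
    if (!is.null(report$behavior_summary)) {
      write.csv(report$behavior_summary,
                file.path(config$out_dir, "behavior_summary.csv"),
                row.names = FALSE)
    }
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("CBGT-DDM pipeline report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$behavior_summary)) {
    cat("\nBehaviour by condition:\n")
    print(x$behavior_summary[, c("condition", "n", "acc_pct", "mean_rt_ms",
                                 "rt_skew")])
  }
  if (!is.null(x$condition_drift)) {
    cat("\nPosterior-mean drift by condition:\n")
    print(x$condition_drift)
  }
  if (!is.null(x$search)) print(x$search)
  invisible(x)
}
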