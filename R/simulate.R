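## Trial simulation and experiment orchestration for the CBGT network.

.kernel_opts <- function(config) {
  list(dt_ms = config$dt_ms, t_max_ms = config$t_max_ms,
       delay_ms = config$delay_ms, threshold_hz = config$threshold_hz,
       rate_window_ms = as.integer(config$rate_window_ms),
       stim_ramp_ms = config$stim_ramp_ms %||% 300,
       decide_pops = NULL,  # filled per network
       tau_ampa = 2, tau_gaba = 5, tau_nmda = 100, alpha_nmda = 0.63,
       VE = 0, VI = -70)
}

#' Simulate one decision trial of the CBGT network
#'
#' Draws a stimulus rate from the truncated normal (unless supplied),
#' applies it identically to the L and R cortical populations from stimulus
#' onset as independent Poisson trains, integrates the network, and decides
#' by the first action channel whose thalamic population rate (sliding
#' window) reaches the 30 Hz threshold. A trial that times out is recorded
#' as `choice = "none"`. The reported RT is the absolute crossing time
#' within the trial (stimulus onset at 200 ms is included). In the
#' measure-zero event that both channels cross within the same millisecond,
#' the L channel is checked first.
#'
#' @param net a [build_cbgt_network()] result, usually after
#'   [apply_reward_condition()]
#' @param seed integer seed for this trial's stochasticity
#' @param stim_rate_hz optional fixed stimulus rate (Hz); 0 disables drive
#' @return object of class `cbgt_trial`: `choice` (`"L"`, `"R"`, `"none"`),
#'   `rt_ms`, `stimulus_rate_hz`, and `rate_traces` (population x 1-ms-bin
#'   firing rates, Hz per neuron)
#' @export
run_trial <- function(net, seed = NULL, stim_rate_hz = NULL) {
  stopifnot(inherits(net, "cbgt_network"))
  config <- net$config
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(stim_rate_hz)) {
    stim_rate_hz <- rtruncnorm(1, config$stim_mean_hz, config$stim_sd_hz,
                               config$stim_lo_hz, config$stim_hi_hz)
  }
  stim_vec <- ifelse(net$pop_names %in% c("Ctx_L", "Ctx_R"),
                     stim_rate_hz * config$stim_fan_in, 0)
  cv <- config$bg_trial_cv %||% 0
  if (cv > 0) {
    m <- rtruncnorm(1, 1, cv, max(1 - 3 * cv, 0.05), 1 + 3 * cv)
    ctx <- net$region_of == "Ctx"
    net$bg_rate_hz[ctx] <- net$bg_rate_hz[ctx] * m
  }
  opts <- .kernel_opts(config)
  opts$decide_pops <- as.integer(c(which(net$pop_names == "Th_L"),
                                   which(net$pop_names == "Th_R")) - 1L)
  res <- cbgt_trial_cpp(net, stim_vec, config$stim_g, config$stim_onset_ms,
                        opts)
  n_of <- vapply(net$pops, `[[`, 0L, "n")
  rates <- res$spike_bins / (n_of * 1e-3)
  rownames(rates) <- net$pop_names
  choice <- c("none", "L", "R")[res$choice + 1L]
  structure(list(choice = choice,
                 rt_ms = if (choice == "none") NA_real_ else res$rt_ms,
                 stimulus_rate_hz = stim_rate_hz,
                 rate_traces = rates, t_end_ms = res$t_end, seed = seed),
            class = "cbgt_trial")
}

#' @export
print.cbgt_trial <- function(x, ...) {
  cat("CBGT trial: choice =", x$choice,
      if (!is.na(x$rt_ms)) sprintf("(RT %.0f ms)", x$rt_ms) else "(timeout)",
      sprintf("| stimulus %.3f Hz\n", x$stimulus_rate_hz))
  invisible(x)
}

#' Run a batch of CBGT trials across reward conditions
#'
#' Iterates [run_trial()] with per-trial seeds derived from the master seed
#' (so the same `(network, seed)` pair reproduces the identical trial
#' table), applying each reward condition in turn. Trial-level errors are
#' caught, logged in the table, and do not abort the batch.
#'
#' @param net a baseline [build_cbgt_network()] result
#' @param conditions character vector of reward conditions
#' @param n_trials trials per condition
#' @param seed master seed
#' @param keep_traces keep per-trial rate traces (needed for the striatal
#'   summary regressors)
#' @param progress print progress every 25 trials
#' @return object of class `cbgt_experiment` with `trials` (data.frame:
#'   `condition`, `trial`, `choice`, `rt_ms`, `stimulus_rate_hz`, `seed`)
#'   and `traces` (nested list by condition then trial)
#' @export
run_experiment <- function(net, conditions = c("low", "med", "high"),
                           n_trials = 100, seed = 1, keep_traces = TRUE,
                           progress = FALSE) {
  stopifnot(inherits(net, "cbgt_network"), n_trials >= 0)
  seeds <- if (n_trials > 0) {
    matrix(derive_seeds(seed, n_trials * length(conditions)),
           nrow = n_trials)
  } else {
    matrix(integer(0), nrow = 0, ncol = length(conditions))
  }
  rows <- list()
  traces <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    net_c <- apply_reward_condition(net, cond)
    cond_traces <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      res <- tryCatch(run_trial(net_c, seed = seeds[tr, ci]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("trial %d (%s) failed: %s", tr, cond,
                        conditionMessage(res)))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, trial = tr, choice = NA_character_,
          rt_ms = NA_real_, stimulus_rate_hz = NA_real_,
          seed = seeds[tr, ci], stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, trial = tr, choice = res$choice,
        rt_ms = res$rt_ms, stimulus_rate_hz = res$stimulus_rate_hz,
        seed = seeds[tr, ci], stringsAsFactors = FALSE)
      if (keep_traces) cond_traces[[tr]] <- res$rate_traces
      if (progress && tr %% 25 == 0) {
        message(sprintf("  %s: trial %d / %d", cond, tr, n_trials))
      }
    }
    traces[[cond]] <- cond_traces
  }
  trials <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(condition = character(0), trial = integer(0),
               choice = character(0), rt_ms = numeric(0),
               stimulus_rate_hz = numeric(0), seed = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(trials = trials, traces = if (keep_traces) traces else NULL,
                 conditions = conditions, n_trials = n_trials, seed = seed,
                 onset_ms = net$config$stim_onset_ms),
            class = "cbgt_experiment")
}

#' @export
print.cbgt_experiment <- function(x, ...) {
  cat("CBGT experiment:", nrow(x$trials), "trials across",
      length(x$conditions), "conditions\n")
  if (nrow(x$trials)) print(summarize_behavior(x, n_boot = 200))
  invisible(x)
}

#' Behavioural summaries with bootstrap confidence intervals
#'
#' Accuracy is the percentage of trials on which the L (higher-reward)
#' action was chosen; RT summaries are computed on correct (L-choice) trials
#' only, as absolute crossing times within the trial. Undecided trials are
#' counted but excluded from both measures. CIs are percentile bootstrap
#' intervals.
#'
#' @param x a `cbgt_experiment` or a trial table data.frame
#' @param n_boot bootstrap resamples
#' @param seed seed for the bootstrap
#' @param conf confidence level
#' @return data.frame with one row per condition
#' @export
summarize_behavior <- function(x, n_boot = 2000, seed = 1, conf = 0.95) {
  trials <- if (inherits(x, "cbgt_experiment")) x$trials else x
  stopifnot(is.data.frame(trials), n_boot >= 1)
  set.seed(seed)
  al <- (1 - conf) / 2
  conds <- unique(trials$condition)
  out <- lapply(conds, function(cond) {
    d <- trials[trials$condition == cond, , drop = FALSE]
    dec <- d[!is.na(d$choice) & d$choice != "none", , drop = FALSE]
    if (nrow(dec) == 0) {
      warning("no decided trials in condition ", cond)
      return(data.frame(condition = cond, n = nrow(d), n_decided = 0,
                        acc_pct = NA_real_, acc_lo = NA_real_,
                        acc_hi = NA_real_, mean_rt_ms = NA_real_,
                        rt_lo = NA_real_, rt_hi = NA_real_,
                        rt_skew = NA_real_))
    }
    correct <- dec$choice == "L"
    rts <- dec$rt_ms[correct]
    acc_boot <- vapply(seq_len(n_boot), function(b)
      100 * mean(sample(correct, replace = TRUE)), 0)
    rt_boot <- if (length(rts) >= 2) {
      vapply(seq_len(n_boot), function(b)
        mean(sample(rts, replace = TRUE)), 0)
    } else rep(NA_real_, 2)
    skew <- if (length(rts) >= 3) {
      m <- mean(rts); s <- sd(rts)
      mean((rts - m)^3) / s^3
    } else NA_real_
    data.frame(condition = cond, n = nrow(d), n_decided = nrow(dec),
               acc_pct = 100 * mean(correct),
               acc_lo = unname(quantile(acc_boot, al)),
               acc_hi = unname(quantile(acc_boot, 1 - al)),
               mean_rt_ms = mean(rts),
               rt_lo = unname(quantile(rt_boot, al, na.rm = TRUE)),
               rt_hi = unname(quantile(rt_boot, 1 - al, na.rm = TRUE)),
               rt_skew = skew)
  })
  do.call(rbind, out)
}

#' Calibrate background drives against target tonic rates
#'
#' Runs repeated short stimulus-free simulations and multiplicatively
#' adjusts each population's background Poisson rate toward the target
#' pre-stimulus firing rates. This is how the package's default background
#' rates were derived; it is exposed so the calibration can be re-run under
#' modified connectivity.
#'
#' @param config a [cbgt_config()]
#' @param targets named per-region target tonic rates (Hz)
#' @param n_iter calibration iterations
#' @param t_sim_ms duration of each probe simulation (rates measured over
#'   its second half)
#' @param seed integer seed
#' @param gain multiplicative adjustment exponent in (0, 1]
#' @return the config with updated `bg_rate_hz`, plus attribute `history`
#' @export
calibrate_background <- function(config = cbgt_config(),
                                 targets = c(Ctx = 3, CtxI = 10, dMSN = 2,
                                             iMSN = 3, FSI = 12, GPe = 65,
                                             STN = 15, GPi = 70, Th = 8),
                                 n_iter = 30, t_sim_ms = 1000, seed = 1,
                                 gain = 0.3, max_step = 1.25) {
  stopifnot(inherits(config, "cbgt_config"))
  probe_cfg <- config
  probe_cfg$t_max_ms <- t_sim_ms
  probe_cfg$threshold_hz <- 1e9   # never decide during calibration probes
  net <- build_cbgt_network(probe_cfg, seed = seed)
  history <- list()
  measure <- seq(max(1, t_sim_ms - 400), t_sim_ms - 1)
  for (it in seq_len(n_iter)) {
    tr <- run_trial(net, seed = seed + 100 + it, stim_rate_hz = 0)
    rates <- rowMeans(tr$rate_traces[, measure, drop = FALSE])
    region_rates <- tapply(rates, net$region_of, mean)
    adj <- (targets[names(region_rates)] /
              pmax(region_rates, 0.3))^gain
    adj <- pmin(pmax(adj, 1 / max_step), max_step)
    probe_cfg$bg_rate_hz[names(region_rates)] <-
      probe_cfg$bg_rate_hz[names(region_rates)] * adj
    net$bg_rate_hz <- as.numeric(probe_cfg$bg_rate_hz[net$region_of])
    history[[it]] <- region_rates
  }
  config$bg_rate_hz <- probe_cfg$bg_rate_hz
  attr(config, "history") <- history
  config
}
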