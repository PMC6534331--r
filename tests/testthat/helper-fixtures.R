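# Shared fixtures, computed lazily and cached for the whole test run.
# The CBGT batch is the expensive one (full-size network, 200 trials per
# reward condition); every test that needs network behaviour reuses it.

.fixture_env <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Full-scale CBGT experiment under the three reward conditions.
cbgt_batch <- function(n_trials = 200) {
  .cached("cbgt_batch", {
    net <- build_cbgt_network(cbgt_config(), seed = 7)
    run_experiment(net, n_trials = n_trials, seed = 2024,
                   keep_traces = TRUE)
  })
}

cbgt_summaries <- function() {
  .cached("cbgt_summaries", suppressMessages(striatal_summaries(cbgt_batch())))
}

cbgt_behavior_table <- function() {
  .cached("cbgt_behavior", {
    experiment_to_behavior(cbgt_batch(), cbgt_summaries())
  })
}

cbgt_behavior_summary <- function() {
  .cached("cbgt_behavior_summary", summarize_behavior(cbgt_batch(), seed = 1))
}

# Regression-structured synthetic dataset (model III ground truth).
synthetic_reg_batch <- function() {
  .cached("synthetic_reg", {
    generate_dataset(synthetic_design(trials_per_cond = 300), seed = 91)
  })
}

# Fixed-parameter synthetic dataset for recovery tests.
synthetic_flat_batch <- function(n = 2000) {
  .cached("synthetic_flat", {
    des <- synthetic_design(
      conditions = "one", trials_per_cond = n,
      beta_v = 0, beta_a = 0,
      regressor_means = list(d_diff = 0.3, d_minus_i = 0.3, i_diff = 0.3,
                             i_all = 0.5),
      params_by_cond = list(list(a = 1.2, v = 1.5, z_rel = 0.45,
                                 tr = 0.25)))
    generate_dataset(des, seed = 97)
  })
}

# Tiny CBGT experiment object with hand-built traces, for feature tests
# that need exact control over the rate curves.
fake_experiment <- function(rts, choices, conds, trace_maker) {
  n <- length(rts)
  trials <- data.frame(condition = conds, trial = ave(seq_len(n), conds,
                                                      FUN = seq_along),
                       choice = choices, rt_ms = rts,
                       stimulus_rate_hz = 2.5, seed = seq_len(n),
                       stringsAsFactors = FALSE)
  traces <- list()
  for (i in seq_len(n)) {
    traces[[conds[i]]][[trials$trial[i]]] <- trace_maker(i)
  }
  structure(list(trials = trials, traces = traces,
                 conditions = unique(conds), n_trials = max(trials$trial),
                 seed = 1, onset_ms = 200),
            class = "cbgt_experiment")
}
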