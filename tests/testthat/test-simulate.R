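# Trial simulation and behavioural summaries (fast checks on reduced-scale
# networks; full-scale behaviour is covered by the acceptance suite).

test_that("experiments honour the empty-batch schema and determinism", {
  net <- build_cbgt_network(cbgt_config(scale = 0.1, t_max_ms = 320),
                            seed = 2)
  ex0 <- run_experiment(net, n_trials = 0)
  expect_equal(nrow(ex0$trials), 0)
  expect_setequal(names(ex0$trials),
                  c("condition", "trial", "choice", "rt_ms",
                    "stimulus_rate_hz", "seed"))
  ex1 <- run_experiment(net, conditions = "high", n_trials = 2, seed = 5,
                        keep_traces = FALSE)
  ex2 <- run_experiment(net, conditions = "high", n_trials = 2, seed = 5,
                        keep_traces = FALSE)
  expect_identical(ex1$trials, ex2$trials)
})

test_that("zero external drive never triggers a decision", {
  # full-size network: baseline thalamic rates sit far below the 30 Hz
  # threshold, so a stimulus-free trial times out undecided
  net <- build_cbgt_network(cbgt_config(t_max_ms = 700), seed = 4)
  tr <- run_trial(net, seed = 6, stim_rate_hz = 0)
  expect_equal(tr$choice, "none")
  expect_true(is.na(tr$rt_ms))
})

test_that("rate traces carry all populations on a 1 ms grid", {
  net <- build_cbgt_network(cbgt_config(scale = 0.1, t_max_ms = 300),
                            seed = 4)
  tr <- run_trial(net, seed = 8)
  expect_equal(nrow(tr$rate_traces), 16)
  expect_equal(ncol(tr$rate_traces), 300)
  expect_true(all(c("dMSN_L", "iMSN_R", "Th_L", "GPi_R") %in%
                    rownames(tr$rate_traces)))
  expect_true(all(tr$rate_traces >= 0))
})

test_that("stimulus draws respect the truncated-normal bounds", {
  set.seed(10)
  draws <- rtruncnorm(4000, 2.5, 0.06, 2.4, 2.6)
  expect_true(all(draws >= 2.4 & draws <= 2.6))
  expect_equal(mean(draws), 2.5, tolerance = 0.01)
  # truncation at +/- 5/3 sigma shrinks the sd of the parent normal
  b <- 5 / 3
  sd_trunc <- 0.06 * sqrt(1 - 2 * b * dnorm(b) / (2 * pnorm(b) - 1))
  expect_equal(sd(draws), sd_trunc, tolerance = 0.05)
})

test_that("behaviour summaries handle degenerate tables exactly", {
  toy <- data.frame(condition = "high", trial = 1:6, choice = "L",
                    rt_ms = 450, stimulus_rate_hz = 2.5, seed = 1:6,
                    stringsAsFactors = FALSE)
  s <- summarize_behavior(toy, n_boot = 200)
  expect_equal(s$acc_pct, 100)
  expect_equal(c(s$acc_lo, s$acc_hi), c(100, 100))
  # bootstrap of a constant RT column has zero width
  expect_equal(s$rt_lo, s$rt_hi)
  expect_equal(s$mean_rt_ms, 450)
})

test_that("bootstrap accuracy intervals achieve nominal coverage", {
  set.seed(12)
  p_true <- 0.7
  covered <- 0
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    ch <- ifelse(runif(80) < p_true, "L", "R")
    toy <- data.frame(condition = "c", trial = seq_along(ch), choice = ch,
                      rt_ms = 450, stimulus_rate_hz = 2.5,
                      seed = seq_along(ch), stringsAsFactors = FALSE)
    s <- summarize_behavior(toy, n_boot = 400, seed = r)
    if (s$acc_lo <= 100 * p_true && 100 * p_true <= s$acc_hi) {
      covered <- covered + 1
    }
  }
  expect_gt(covered / n_rep, 0.85)
  expect_lt(covered / n_rep, 1)
})

test_that("undecided conditions produce an NA row with a warning", {
  toy <- data.frame(condition = "x", trial = 1:3, choice = "none",
                    rt_ms = NA_real_, stimulus_rate_hz = 2.5, seed = 1:3,
                    stringsAsFactors = FALSE)
  expect_warning(s <- summarize_behavior(toy, n_boot = 50), "no decided")
  expect_true(is.na(s$acc_pct))
  expect_equal(s$n, 3)
})

test_that("behaviour tables map L to the upper boundary in seconds", {
  toy <- data.frame(condition = c("a", "a", "a"), trial = 1:3,
                    choice = c("L", "R", "none"),
                    rt_ms = c(400, 500, NA), stimulus_rate_hz = 2.5,
                    seed = 1:3, stringsAsFactors = FALSE)
  b <- experiment_to_behavior(toy)
  expect_equal(nrow(b), 2)
  expect_equal(b$response, c("upper", "lower"))
  expect_equal(b$rt, c(0.4, 0.5))
})
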