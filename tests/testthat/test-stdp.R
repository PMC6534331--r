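# Reduced striatal learning network: daughter-train thinning, STDP
# eligibility, the dopamine/weight update, the spike-count selection rule,
# and short learning runs.

test_that("daughter thinning preserves and deletes spikes at the limits", {
  set.seed(1)
  mother <- sort(runif(500, 0, 10000))
  expect_identical(generate_daughter_trains(mother, 1, 2)[[1]], mother)
  expect_length(generate_daughter_trains(mother, 0, 1)[[1]], 0)
})

test_that("daughter rate approaches p times the mother rate", {
  set.seed(2)
  mother <- generate_mother_train(300, 0.5, 8, 60000)
  d <- generate_daughter_trains(mother, 0.6, 20)
  rates <- vapply(d, function(x) length(x) / 60, 0)
  expect_equal(mean(rates), 0.6 * length(mother) / 60, tolerance = 0.03)
})

test_that("mother train has the requested mean rate and oscillation", {
  set.seed(3)
  m <- generate_mother_train(200, 0.8, 8, 120000)
  expect_equal(length(m) / 120, 200, tolerance = 0.05)
  # spike density should peak near the oscillation crests
  phase <- (m / 1000 * 8) %% 1
  top <- mean(phase > 0.05 & phase < 0.45)   # sin > 0 quarter-cycles
  expect_gt(top, 0.45)
})

test_that("eligibility decays without spikes and tracks single pairings", {
  expect_equal(stdp_eligibility_update(2, numeric(0), numeric(0),
                                       tau_elig = 300, t_end = 300),
               2 * exp(-1))
  # one pre spike at 0, one post at 10 ms: potentiation A+ exp(-10/tau+)
  e <- stdp_eligibility_update(0, pre_spikes = 0, post_spikes = 10,
                               A_plus = 1, A_minus = 1, tau_plus = 20,
                               tau_minus = 20, tau_elig = 1e9)
  expect_equal(e, exp(-10 / 20), tolerance = 1e-12)
})

test_that("symmetric kernels cancel over symmetric pair orderings", {
  # pre at 0 & 30, post at 15: +A exp(-15/tau) then -A exp(-15/tau)
  e <- stdp_eligibility_update(0, pre_spikes = c(0, 30), post_spikes = 15,
                               A_plus = 1, A_minus = 1, tau_plus = 20,
                               tau_minus = 20, tau_elig = 1e12)
  expect_equal(e, 0, tolerance = 1e-9)
})

test_that("weight updates gate on eligibility and prediction error", {
  p <- stdp_params()
  expect_equal(dopamine_and_weight_update(5, 0, 1, c(0.2, 0.1), "dMSN",
                                          p)$w, 5)
  r <- dopamine_and_weight_update(5, 2, 0.4, c(0.4, 0.1), "dMSN", p)
  expect_equal(r$DA, 0)
  expect_equal(r$w, 5)
  up <- dopamine_and_weight_update(5, 2, 1, c(0.2, 0.1), "dMSN", p)
  expect_gt(up$w, 5)
  dn <- dopamine_and_weight_update(5, 2, 1, c(0.2, 0.1), "iMSN", p)
  expect_lt(dn$w, 5)     # opposite-signed iMSN gain
  # clipping
  expect_equal(dopamine_and_weight_update(p$w_max, 100, 1, c(0, 0), "dMSN",
                                          p)$w, p$w_max)
})

test_that("selection needs three surviving dMSN spikes in the window", {
  expect_true(select_action(c(100, 104, 108), numeric(0))$selected)
  expect_false(select_action(c(100, 104), numeric(0))$selected)
  # an interleaved iMSN spike cancels the latest dMSN spike: the third
  # dMSN spike alone cannot complete the triple, a fourth can
  tr <- select_action(c(100, 104, 108), imsn_spikes = 105)
  expect_false(tr$selected)
  tr2 <- select_action(c(100, 104, 108, 109), imsn_spikes = 105)
  expect_true(tr2$selected)
  expect_equal(tr2$t_select, 109)
  # window expiry: spikes spread beyond 10 ms never accumulate
  expect_false(select_action(c(0, 20, 40, 60, 80), numeric(0))$selected)
})

test_that("short learning runs are deterministic, bounded, and active", {
  p <- stdp_params(duration_ms = 3000, n_per_pop = 8)
  r1 <- run_learning(p_L = 0.85, params = p, n_realizations = 2, seed = 21)
  r2 <- run_learning(p_L = 0.85, params = p, n_realizations = 2, seed = 21)
  expect_identical(r1$trajectory, r2$trajectory)
  w <- as.matrix(r1$trajectory[, c("dMSN_L", "iMSN_L", "dMSN_R", "iMSN_R")])
  expect_true(all(w >= 0 & w <= p$w_max))
  expect_gt(sum(r1$n_selections), 0)
  expect_true(all(r1$q_final >= 0 & r1$q_final <= 1))
})

test_that("Q values approach the reward probability of the chosen action", {
  p <- stdp_params(duration_ms = 10000, n_per_pop = 8)
  r <- run_learning(p_L = 0.85, params = p, n_realizations = 3, seed = 31)
  # Q_L heads toward p_L * r = 0.85 and dominates Q_R
  expect_gt(r$q_final["Q_L"], 0.3)
  expect_lt(r$q_final["Q_L"], 1)
  expect_gt(r$q_final["Q_L"], r$q_final["Q_R"])
})
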