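# Striatal summary statistics: AUC integration, pooled min-max
# normalization, summary composition, and the behaviour regressions.

test_that("AUC handles rectangles, zeros, and ramps exactly", {
  expect_equal(trial_auc(rep(10, 201), t0 = 50, t1 = 150), 1000)
  expect_equal(trial_auc(rep(0, 300), t0 = 0, t1 = 299), 0)
  ramp <- seq(0, 20, length.out = 101)   # 0 -> 20 Hz over 100 ms
  expect_equal(trial_auc(ramp, t0 = 0, t1 = 100), 20 * 100 / 2)
})

test_that("AUC is additive over adjacent windows and monotone", {
  set.seed(3)
  trace <- runif(400, 0, 40)
  whole <- trial_auc(trace, 20, 340)
  split <- trial_auc(trace, 20, 171) + trial_auc(trace, 171, 340)
  expect_equal(whole, split, tolerance = 1e-10)
  expect_gte(trial_auc(trace + 5, 20, 340), whole)
})

test_that("min-max normalization is exact and flags degenerate input", {
  expect_equal(normalize_unit(c(5, 15)), c(0, 1))
  x <- c(2, 9, 4, 7)
  expect_equal(normalize_unit(3 * x - 1), normalize_unit(x))
  expect_error(normalize_unit(rep(4, 5)), "degenerate")
})

test_that("summaries pool normalization across conditions and drop timeouts", {
  # traces: dMSN_L AUC grows with trial index; others fixed shapes
  maker <- function(i) {
    m <- matrix(0, 4, 600,
                dimnames = list(c("dMSN_L", "dMSN_R", "iMSN_L", "iMSN_R"),
                                NULL))
    m["dMSN_L", ] <- i * 2
    m["dMSN_R", ] <- 5
    m["iMSN_L", ] <- 10 + i
    m["iMSN_R", ] <- 12
    m
  }
  ex <- fake_experiment(rts = c(400, 450, 500, NA, 420, 480),
                        choices = c("L", "L", "R", "none", "L", "R"),
                        conds = rep(c("low", "high"), each = 3),
                        trace_maker = maker)
  expect_message(s <- striatal_summaries(ex), "undecided")
  expect_equal(nrow(s), 5)
  expect_true(all(s$i_all >= 0 & s$i_all <= 1))
  expect_true(all(abs(s$d_diff) <= 1))
  # pooled normalization: the largest dMSN_L AUC across *all* conditions is 1
  nd <- normalize_unit(s$auc_dL)
  expect_equal(max(nd), 1)
  expect_equal(s$d_diff, nd - normalize_unit(s$auc_dR))
})

test_that("null regressors give near-zero coefficients", {
  set.seed(44)
  n <- 400
  d <- data.frame(condition = "one", choice = sample(c("L", "R"), n, TRUE),
                  rt_ms = rnorm(n, 450, 40),
                  d_diff = runif(n), d_minus_i = runif(n),
                  i_diff = runif(n), i_all = runif(n),
                  stringsAsFactors = FALSE)
  r <- regress_behavior(d)
  cf <- r$choice_fit
  expect_lt(abs(cf$estimate[cf$term == "d_diff"]),
            2.5 * cf$se[cf$term == "d_diff"] + 0.2)
  rf <- r$rt_fit
  expect_lt(abs(rf$estimate[rf$term == "i_all"]),
            3 * rf$se[rf$term == "i_all"])
})

test_that("logistic coefficients are recovered from a known model", {
  set.seed(45)
  n <- 2500
  d_diff <- runif(n, -0.5, 0.5)
  d_minus_i <- runif(n, -0.5, 0.5)
  eta <- 0.3 + 4 * d_diff + 1.5 * d_minus_i
  choice <- ifelse(runif(n) < plogis(eta), "L", "R")
  d <- data.frame(condition = "one", choice = choice, rt_ms = 450,
                  d_diff = d_diff, d_minus_i = d_minus_i,
                  i_diff = runif(n), i_all = runif(n),
                  stringsAsFactors = FALSE)
  r <- regress_behavior(d)
  cf <- r$choice_fit
  est <- cf$estimate[cf$term == "d_diff"]
  se <- cf$se[cf$term == "d_diff"]
  expect_lt(abs(est - 4), 3 * se)
})

test_that("perfect separation falls back to a penalized fit", {
  set.seed(46)
  n <- 120
  d_diff <- seq(-1, 1, length.out = n)
  d <- data.frame(condition = "one",
                  choice = ifelse(d_diff > 0, "L", "R"),
                  rt_ms = rnorm(n, 450, 30),
                  d_diff = d_diff, d_minus_i = runif(n),
                  i_diff = runif(n), i_all = runif(n),
                  stringsAsFactors = FALSE)
  r <- regress_behavior(d)
  expect_true(r$penalized)
  expect_gt(r$choice_fit$estimate[r$choice_fit$term == "d_diff"], 0)
})
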