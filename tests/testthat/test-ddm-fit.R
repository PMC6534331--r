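# DDM likelihood assembly, MCMC fitting, DIC, and the posterior transform
# to per-condition parameters.

toy_table <- function() {
  data.frame(condition = c("x", "x", "y", "y", "y"),
             response = c("upper", "lower", "upper", "upper", "lower"),
             rt = c(0.5, 0.7, 0.45, 0.9, 0.6),
             d_diff = c(0.2, 0.4, 0.6, 0.1, 0.9),
             stringsAsFactors = FALSE)
}

test_that("log-likelihood equals the brute-force per-trial product", {
  d <- toy_table()
  model <- ddm_model()
  theta <- c(a = 1.3, v = 0.8, z = 0.45, tr = 0.2)
  ll <- ddm_loglik(theta, d, model)
  manual <- 0
  for (i in seq_len(nrow(d))) {
    manual <- manual + log(dwfpt(d$rt[i], 1.3, 0.8, 0.45, 0.2,
                                 boundary = d$response[i]))
  }
  expect_equal(as.numeric(ll), manual, tolerance = 1e-12)
})

test_that("zero regression slopes reproduce the shared-parameter model", {
  d <- toy_table()
  base <- ddm_loglik(c(a = 1.3, v = 0.8, z = 0.45, tr = 0.2), d,
                     ddm_model())
  reg <- ddm_loglik(c(a = 1.3, v_int = 0.8, `v_slope[x]` = 0,
                      `v_slope[y]` = 0, z = 0.45, tr = 0.2), d,
                    ddm_model(regress = list(v = "d_diff")))
  expect_equal(as.numeric(reg), as.numeric(base), tolerance = 1e-12)
})

test_that("a unit slope with zero intercept passes the regressor through", {
  d <- toy_table()
  d$d_diff <- 0.9   # constant regressor -> v = 0.9 on every trial
  reg <- ddm_loglik(c(a = 1.3, v_int = 0, `v_slope[x]` = 1,
                      `v_slope[y]` = 1, z = 0.45, tr = 0.2), d,
                    ddm_model(regress = list(v = "d_diff")))
  base <- ddm_loglik(c(a = 1.3, v = 0.9, z = 0.45, tr = 0.2), d,
                     ddm_model())
  expect_equal(as.numeric(reg), as.numeric(base), tolerance = 1e-12)
})

test_that("likelihood is -Inf for structurally impossible parameters", {
  d <- toy_table()
  expect_identical(as.numeric(ddm_loglik(
    c(a = 1.3, v = 0.8, z = 0.45, tr = 0.5), d, ddm_model())), -Inf)
  expect_identical(as.numeric(ddm_loglik(
    c(a = -1, v = 0.8, z = 0.45, tr = 0.1), d, ddm_model())), -Inf)
})

test_that("flat MCMC recovers generating parameters", {
  gen <- synthetic_flat_batch()
  fit <- ddm_fit(gen$data, ddm_model(), n_samples = 1200, burn = 700,
                 seed = 41)
  est <- coef(fit)
  truth <- c(a = 1.2, v = 1.5, z = 0.45, tr = 0.25)
  s <- summary(fit)
  for (p in names(truth)) {
    ci <- c(s[p, "q025"], s[p, "q975"])
    width <- ci[2] - ci[1]
    expect_lt(abs(est[[p]] - truth[[p]]), max(3 * width, 0.15 * truth[[p]]))
  }
})

test_that("MCMC chains are reproducible under a fixed seed", {
  d <- head(synthetic_flat_batch()$data, 120)
  f1 <- ddm_fit(d, ddm_model(), n_samples = 150, burn = 100, seed = 77)
  f2 <- ddm_fit(d, ddm_model(), n_samples = 150, burn = 100, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("DIC decomposition is internally consistent", {
  d <- head(synthetic_flat_batch()$data, 200)
  fit <- ddm_fit(d, ddm_model(), n_samples = 300, burn = 200, seed = 52)
  dic <- fit$dic
  expect_equal(dic$dic, dic$deviance_at_mean + 2 * dic$pD, tolerance = 1e-9)
  expect_equal(dic$dic, dic$mean_deviance + dic$pD, tolerance = 1e-9)
  expect_gt(dic$pD, 0)
  # a fit is its own null: delta = 0
  expect_equal(compute_dic(fit, null = fit)$delta_dic, 0, tolerance = 1e-9)
})

test_that("condition-parameter transform is the exact affine map", {
  d <- toy_table()
  d <- d[rep(1:5, 20), ]
  fit <- ddm_fit(d, ddm_model(regress = list(v = "d_diff")),
                 n_samples = 150, burn = 100, seed = 63)
  cm <- list(v = c(0.3, 0.6))
  post <- posterior_to_condition_params(fit, cm)
  b0 <- fit$draws[, "v_int"]
  for (j in 1:2) {
    expected <- mean(b0 + fit$draws[, sprintf("v_slope[%s]", c("x", "y")[j])] *
                       cm$v[j])
    expect_equal(unname(post$v$summary$mean[j]), expected, tolerance = 1e-12)
  }
  expect_error(posterior_to_condition_params(fit, NULL), "cond_means")
})

test_that("posterior-predictive simulation matches the fitted design", {
  d <- head(synthetic_flat_batch()$data, 150)
  fit <- ddm_fit(d, ddm_model(), n_samples = 150, burn = 100, seed = 9)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(d))
  expect_true(all(sims[[1]]$condition == d$condition))
})
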