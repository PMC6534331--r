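# Synthetic choice/RT generator: determinism, ground truth, and the
# statistical structure the DDM stage assumes.

test_that("generator is seed-deterministic and always emits ground truth", {
  des <- synthetic_design(trials_per_cond = 50)
  g1 <- generate_dataset(des, seed = 5)
  g2 <- generate_dataset(des, seed = 5)
  expect_identical(g1$data, g2$data)
  expect_s3_class(g1$truth$cond_param_means, "data.frame")
  expect_true(all(c("d_diff", "d_minus_i", "i_diff", "i_all") %in%
                    names(g1$data)))
  for (cc in c("d_diff", "d_minus_i", "i_diff", "i_all")) {
    expect_true(all(g1$data[[cc]] >= 0 & g1$data[[cc]] <= 1))
  }
})

test_that("null design is exchangeable across conditions", {
  des <- synthetic_design(trials_per_cond = 400, beta_v = c(0, 0, 0),
                          beta_a = c(0, 0, 0), beta0_v = 1.2, beta0_a = 1)
  g <- generate_dataset(des, seed = 15)
  rt_low <- g$data$rt[g$data$condition == "low"]
  rt_high <- g$data$rt[g$data$condition == "high"]
  ks <- suppressWarnings(stats::ks.test(rt_low, rt_high))
  expect_gt(ks$p.value, 0.01)
})

test_that("a positive drift slope couples the regressor to choice", {
  des <- synthetic_design(conditions = "one", trials_per_cond = 1500,
                          beta_v = 6, beta0_v = -2, beta_a = 0,
                          beta0_a = 1,
                          regressor_means = list(d_diff = 0.4,
                                                 d_minus_i = 0.4,
                                                 i_diff = 0.3, i_all = 0.5))
  g <- generate_dataset(des, seed = 25)
  fit <- glm(I(response == "upper") ~ d_diff, data = g$data,
             family = binomial())
  z <- summary(fit)$coefficients["d_diff", ]
  expect_gt(z["Estimate"], 0)
  expect_lt(z["Pr(>|z|)"], 0.01)
})

test_that("increasing condition drift yields rising accuracy and skewed RTs", {
  g <- synthetic_reg_batch()
  acc <- tapply(g$data$response == "upper", g$data$condition, mean)
  acc <- acc[c("low", "med", "high")]
  expect_true(all(diff(acc) > 0))
  for (cc in c("low", "med", "high")) {
    rts <- g$data$rt[g$data$condition == cc & g$data$response == "upper"]
    m <- mean(rts); s <- sd(rts)
    expect_gt(mean((rts - m)^3) / s^3, 0)
  }
})

test_that("zero between-subject spread duplicates the group truth", {
  des <- synthetic_design(trials_per_cond = 20)
  g <- generate_subjects(des, n_subjects = 4, sd_v = 0, sd_a = 0, seed = 8)
  expect_equal(length(unique(g$truth$beta0_v)), 1)
  expect_equal(length(unique(g$truth$beta0_a)), 1)
  expect_setequal(unique(g$data$subject), 1:4)
})

test_that("subject-level intercepts vary when spread is positive", {
  des <- synthetic_design(trials_per_cond = 10)
  g <- generate_subjects(des, n_subjects = 6, sd_v = 0.5, sd_a = 0.05,
                         seed = 9)
  expect_gt(sd(g$truth$beta0_v), 0.05)
})
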