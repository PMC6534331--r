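# Wiener first-passage-time density: closed-form properties, normalization,
# and agreement with brute-force path simulation.

test_that("density is zero at and before the non-decision time", {
  expect_equal(dwfpt(c(0, 0.1, 0.2), a = 1, v = 1, z_rel = 0.5, tr = 0.2),
               c(0, 0, 0))
  expect_gt(dwfpt(0.25, a = 1, v = 1, z_rel = 0.5, tr = 0.2), 0)
})

test_that("zero drift with centred start point gives symmetric boundaries", {
  tt <- seq(0.21, 3, by = 0.03)
  lo <- dwfpt(tt, a = 1.3, v = 0, z_rel = 0.5, tr = 0.2, "lower")
  up <- dwfpt(tt, a = 1.3, v = 0, z_rel = 0.5, tr = 0.2, "upper")
  expect_equal(lo, up, tolerance = 1e-10)
})

test_that("upper-boundary density equals the reflected lower-boundary one", {
  tt <- seq(0.05, 2.5, by = 0.07)
  for (p in list(c(1, 2, 0.35, 0.02), c(0.6, -1.5, 0.7, 0.01),
                 c(2, 0.5, 0.5, 0.3))) {
    up <- dwfpt(tt, a = p[1], v = p[2], z_rel = p[3], tr = p[4], "upper")
    refl <- dwfpt(tt, a = p[1], v = -p[2], z_rel = 1 - p[3], tr = p[4],
                  "lower")
    expect_equal(up, refl, tolerance = 1e-12)
  }
})

test_that("lower + upper densities integrate to total probability one", {
  set.seed(11)
  for (i in 1:8) {
    a <- runif(1, 0.5, 2); v <- runif(1, -3, 3)
    z <- runif(1, 0.2, 0.8); tr <- runif(1, 0, 0.4)
    total <- integrate(function(t)
      dwfpt(t, a, v, z, tr, "lower") + dwfpt(t, a, v, z, tr, "upper"),
      tr, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(total - 1), 1e-4)
  }
})

test_that("boundary split matches the analytic absorption probability", {
  set.seed(12)
  for (i in 1:5) {
    a <- runif(1, 0.5, 2); v <- runif(1, -2, 2); z <- runif(1, 0.3, 0.7)
    p_up_int <- integrate(function(t) dwfpt(t, a, v, z, 0, "upper"),
                          0, Inf, rel.tol = 1e-9)$value
    expect_equal(p_up_int, ddm_choice_prob(v, a, z), tolerance = 1e-5)
  }
})

test_that("density matches Euler-Maruyama first-passage histograms", {
  a <- 1.1; v <- 1.4; z <- 0.45; tr <- 0.2
  sim <- simulate_ddm(20000, a, v, z, tr, dt = 1e-4, seed = 31)
  up <- sim$rt[sim$response == "upper"]
  p_up <- ddm_choice_prob(v, a, z)
  cdf <- function(q) vapply(q, function(qq) {
    if (qq <= tr) return(0)
    integrate(function(t) dwfpt(t, a, v, z, tr, "upper"), tr, qq,
              rel.tol = 1e-8)$value / p_up
  }, 0)
  ks <- suppressWarnings(stats::ks.test(up, cdf))
  # critical KS distance at alpha = 0.01 for this n, plus E-M bias allowance
  crit <- 1.63 / sqrt(length(up))
  expect_lt(unname(ks$statistic), crit + 0.01)
})

test_that("simulator respects drift limits and start-point symmetry", {
  s_hi <- simulate_ddm(300, a = 1, v = 40, z_rel = 0.5, tr = 0, seed = 4)
  expect_true(all(s_hi$response == "upper"))
  s_sym <- simulate_ddm(4000, a = 1, v = 0, z_rel = 0.5, tr = 0, seed = 5)
  p <- mean(s_sym$response == "upper")
  expect_gt(p, 0.47)
  expect_lt(p, 0.53)
})

test_that("per-trial parameter vectors are honoured by the simulator", {
  sim <- simulate_ddm(400, a = rep(c(0.4, 3), each = 200),
                      v = rep(c(8, 0.1), each = 200),
                      z_rel = 0.5, tr = c(0.1, 0.5), seed = 6)
  expect_true(mean(sim$rt[1:200]) < mean(sim$rt[201:400]))
  expect_true(mean(sim$response[1:200] == "upper") >
                mean(sim$response[201:400] == "upper"))
})
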