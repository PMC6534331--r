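# CBGT network construction: wiring realizations against the connectivity
# table, reward-condition scaling, and subject-network sampling.

small_cfg <- function() cbgt_config(scale = 0.2)

proj_find <- function(net, src_region, tgt_region, receptor,
                      src_channel = NULL, tgt_channel = NULL) {
  hits <- Filter(function(p) {
    p$src_region == src_region && p$tgt_region == tgt_region &&
      p$receptor == c(AMPA = 0, NMDA = 1, GABA = 2)[[receptor]] &&
      (is.null(src_channel) || p$src_channel == src_channel) &&
      (is.null(tgt_channel) || p$tgt_channel == tgt_channel)
  }, net$projections)
  hits
}

test_that("focal full-probability rows wire all-to-all within channel only", {
  net <- build_cbgt_network(small_cfg(), seed = 3)
  n_ctx <- net$pops[[which(net$pop_names == "Ctx_L")]]$n
  n_dmsn <- net$pops[[which(net$pop_names == "dMSN_L")]]$n
  within <- proj_find(net, "Ctx", "dMSN", "AMPA", "L", "L")
  expect_length(within, 1)
  # every L-cortical cell contacts every L-dMSN cell
  expect_equal(length(within[[1]]$adj), n_ctx * n_dmsn)
  # and none cross to the R channel
  expect_length(proj_find(net, "Ctx", "dMSN", "AMPA", "L", "R"), 0)
})

test_that("diffuse full-probability rows reach both channels", {
  net <- build_cbgt_network(small_cfg(), seed = 3)
  n_fsi <- net$pops[[which(net$pop_names == "FSI")]]$n
  n_dmsn <- net$pops[[which(net$pop_names == "dMSN_L")]]$n
  for (ch in c("L", "R")) {
    pr <- proj_find(net, "FSI", "dMSN", "GABA", tgt_channel = ch)
    expect_length(pr, 1)
    # P = 1 diffuse: in-degree equals the full source size
    indeg <- tabulate(pr[[1]]$adj - min(pr[[1]]$adj) + 1L, n_dmsn)
    expect_true(all(indeg == n_fsi))
  }
})

test_that("sparse rows realize their Bernoulli probability", {
  net <- build_cbgt_network(cbgt_config(scale = 0.5), seed = 9)
  prs <- proj_find(net, "GPe", "GPe", "GABA")
  n_edges <- sum(vapply(prs, function(p) length(p$adj), 0))
  n_gpe <- net$pops[[which(net$pop_names == "GPe_L")]]$n
  # diffuse across both channels, self-pairs excluded
  n_possible <- (2 * n_gpe)^2 - 2 * n_gpe
  frac <- n_edges / n_possible
  se <- sqrt(0.05 * 0.95 / n_possible)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("every connectivity-table row is represented", {
  net <- build_cbgt_network(small_cfg(), seed = 3)
  tab <- cbgt_table3()
  for (i in seq_len(nrow(tab))) {
    expect_gt(length(proj_find(net, tab$src[i], tab$tgt[i],
                               tab$receptor[i])), 0)
  }
})

test_that("unknown populations in the connection table are rejected", {
  cfg <- small_cfg()
  cfg$conn <- rbind(cfg$conn,
                    data.frame(src = "Ctx", tgt = "Hippocampus", P = 0.5,
                               g = 1, topology = "focal",
                               receptor = "AMPA"))
  expect_error(build_cbgt_network(cfg, seed = 1), "Hippocampus")
})

test_that("wiring is reproducible under a fixed seed", {
  n1 <- build_cbgt_network(small_cfg(), seed = 11)
  n2 <- build_cbgt_network(small_cfg(), seed = 11)
  expect_identical(lapply(n1$projections, `[[`, "adj"),
                   lapply(n2$projections, `[[`, "adj"))
})

test_that("reward conditions scale only the direct-pathway efficacies", {
  net <- build_cbgt_network(small_cfg(), seed = 3)
  high <- apply_reward_condition(net, "high")
  gs <- function(n, tgt, ch) {
    vapply(proj_find(n, "Ctx", tgt, "AMPA", tgt_channel = ch),
           `[[`, 0, "g")
  }
  expect_equal(gs(high, "dMSN", "L"), 0.225 * 1.035)  # = 0.232875
  expect_equal(gs(high, "dMSN", "R"), 0.225 * 0.945)
  expect_equal(gs(high, "iMSN", "L"), 0.225)
  low <- apply_reward_condition(net, "low")
  expect_equal(gs(low, "dMSN", "R"), 0.225 * 0.99)
  # identity scaling restores the baseline exactly
  ident <- apply_reward_condition(high, data.frame(
    condition = "neutral", phi_LD = 1, phi_LI = 1, phi_RD = 1, phi_RI = 1))
  expect_equal(gs(ident, "dMSN", "L"), 0.225)
  expect_error(apply_reward_condition(net, "ultra"), "unknown")
})

test_that("subject sampling perturbs efficacies by five percent", {
  cfg <- small_cfg()
  draws <- vapply(1:400, function(s) {
    sample_subject_network(cfg, subject_seed = s, build = FALSE)$conn$g[1]
  }, 0)
  mu <- cbgt_table3()$g[1]
  expect_lt(abs(mean(draws) / mu - 1), 0.01)
  expect_lt(abs(sd(draws) / mu - 0.05), 0.01)
  # omega = P * g
  s1 <- sample_subject_network(cfg, subject_seed = 5, build = FALSE)
  expect_equal(s1$conn$omega, s1$conn$P * s1$conn$g)
  # zero spread duplicates the base table
  s0 <- sample_subject_network(cfg, subject_seed = 5, sigma_frac = 0,
                               build = FALSE)
  expect_equal(s0$conn$g, cbgt_table3()$g)
})

test_that("table asymmetries match the wiring intent", {
  tab <- cbgt_table3()
  fsi_d <- tab$g[tab$src == "FSI" & tab$tgt == "dMSN"]
  fsi_i <- tab$g[tab$src == "FSI" & tab$tgt == "iMSN"]
  expect_gt(fsi_d, fsi_i)
  p_id <- tab$P[tab$src == "iMSN" & tab$tgt == "dMSN"]
  p_di <- tab$P[tab$src == "dMSN" & tab$tgt == "iMSN"]
  expect_gt(p_id, p_di)
})
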