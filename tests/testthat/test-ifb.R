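# Integrate-and-fire-or-burst neuron kernel: leak closed form, T-current
# inactivation, gating dynamics, convergence, and rebound behaviour.

test_that("with gT = 0 the membrane follows the LIF closed form", {
  p <- neuron_params(gT = 0)
  out <- ifb_integrate(p, t_end = 100, dt = 0.01, V0 = -60)
  tau <- 1000 * p$C / p$gL          # 20 ms
  expected <- p$VL + (-60 - p$VL) * exp(-out$t / tau)
  expect_lt(max(abs(out$V - expected)), 0.02)
  expect_length(out$spikes, 0)
})

test_that("halving dt changes the trajectory by less than the tolerance", {
  p <- neuron_params(gT = 0.06)
  I_fun <- function(t, V) if (t < 40) 600 else -150   # pA, drive + release
  coarse <- ifb_integrate(p, 120, dt = 0.05, V0 = -65, I_fun = I_fun)
  fine <- ifb_integrate(p, 120, dt = 0.025, V0 = -65, I_fun = I_fun)
  idx <- seq(2, length(fine$V), by = 2)
  expect_lt(max(abs(coarse$V - fine$V[idx])), 0.25)
})

test_that("h recovers to 1 under sustained hyperpolarization", {
  p <- neuron_params(gT = 0.06)
  # hold far below Vh for many recovery time constants
  out <- ifb_integrate(p, 800, dt = 0.05, V0 = -80, h0 = 0,
                       I_fun = function(t, V) 300)  # inhibitory hold
  expect_lt(tail(out$V, 1), p$Vh)
  expect_gt(tail(out$h, 1), 0.999)
})

test_that("h decays when depolarized above Vh", {
  p <- neuron_params(gT = 0)
  out <- ifb_integrate(p, 100, dt = 0.05, V0 = -55, h0 = 1,
                       I_fun = function(t, V) -300)  # depolarizing hold
  expect_lt(tail(out$h, 1), 0.01)
})

test_that("release from hyperpolarization yields a T-current rebound", {
  # hyperpolarize 500 ms (h de-inactivates), then release with a modest
  # depolarizing drive that crosses Vh; the burst-capable cell must exceed
  # the leak-only trajectory. Oracle: reference integration at dt/100.
  drive <- function(t, V) if (t < 500) 450 else -320
  pT <- neuron_params(gT = 60)
  p0 <- neuron_params(gT = 0)
  reb <- ifb_integrate(pT, 650, dt = 0.05, V0 = -70, h0 = 0.2,
                       I_fun = drive)
  leak <- ifb_integrate(p0, 650, dt = 0.05, V0 = -70, h0 = 0.2,
                        I_fun = drive)
  post <- reb$t > 510 & reb$t < 650
  expect_gt(max(reb$V[post] - leak$V[post]), 1)
  # burst-capable cell spikes after release; the leak-only cell never does
  expect_gt(sum(reb$spikes > 500), 0)
  expect_length(leak$spikes, 0)
  # high-resolution reference: same pre-burst trajectory and a comparable
  # rebound spike count
  ref <- ifb_integrate(pT, 650, dt = 0.0005, V0 = -70, h0 = 0.2,
                       I_fun = drive)
  v_coarse <- reb$V[abs(reb$t - 512) < 1e-9]
  v_ref <- ref$V[abs(ref$t - 512) < 1e-9]
  # during the rebound upswing dV/dt is ~1.5 mV/ms, so a sub-step timing
  # offset shows up as a ~0.5 mV pointwise difference
  expect_lt(abs(v_coarse - v_ref), 1)
  expect_lt(abs(sum(reb$spikes > 500) - sum(ref$spikes > 500)), 10)
})

test_that("synaptic currents vanish at their reversal potentials", {
  st <- population_state(1)
  expect_equal(synaptic_current(st, receptor_params(1, 1, 1), V = -60), 0)
  st$s2 <- 1
  expect_equal(synaptic_current(st, receptor_params(g2 = 1), V = 0), 0)
  st2 <- population_state(1, s3 = 1)
  expect_equal(synaptic_current(st2, receptor_params(g3 = 1), V = -70), 0)
  # GABA above its reversal is hyperpolarizing (positive Isyn here)
  expect_gt(synaptic_current(st2, receptor_params(g3 = 1), V = -55), 0)
})

test_that("gating decays exponentially and the NMDA gate saturates", {
  st <- population_state(1, s1 = 1, s2 = 1, s3 = 1)
  rp <- receptor_params()
  for (k in 1:40) st <- update_gating(st, rp, dt = 0.05)
  expect_equal(st$s1, exp(-2 / rp$tau_ampa), tolerance = 1e-10)
  expect_equal(st$s3, exp(-2 / rp$tau_gaba), tolerance = 1e-10)
  # NMDA at s = 1 cannot exceed 1
  st2 <- population_state(1, s2 = 1)
  st2 <- update_gating(st2, rp, nmda_spikes = 1, dt = 1e-9)
  expect_lte(st2$s2, 1)
})

test_that("k rapid spikes drive the NMDA gate to 1 - (1 - alpha)^k", {
  rp <- receptor_params()
  for (k in c(1, 3, 6)) {
    st <- population_state(1)
    st <- update_gating(st, rp, nmda_spikes = k, dt = 1e-9)
    expect_equal(st$s2, 1 - (1 - rp$alpha)^k, tolerance = 1e-6)
  }
})

test_that("gating bounds hold over randomized spike trains", {
  set.seed(6)
  rp <- receptor_params()
  st <- population_state(5)
  for (i in 1:300) {
    st <- update_gating(st, rp,
                        ampa_spikes = stats::rpois(5, 0.3),
                        nmda_spikes = stats::rpois(5, 0.3),
                        gaba_spikes = stats::rpois(5, 0.3), dt = 0.5)
    expect_true(all(st$s3 >= 0 & st$s3 <= 1))
    expect_true(all(st$s2 >= 0 & st$s2 <= 1))
    expect_true(all(st$s1 >= 0))
  }
})

test_that("non-finite state raises a diagnostic integration error", {
  st <- population_state(3)
  st$V[2] <- NaN
  expect_error(step_membrane(st, neuron_params(), 0, dt = 0.05),
               "diverged.*0.05.*3")
})
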