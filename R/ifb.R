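## Integrate-and-fire-or-burst (IFB) neuron model: a leaky integrate-and-fire
## unit augmented with a low-threshold T-type calcium current,
##
##   C dV/dt = -gL (V - VL) - gT h H(V - Vh) (V - VT) - Isyn,
##
## where the inactivation h decays with time constant tau_h_minus while the
## cell is depolarized above Vh and recovers toward 1 with tau_h_plus below
## it.  With gT = 0 the model reduces exactly to leaky integrate-and-fire.
## These R functions are the reference implementation used by the unit tests
## and small experiments; the network simulator runs the same dynamics in
## compiled code.

#' IFB neuron parameters
#'
#' Defaults are the common CBGT values: C = 0.5 nF, gL = 25 nS, VL = -70 mV,
#' VT = 120 mV, spike boundary Vb = -50 mV, reset Vr = -55 mV. `gT = 0`
#' reduces the model to leaky integrate-and-fire (used for cortex, striatum,
#' GPi and thalamus); bursting GPe/STN units use `gT > 0`. The T-current
#' activation threshold defaults to Vh = -60 mV. The inactivation decay
#' constant is quoted with a negative sign in some sources; it is stored
#' here as a positive magnitude (`tau_h_minus = 20` ms) and always applied
#' as a decay, since growth of h during depolarization would be unphysical.
#'
#' @param C capacitance (nF)
#' @param gL leak conductance (nS)
#' @param VL leak reversal (mV)
#' @param Vh T-current activation threshold (mV)
#' @param VT T-current reversal (mV)
#' @param gT T-current conductance (nS)
#' @param tau_h_minus inactivation decay time constant, magnitude (ms)
#' @param tau_h_plus inactivation recovery time constant (ms)
#' @param Vb spike boundary (mV)
#' @param Vr reset potential (mV)
#' @return list of class `neuron_params`
#' @export
neuron_params <- function(C = 0.5, gL = 25, VL = -70, Vh = -60, VT = 120,
                          gT = 0, tau_h_minus = 20, tau_h_plus = 100,
                          Vb = -50, Vr = -55) {
  stopifnot(C > 0, gL > 0, gT >= 0, Vr < Vb, tau_h_plus > 0,
            tau_h_minus > 0)
  structure(list(C = C, gL = gL, VL = VL, Vh = Vh, VT = VT, gT = gT,
                 tau_h_minus = tau_h_minus, tau_h_plus = tau_h_plus,
                 Vb = Vb, Vr = Vr),
            class = "neuron_params")
}

#' Receptor and synaptic-kinetics parameters
#'
#' AMPA (`g1`), NMDA (`g2`) and GABA_A (`g3`) conductances with reversal
#' potentials VE = 0 mV (excitatory) and VI = -70 mV (inhibitory), decay
#' constants 2 / 100 / 5 ms, NMDA saturation rate `alpha = 0.63`, and a
#' transmission delay of 0.2 ms.
#'
#' @param g1,g2,g3 AMPA, NMDA, GABA_A conductances (nS)
#' @param VE,VI excitatory and inhibitory reversal potentials (mV)
#' @param tau_ampa,tau_gaba,tau_nmda gating decay constants (ms)
#' @param alpha NMDA saturation rate per presynaptic spike
#' @param delay transmission delay (ms)
#' @return list of class `receptor_params`
#' @export
receptor_params <- function(g1 = 0, g2 = 0, g3 = 0, VE = 0, VI = -70,
                            tau_ampa = 2, tau_gaba = 5, tau_nmda = 100,
                            alpha = 0.63, delay = 0.2) {
  stopifnot(tau_ampa > 0, tau_gaba > 0, tau_nmda > 0, alpha > 0, alpha <= 1,
            delay >= 0, VE > VI, g1 >= 0, g2 >= 0, g3 >= 0)
  structure(list(g1 = g1, g2 = g2, g3 = g3, VE = VE, VI = VI,
                 tau_ampa = tau_ampa, tau_gaba = tau_gaba,
                 tau_nmda = tau_nmda, alpha = alpha, delay = delay),
            class = "receptor_params")
}

#' State of one neural population
#'
#' @param n number of neurons
#' @param V membrane potentials (mV)
#' @param h T-current inactivation in \[0, 1\]
#' @param s1,s2,s3 AMPA / NMDA / GABA_A gating variables
#' @return list of class `population_state`
#' @export
population_state <- function(n, V = rep(-70, n), h = rep(1, n),
                             s1 = rep(0, n), s2 = rep(0, n),
                             s3 = rep(0, n)) {
  stopifnot(length(V) == n, length(h) == n, all(h >= 0), all(h <= 1),
            all(s3 >= 0), all(s3 <= 1), all(s1 >= 0), all(s2 >= 0))
  structure(list(n = n, V = V, h = h, s1 = s1, s2 = s2, s3 = s3),
            class = "population_state")
}

#' Advance membrane potentials one time step
#'
#' Forward-Euler step of the IFB membrane equation under the supplied
#' synaptic current, with exact exponential updates of the T-current
#' inactivation. Neurons reaching the spike boundary `Vb` are reset to `Vr`
#' and flagged in the returned state's `spiked` field. The Heaviside gate is
#' closed-on-the-right: `H = 1` at exactly `V = Vh`.
#'
#' @param state a [population_state()]
#' @param p a [neuron_params()]
#' @param I_syn synaptic current per neuron (pA; nS x mV)
#' @param dt time step (ms)
#' @return updated state with logical `spiked`
#' @export
step_membrane <- function(state, p, I_syn = 0, dt = 0.05) {
  stopifnot(dt > 0)
  if (!all(is.finite(state$V)) || !all(is.finite(state$h))) {
    stop(sprintf(
      "integration diverged (non-finite state) at dt = %g for population of %d neurons",
      dt, state$n))
  }
  V <- state$V
  h <- state$h
  dep <- V >= p$Vh
  IT <- ifelse(dep & p$gT > 0, p$gT * h * (V - p$VT), 0)
  I_syn <- rep_len(I_syn, state$n)
  V_new <- V + dt / (1000 * p$C) * (-p$gL * (V - p$VL) - IT - I_syn)
  h_new <- ifelse(dep,
                  h * exp(-dt / p$tau_h_minus),
                  1 + (h - 1) * exp(-dt / p$tau_h_plus))
  spiked <- V_new >= p$Vb
  V_new[spiked] <- p$Vr
  out <- state
  out$V <- V_new
  out$h <- h_new
  out$spiked <- spiked
  out
}

#' Receptor-resolved synaptic current
#'
#' `Isyn = g1 s1 (V - VE) + g2 s2 (V - VE) / (1 + exp(-0.062 V)/3.57)
#'       + g3 s3 (V - VI)`; the middle factor is the voltage-dependent
#' magnesium block of the NMDA receptor.
#'
#' @param state a [population_state()]
#' @param rp a [receptor_params()]
#' @param V membrane potentials (defaults to the state's)
#' @return current per neuron (nS x mV = pA)
#' @export
synaptic_current <- function(state, rp, V = state$V) {
  nmda_gate <- 1 / (1 + exp(-0.062 * V) / 3.57)
  rp$g1 * state$s1 * (V - rp$VE) +
    rp$g2 * state$s2 * (V - rp$VE) * nmda_gate +
    rp$g3 * state$s3 * (V - rp$VI)
}

#' Update synaptic gating variables for one step
#'
#' AMPA and GABA_A gates increment by one per arriving presynaptic spike and
#' decay exponentially; the NMDA gate increments by `alpha * (1 - s)` per
#' spike (saturating at 1) and decays with its 100 ms constant. Spike counts
#' must already be delayed by the transmission delay.
#'
#' @param state a [population_state()]
#' @param rp a [receptor_params()]
#' @param ampa_spikes,nmda_spikes,gaba_spikes integer spike counts arriving
#'   at each neuron during this step
#' @param dt time step (ms)
#' @return updated state
#' @export
update_gating <- function(state, rp, ampa_spikes = 0, nmda_spikes = 0,
                          gaba_spikes = 0, dt = 0.05) {
  ampa_spikes <- rep_len(ampa_spikes, state$n)
  nmda_spikes <- rep_len(nmda_spikes, state$n)
  gaba_spikes <- rep_len(gaba_spikes, state$n)
  out <- state
  out$s1 <- (state$s1 + ampa_spikes) * exp(-dt / rp$tau_ampa)
  out$s3 <- pmin((state$s3 + gaba_spikes), 1) * exp(-dt / rp$tau_gaba)
  s2 <- state$s2
  kmax <- max(nmda_spikes)
  if (kmax > 0) {
    for (k in seq_len(kmax)) {
      hit <- nmda_spikes >= k
      s2[hit] <- s2[hit] + rp$alpha * (1 - s2[hit])
    }
  }
  out$s2 <- s2 * exp(-dt / rp$tau_nmda)
  out
}

#' Integrate a single IFB population over time
#'
#' Convenience reference integrator: repeatedly applies [step_membrane()]
#' under a user-supplied current function `I_fun(t, V)`. Used as the
#' high-resolution oracle in convergence and rebound tests.
#'
#' @param p a [neuron_params()]
#' @param t_end total time (ms)
#' @param dt step (ms)
#' @param V0,h0 initial conditions
#' @param I_fun function of time and voltage returning current (pA)
#' @return list with vectors `t`, `V`, `h` and `spikes` (spike times)
#' @export
ifb_integrate <- function(p, t_end, dt, V0 = -70, h0 = 1,
                          I_fun = function(t, V) 0) {
  n_steps <- round(t_end / dt)
  st <- population_state(1, V = V0, h = max(min(h0, 1), 0))
  tt <- numeric(n_steps)
  VV <- numeric(n_steps)
  hh <- numeric(n_steps)
  spikes <- numeric(0)
  for (i in seq_len(n_steps)) {
    t <- i * dt
    st <- step_membrane(st, p, I_fun(t, st$V), dt)
    if (st$spiked[1]) spikes <- c(spikes, t)
    tt[i] <- t; VV[i] <- st$V; hh[i] <- st$h
  }
  list(t = tt, V = VV, h = hh, spikes = spikes)
}
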