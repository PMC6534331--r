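## Reduced two-channel striatal learning network: dopamine-modulated STDP
## at corticostriatal synapses plus Q-learning of action values.  The
## exported R functions implement the individual rules (daughter-train
## thinning, eligibility updates, the dopamine/weight update, and the
## spike-count action-selection rule) for direct testing; `run_learning()`
## executes full realizations through the compiled kernel.

#' Parameters of the reduced STDP learning network
#'
#' Constants not fixed by the published description (mother-train rate and
#' oscillation, STDP amplitudes and time constants, eligibility decay,
#' dopamine gains, Q-learning rate, synaptic scales) are configuration
#' parameters whose defaults were chosen once to reproduce the qualitative
#' benchmarks of the learning model (dMSN weight separation that tracks
#' reward, near-equal iMSN weights, concurrent dMSN/iMSN activity during
#' selections); they are not canonical values.
#'
#' @param n_per_pop neurons per population (4 populations: dMSN/iMSN x L/R)
#' @param duration_ms length of one realization (ms); 15 s default
#' @param dt_ms membrane integration step (ms)
#' @param mother_rate_hz baseline rate of each channel's mother train (Hz)
#' @param osc_depth,osc_freq_hz oscillatory modulation depth and frequency
#' @param pD,pI mother-to-daughter transfer probabilities for dMSNs and
#'   iMSNs; cortex-to-iMSN release exceeds cortex-to-dMSN, so `pD < pI`
#' @param w0,w_max initial and maximal corticostriatal weight (nS)
#' @param A_plus,A_minus,tau_plus,tau_minus STDP kernel amplitudes and time
#'   constants (ms)
#' @param tau_elig eligibility-trace decay constant (ms)
#' @param eta_d,eta_i dopamine gain on weight updates for dMSNs and iMSNs
#'   (dMSNs respond more strongly to phasic dopamine; the iMSN update has
#'   opposite sign)
#' @param kappa_d relative sensitivity of dMSN synapses to dopamine dips
#'   (DA < 0) versus bursts; D1-receptor plasticity responds mainly to
#'   phasic bursts, so `kappa_d < 1`
#' @param alpha_q Q-learning rate
#' @param select_window_ms,select_count action-selection window and dMSN
#'   spike count
#' @param silence_ms cortical silencing after each selection (ms)
#' @param C,gL,VL,VT,DeltaT,Vb,Vr,VE,tau_s exponential integrate-and-fire
#'   membrane and synapse constants
#' @return list of class `stdp_params`
#' @export
stdp_params <- function(n_per_pop = 12, duration_ms = 15000, dt_ms = 0.01,
                        mother_rate_hz = 500, osc_depth = 0.8,
                        osc_freq_hz = 8, pD = 0.65, pI = 0.8,
                        w0 = 12, w_max = 60,
                        A_plus = 1, A_minus = 0.3, tau_plus = 20,
                        tau_minus = 20, tau_elig = 300,
                        eta_d = 0.4, eta_i = 0.05, kappa_d = 0.6,
                        alpha_q = 0.02,
                        select_window_ms = 10, select_count = 3,
                        silence_ms = 50,
                        C = 0.5, gL = 25, VL = -70, VT = -50, DeltaT = 2,
                        Vb = -40, Vr = -55, VE = 0, tau_s = 2) {
  stopifnot(pD > 0, pD < pI, pI <= 1, duration_ms > 0, w0 >= 0,
            w_max >= w0, select_count >= 1)
  structure(as.list(environment()), class = "stdp_params")
}

#' Thin a mother spike train into daughter trains
#'
#' Each daughter keeps each mother spike independently with the transfer
#' probability, so a daughter's long-run rate is `p` times the mother's.
#'
#' @param mother_spikes sorted spike times (ms)
#' @param p transfer probability in \[0, 1\]
#' @param n_daughters number of daughter trains
#' @return list of spike-time vectors
#' @export
generate_daughter_trains <- function(mother_spikes, p, n_daughters) {
  stopifnot(p >= 0, p <= 1, n_daughters >= 1)
  lapply(seq_len(n_daughters), function(i) {
    mother_spikes[runif(length(mother_spikes)) < p]
  })
}

#' Sample an oscillatory Poisson mother train
#'
#' Inhomogeneous Poisson process with rate
#' `rate0 * (1 + depth * sin(2 pi f t))`, sampled by thinning a homogeneous
#' process at the peak rate.
#'
#' @param rate0 baseline rate (Hz)
#' @param depth modulation depth in \[0, 1)
#' @param freq_hz oscillation frequency (Hz)
#' @param duration_ms duration (ms)
#' @return sorted spike times (ms)
#' @export
generate_mother_train <- function(rate0, depth, freq_hz, duration_ms) {
  stopifnot(rate0 > 0, depth >= 0, depth < 1, duration_ms > 0)
  peak <- rate0 * (1 + depth)
  n_exp <- stats::rpois(1, peak * duration_ms / 1000 * 1.1) +
    ceiling(4 * sqrt(peak * duration_ms / 1000) + 10)
  gaps <- stats::rexp(n_exp, rate = peak / 1000)
  t <- cumsum(gaps)
  t <- t[t <= duration_ms]
  keep <- runif(length(t)) <
    (1 + depth * sin(2 * pi * freq_hz * t / 1000)) / (1 + depth)
  t[keep]
}

#' Eligibility-trace update from pre/post spike pairs
#'
#' Event-driven pair-based STDP on nearest-neighbour spike pairings:
#' a postsynaptic spike at `t` adds `A_plus * exp(-(t - t_pre)/tau_plus)`
#' (potentiation for pre-before-post), a presynaptic spike subtracts
#' `A_minus * exp(-(t - t_post)/tau_minus)` (depression for post-before-pre),
#' and the trace decays exponentially with `tau_elig` between events.
#'
#' @param e initial eligibility
#' @param pre_spikes,post_spikes sorted spike-time vectors (ms)
#' @param A_plus,A_minus,tau_plus,tau_minus STDP kernel
#' @param tau_elig eligibility decay (ms)
#' @param t_end time at which the final decayed value is reported (default:
#'   last event)
#' @return eligibility at `t_end`
#' @export
stdp_eligibility_update <- function(e, pre_spikes, post_spikes, A_plus = 1,
                                    A_minus = 1, tau_plus = 20,
                                    tau_minus = 20, tau_elig = 300,
                                    t_end = NULL) {
  ev <- rbind(
    if (length(pre_spikes)) data.frame(t = pre_spikes, pre = TRUE),
    if (length(post_spikes)) data.frame(t = post_spikes, pre = FALSE))
  if (is.null(ev) || nrow(ev) == 0) {
    if (!is.null(t_end)) e <- e * exp(-t_end / tau_elig)
    return(e)
  }
  ev <- ev[order(ev$t), , drop = FALSE]
  last_pre <- -Inf; last_post <- -Inf; t_last <- 0
  for (i in seq_len(nrow(ev))) {
    t <- ev$t[i]
    e <- e * exp(-(t - t_last) / tau_elig)
    if (ev$pre[i]) {
      e <- e - A_minus * exp(-(t - last_post) / tau_minus)
      last_pre <- t
    } else {
      e <- e + A_plus * exp(-(t - last_pre) / tau_plus)
      last_post <- t
    }
    t_last <- t
  }
  if (!is.null(t_end)) e <- e * exp(-(t_end - t_last) / tau_elig)
  e
}

#' Dopamine release and corticostriatal weight update
#'
#' The phasic dopamine level is the reward prediction error
#' `DA = reward - max(Q_L, Q_R)` (comparison of the obtained reward with the
#' maximal action value learned so far). The weight moves by
#' `gain * DA_eff * e`, where dMSNs carry a larger positive gain (`eta_d`)
#' but attenuated sensitivity to dopamine dips (`DA_eff = kappa_d * DA` for
#' `DA < 0`), and iMSNs a smaller opposite-signed gain (`eta_i`), reflecting
#' the weaker and opposing sensitivity of indirect-pathway synapses to
#' phasic dopamine. Weights are clipped to `[0, w_max]`.
#'
#' @param w current weight(s)
#' @param e eligibility trace(s)
#' @param reward obtained reward
#' @param Q named or unnamed numeric vector of the two action values
#' @param cell_type `"dMSN"` or `"iMSN"`
#' @param params an [stdp_params()]
#' @return list with updated `w` and the dopamine level `DA`
#' @export
dopamine_and_weight_update <- function(w, e, reward, Q,
                                       cell_type = c("dMSN", "iMSN"),
                                       params = stdp_params()) {
  cell_type <- match.arg(cell_type)
  da <- reward - max(Q)
  if (cell_type == "dMSN") {
    da_eff <- if (da >= 0) da else params$kappa_d * da
    gain <- params$eta_d
  } else {
    da_eff <- da
    gain <- -params$eta_i
  }
  w_new <- pmin(pmax(w + gain * da_eff * e, 0), params$w_max)
  list(w = w_new, DA = da)
}

#' Spike-count action selection with iMSN suppression
#'
#' Replays time-ordered dMSN and iMSN spikes of one channel: each iMSN
#' spike suppresses the most recent still-counted dMSN spike; the channel
#' is selected at the first moment it holds `select_count` distinct counted
#' dMSN spikes within the selection window.
#'
#' @param dmsn_spikes,imsn_spikes sorted spike times (ms) of one channel
#' @param window selection window (ms)
#' @param count required dMSN spikes (default 3)
#' @return list with `selected` (logical) and `t_select` (time or NA)
#' @export
select_action <- function(dmsn_spikes, imsn_spikes, window = 10, count = 3) {
  ev <- rbind(
    if (length(dmsn_spikes)) data.frame(t = dmsn_spikes, d = TRUE),
    if (length(imsn_spikes)) data.frame(t = imsn_spikes, d = FALSE))
  if (is.null(ev) || nrow(ev) == 0) {
    return(list(selected = FALSE, t_select = NA_real_))
  }
  ev <- ev[order(ev$t), , drop = FALSE]
  counted <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    t <- ev$t[i]
    if (ev$d[i]) {
      counted <- c(counted, t)
      counted <- counted[counted >= t - window]
      if (length(counted) >= count) {
        return(list(selected = TRUE, t_select = t))
      }
    } else if (length(counted)) {
      counted <- counted[-length(counted)]
    }
  }
  list(selected = FALSE, t_select = NA_real_)
}

#' Run dopamine-modulated STDP learning realizations
#'
#' Simulates the reduced striatal network for `duration_ms` under a reward
#' schedule, repeated over independent realizations, and returns averaged
#' weight and action-value trajectories plus the final per-channel weight
#' ratios `w_D / w_I`. Realizations in which no action was ever selected
#' are flagged and excluded from averages with a warning.
#'
#' @param p_L reward probability of the L action (`p_R = 1 - p_L`); ignored
#'   when fixed rewards are supplied
#' @param params an [stdp_params()]
#' @param n_realizations independent realizations to average over (8 in the
#'   reference protocol)
#' @param seed master seed
#' @param fixed_rewards optional numeric vector `c(r_L, r_R)` for the
#'   constant-reward benchmark protocol
#' @return object of class `stdp_learning`: `trajectory` (averaged time
#'   series: time, per-population mean weights, Q values, per-channel
#'   weight ratios), `final_ratios`, `rates_hz`, `n_selections`
#' @export
run_learning <- function(p_L = 0.85, params = stdp_params(),
                         n_realizations = 8, seed = 1,
                         fixed_rewards = NULL) {
  stopifnot(inherits(params, "stdp_params"))
  if (is.null(fixed_rewards)) {
    stopifnot(p_L > 0.5, p_L < 1)
  }
  seeds <- derive_seeds(seed, n_realizations)
  cfg <- c(unclass(params), list(
    p_L = if (is.null(fixed_rewards)) p_L else 0.5,
    p_R = if (is.null(fixed_rewards)) 1 - p_L else 0.5,
    fixed_reward = !is.null(fixed_rewards),
    r_L = if (is.null(fixed_rewards)) 1 else fixed_rewards[1],
    r_R = if (is.null(fixed_rewards)) 1 else fixed_rewards[2],
    record_every_ms = 50))
  names(cfg)[names(cfg) == "duration_ms"] <- "duration_ms"
  runs <- vector("list", n_realizations)
  excluded <- 0L
  for (r in seq_len(n_realizations)) {
    set.seed(seeds[r])
    res <- stdp_learn_cpp(cfg)
    if (sum(res$n_selections) == 0) {
      excluded <- excluded + 1L
      next
    }
    runs[[r]] <- res
  }
  runs <- Filter(Negate(is.null), runs)
  if (excluded > 0) {
    warning(excluded, " realization(s) with no selected actions excluded")
  }
  stopifnot(length(runs) > 0)
  nr <- min(vapply(runs, `[[`, 0L, "rec_filled"))
  time_ms <- runs[[1]]$time_ms[seq_len(nr)]
  w_mean <- Reduce(`+`, lapply(runs, function(r)
    r$w_traj[seq_len(nr), ])) / length(runs)
  q_mean <- Reduce(`+`, lapply(runs, function(r)
    r$q_traj[seq_len(nr), ])) / length(runs)
  colnames(w_mean) <- c("dMSN_L", "iMSN_L", "dMSN_R", "iMSN_R")
  colnames(q_mean) <- c("Q_L", "Q_R")
  traj <- data.frame(time_ms = time_ms, w_mean, q_mean)
  traj$ratio_L <- traj$dMSN_L / pmax(traj$iMSN_L, 1e-9)
  traj$ratio_R <- traj$dMSN_R / pmax(traj$iMSN_R, 1e-9)
  final <- traj[nrow(traj), ]
  rates <- Reduce(`+`, lapply(runs, `[[`, "mean_rate_hz")) / length(runs)
  names(rates) <- c("dMSN_L", "iMSN_L", "dMSN_R", "iMSN_R")
  nsel <- Reduce(`+`, lapply(runs, `[[`, "n_selections")) / length(runs)
  structure(list(trajectory = traj,
                 final_ratios = c(L = final$ratio_L, R = final$ratio_R),
                 final_weights = unlist(final[c("dMSN_L", "iMSN_L",
                                                "dMSN_R", "iMSN_R")]),
                 q_final = unlist(final[c("Q_L", "Q_R")]),
                 rates_hz = rates,
                 n_selections = c(L = nsel[1], R = nsel[2]),
                 n_realizations = length(runs), p_L = p_L,
                 fixed_rewards = fixed_rewards, params = params),
            class = "stdp_learning")
}

#' @export
print.stdp_learning <- function(x, ...) {
  cat("STDP learning (", x$n_realizations, " realizations)\n", sep = "")
  cat(sprintf("  selections per realization: L %.1f, R %.1f\n",
              x$n_selections[1], x$n_selections[2]))
  cat(sprintf("  final weight ratios w_D/w_I: L %.3f, R %.3f\n",
              x$final_ratios["L"], x$final_ratios["R"]))
  cat(sprintf("  final Q: L %.3f, R %.3f\n", x$q_final[1], x$q_final[2]))
  invisible(x)
}

#' Convert learned weight ratios to condition-style scalings
#'
#' Maps per-channel learned ratios `w_D/w_I` into multiplicative scalings of
#' the corticostriatal efficacy relative to their pre-learning baseline,
#' the same form as the reward-condition table (direct-pathway scaling per
#' channel, indirect fixed at 1). Exploratory: the canonical pipeline feeds
#' the printed condition scalings forward.
#'
#' @param learning an [run_learning()] result
#' @return one-row data.frame with `phi_LD`, `phi_LI`, `phi_RD`, `phi_RI`
#' @export
ratios_to_phi <- function(learning) {
  stopifnot(inherits(learning, "stdp_learning"))
  w0 <- learning$params$w0
  data.frame(condition = "learned",
             phi_LD = unname(learning$final_weights["dMSN_L"] / w0),
             phi_LI = 1.00,
             phi_RD = unname(learning$final_weights["dMSN_R"] / w0),
             phi_RI = 1.00)
}
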