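## CBGT network construction: the six-region, two-action-channel wiring with
## per-projection probabilities, conductances, topologies (focal = within
## channel, diffuse = across channels) and receptor types; reward-condition
## scaling of the corticostriatal direct-pathway weights; and the random
## "subject network" sampling used in robustness analyses.

#' Connectivity table of the CBGT network
#'
#' One row per projection between populations: projection probability `P`,
#' synaptic efficacy `g` (nS), topology (`focal` projections stay within an
#' action channel, `diffuse` ones cross channels), and receptor type. Rows
#' with both AMPA and NMDA components appear once per receptor with the same
#' probability and efficacy. Note the asymmetries that shape striatal
#' competition: FSI inhibition is stronger onto dMSNs (1.95 nS) than iMSNs
#' (1.85 nS), and iMSN->dMSN inhibition (P = 0.38) exceeds dMSN->iMSN
#' (P = 0.34).
#'
#' @return data.frame with columns `src`, `tgt`, `P`, `g`, `topology`,
#'   `receptor`
#' @export
cbgt_table3 <- function() {
  tab <- rbind(
    c("Ctx",  "Ctx",  0.325, 0.0127, "diffuse", "AMPA"),
    c("Ctx",  "Ctx",  0.325, 0.15,   "diffuse", "NMDA"),
    c("Ctx",  "CtxI", 0.181, 0.013,  "diffuse", "AMPA"),
    c("Ctx",  "CtxI", 0.181, 0.125,  "diffuse", "NMDA"),
    c("Ctx",  "FSI",  1.00,  0.18,   "diffuse", "AMPA"),
    c("Ctx",  "dMSN", 1.00,  0.225,  "focal",   "NMDA"),
    c("Ctx",  "dMSN", 1.00,  0.225,  "focal",   "AMPA"),
    c("Ctx",  "iMSN", 1.00,  0.225,  "focal",   "NMDA"),
    c("Ctx",  "iMSN", 1.00,  0.225,  "focal",   "AMPA"),
    c("Ctx",  "Th",   0.87,  0.0335, "diffuse", "NMDA"),
    c("Ctx",  "Th",   0.87,  0.0335, "diffuse", "AMPA"),
    c("CtxI", "CtxI", 1.00,  2.3125, "diffuse", "GABA"),
    c("CtxI", "Ctx",  1.00,  1.3125, "diffuse", "GABA"),
    c("dMSN", "dMSN", 0.34,  0.28,   "focal",   "GABA"),
    c("dMSN", "iMSN", 0.34,  0.28,   "focal",   "GABA"),
    c("dMSN", "GPi",  1.00,  1.44,   "focal",   "GABA"),
    c("iMSN", "iMSN", 0.34,  0.28,   "focal",   "GABA"),
    c("iMSN", "dMSN", 0.38,  0.28,   "focal",   "GABA"),
    c("iMSN", "GPe",  1.00,  3.05,   "focal",   "GABA"),
    c("FSI",  "FSI",  1.00,  2.45,   "diffuse", "GABA"),
    c("FSI",  "dMSN", 1.00,  1.95,   "diffuse", "GABA"),
    c("FSI",  "iMSN", 1.00,  1.85,   "diffuse", "GABA"),
    c("GPe",  "GPe",  0.05,  1.50,   "diffuse", "GABA"),
    c("GPe",  "STN",  0.05,  0.40,   "focal",   "GABA"),
    c("GPe",  "GPi",  1.00,  0.03,   "focal",   "GABA"),
    c("STN",  "GPe",  0.12,  0.07,   "focal",   "AMPA"),
    c("STN",  "GPe",  0.12,  4.00,   "focal",   "NMDA"),
    c("STN",  "GPi",  1.00,  0.078,  "diffuse", "NMDA"),
    c("GPi",  "Th",   1.00,  0.142,  "focal",   "GABA"),
    c("Th",   "Ctx",  0.625, 0.015,  "diffuse", "NMDA"),
    c("Th",   "CtxI", 0.625, 0.015,  "diffuse", "NMDA"),
    c("Th",   "dMSN", 1.00,  0.337,  "focal",   "AMPA"),
    c("Th",   "iMSN", 1.00,  0.337,  "focal",   "AMPA"),
    c("Th",   "FSI",  0.625, 0.30,   "diffuse", "AMPA"))
  out <- data.frame(src = tab[, 1], tgt = tab[, 2],
                    P = as.numeric(tab[, 3]), g = as.numeric(tab[, 4]),
                    topology = tab[, 5], receptor = tab[, 6],
                    stringsAsFactors = FALSE)
  out
}

#' Reward-condition corticostriatal weight scalings
#'
#' Multiplicative scalings `phi` of the Ctx->MSN efficacy per pathway and
#' channel. Only direct-pathway (dMSN) weights differ from 1: the left
#' (higher-reward) channel is potentiated and the right depressed, with the
#' imbalance growing from the low to the high reward-probability condition.
#'
#' @return data.frame with columns `condition`, `phi_LD`, `phi_LI`,
#'   `phi_RD`, `phi_RI`
#' @export
cbgt_table4 <- function() {
  data.frame(condition = c("low", "med", "high"),
             phi_LD = c(1.01, 1.02, 1.035),
             phi_LI = c(1.00, 1.00, 1.00),
             phi_RD = c(0.99, 0.97, 0.945),
             phi_RI = c(1.00, 1.00, 1.00),
             stringsAsFactors = FALSE)
}

## Full-scale population sizes per region (per channel where channelized).
.cbgt_sizes <- function(scale = 1) {
  base <- c(Ctx = 270, CtxI = 250, dMSN = 100, iMSN = 100, FSI = 100,
            GPe = 1000, STN = 1000, GPi = 100, Th = 100)
  setNames(pmax(2L, as.integer(round(base * scale))), names(base))
}

.channelized <- c(Ctx = TRUE, CtxI = FALSE, dMSN = TRUE, iMSN = TRUE,
                  FSI = FALSE, GPe = TRUE, STN = TRUE, GPi = TRUE, Th = TRUE)

#' Configuration of a CBGT simulation
#'
#' Bundles population sizes, the connectivity and reward tables, background
#' and stimulus drive settings, and integration options. Background drives
#' are independent Poisson trains per neuron through AMPA receptors; their
#' per-population rates (in Hz, with a common conductance per population) are
#' free parameters of the model, calibrated once (see
#' [calibrate_background()]) so that pre-stimulus firing is low in cortex
#' and striatum and tonically high in GPe/GPi. The per-trial stimulus rate
#' is drawn from a truncated normal (mean 2.5 Hz, sd 0.06, bounds
#' \[2.4, 2.6\] Hz), identical for the L and R cortical populations, and is
#' delivered to each cortical neuron as an independent Poisson train of rate
#' `stimulus x stim_fan_in`.
#'
#' @param scale population-size scale factor in (0, 1] (1 = full size)
#' @param dt_ms integration step (ms)
#' @param t_max_ms trial length (ms); the timeout if no threshold crossing
#' @param stim_onset_ms stimulus onset within the trial (ms); RTs are
#'   reported as absolute crossing times within the trial, so they include
#'   this onset
#' @param threshold_hz thalamic population-rate decision threshold (Hz)
#' @param rate_window_ms sliding window for the rate estimate (ms)
#' @param stim_mean_hz,stim_sd_hz,stim_lo_hz,stim_hi_hz per-trial stimulus
#'   rate distribution (truncated normal)
#' @param stim_fan_in effective number of external input synapses per
#'   cortical neuron (multiplies the stimulus rate)
#' @param stim_g AMPA conductance of one external input event (nS)
#' @param bg_rate_hz named per-population background Poisson rates (Hz)
#' @param bg_g named per-population background AMPA conductances (nS)
#' @param bg_trial_cv coefficient of variation of a per-trial multiplicative
#'   jitter on the cortical background rate (truncated at 3 cv), modelling
#'   slow trial-to-trial fluctuations of cortical excitability; widens the
#'   RT distribution without biasing either action channel
#' @param conn optional replacement connectivity table (defaults to
#'   [cbgt_table3()])
#' @param delay_ms synaptic transmission delay (ms), rounded up to a whole
#'   number of integration steps
#' @return list of class `cbgt_config`
#' @export
cbgt_config <- function(scale = 1, dt_ms = 0.05, t_max_ms = 1800,
                        stim_onset_ms = 200, threshold_hz = 30,
                        rate_window_ms = 10, stim_mean_hz = 2.5,
                        stim_sd_hz = 0.06, stim_lo_hz = 2.4,
                        stim_hi_hz = 2.6, stim_fan_in = 250,
                        stim_g = 1.4, stim_ramp_ms = 200,
                        bg_rate_hz = NULL, bg_g = NULL, bg_trial_cv = 0.04,
                        conn = NULL, delay_ms = 0.2) {
  stopifnot(scale > 0, scale <= 1, dt_ms > 0, t_max_ms > stim_onset_ms)
  ## Calibrated defaults (see the methods vignette): GPe/GPi tonic high,
  ## cortex/striatum low, thalamus far below the 30 Hz decision threshold.
  ## MSNs receive large unitary background events, keeping them in a
  ## fluctuation-driven regime where the corticostriatal weight scalings
  ## express supralinearly.
  bg_default_rate <- c(Ctx = 2047, CtxI = 2817, dMSN = 270.5, iMSN = 288.4,
                       FSI = 2045, GPe = 727.5, STN = 1879.5, GPi = 1500,
                       Th = 1400)
  bg_default_g <- c(Ctx = 3, CtxI = 3, dMSN = 12.48, iMSN = 12.48,
                    FSI = 3, GPe = 3, STN = 3, GPi = 3, Th = 3)
  if (!is.null(bg_rate_hz)) {
    bg_default_rate[names(bg_rate_hz)] <- bg_rate_hz
  }
  if (!is.null(bg_g)) bg_default_g[names(bg_g)] <- bg_g
  structure(list(scale = scale, sizes = .cbgt_sizes(scale), dt_ms = dt_ms,
                 t_max_ms = t_max_ms, stim_onset_ms = stim_onset_ms,
                 threshold_hz = threshold_hz,
                 rate_window_ms = rate_window_ms,
                 stim_mean_hz = stim_mean_hz, stim_sd_hz = stim_sd_hz,
                 stim_lo_hz = stim_lo_hz, stim_hi_hz = stim_hi_hz,
                 stim_fan_in = stim_fan_in, stim_g = stim_g,
                 stim_ramp_ms = stim_ramp_ms,
                 bg_rate_hz = bg_default_rate, bg_g = bg_default_g,
                 bg_trial_cv = bg_trial_cv,
                 conn = conn %||% cbgt_table3(), phi = cbgt_table4(),
                 delay_ms = delay_ms),
            class = "cbgt_config")
}

## Expand region names into channelized population names.
.pop_names <- function() {
  regions <- names(.channelized)
  unlist(lapply(regions, function(r) {
    if (.channelized[[r]]) paste0(r, "_", c("L", "R")) else r
  }))
}

## Bernoulli(P) adjacency from each source neuron to a target population.
## Returns 0-based global target ids concatenated per source neuron plus
## offsets (CSR layout for the compiled kernel).
.wire <- function(n_src, n_tgt, P, tgt_offset0, self_pop = FALSE) {
  adj <- vector("list", n_src)
  for (i in seq_len(n_src)) {
    if (P >= 1) {
      hits <- seq_len(n_tgt)
    } else {
      hits <- which(runif(n_tgt) < P)
    }
    if (self_pop) hits <- hits[hits != i]
    adj[[i]] <- tgt_offset0 + hits - 1L
  }
  lens <- lengths(adj)
  list(adj = as.integer(unlist(adj)),
       ptr = as.integer(c(0L, cumsum(lens))))
}

#' Build a CBGT network
#'
#' Realizes the Bernoulli wiring of every connectivity-table row (seeded and
#' reproducible): focal rows wire only within an action channel, diffuse
#' rows wire all source-target channel combinations, and rows with several
#' receptor components share one wiring draw. Populations are channelized
#' into L and R subpopulations except the cortical interneurons and FSIs,
#' which are shared pools.
#'
#' @param config a [cbgt_config()]
#' @param seed integer seed for the wiring draw
#' @return object of class `cbgt_network`
#' @export
build_cbgt_network <- function(config = cbgt_config(), seed = 1) {
  stopifnot(inherits(config, "cbgt_config"))
  set.seed(seed)
  sizes <- config$sizes
  pop_names <- .pop_names()
  region_of <- sub("_(L|R)$", "", pop_names)
  channel_of <- ifelse(grepl("_L$", pop_names), "L",
                       ifelse(grepl("_R$", pop_names), "R", "none"))
  n_of <- sizes[region_of]
  offset <- c(0L, cumsum(n_of))
  rec_code <- c(AMPA = 0L, NMDA = 1L, GABA = 2L)

  conn <- config$conn
  bad <- setdiff(unique(c(conn$src, conn$tgt)), names(sizes))
  if (length(bad)) {
    stop("unknown population name(s) in connection table: ",
         paste(bad, collapse = ", "))
  }

  ## group rows by (src, tgt, topology) so receptor components share wiring
  key <- paste(conn$src, conn$tgt, conn$topology, conn$P, sep = "|")
  projections <- list()
  for (k in unique(key)) {
    rows <- conn[key == k, , drop = FALSE]
    src_r <- rows$src[1]; tgt_r <- rows$tgt[1]
    topology <- rows$topology[1]; P <- rows$P[1]
    src_pops <- which(region_of == src_r)
    tgt_pops <- which(region_of == tgt_r)
    for (sp in src_pops) {
      for (tp in tgt_pops) {
        if (topology == "focal" &&
            channel_of[sp] != "none" && channel_of[tp] != "none" &&
            channel_of[sp] != channel_of[tp]) {
          next  # focal connections never cross channels
        }
        wiring <- .wire(n_of[sp], n_of[tp], P, offset[tp],
                        self_pop = identical(sp, tp))
        indeg <- tabulate(wiring$adj - offset[tp] + 1L, nbins = n_of[tp])
        for (ri in seq_len(nrow(rows))) {
          projections[[length(projections) + 1L]] <- list(
            src = sp - 1L, tgt = tp - 1L,
            receptor = rec_code[[rows$receptor[ri]]],
            g = rows$g[ri], base_g = rows$g[ri],
            src_region = src_r, tgt_region = tgt_r,
            src_channel = channel_of[sp], tgt_channel = channel_of[tp],
            adj = wiring$adj, ptr = wiring$ptr,
            indeg = pmax(as.numeric(indeg), 1))
        }
      }
    }
  }

  pops <- lapply(seq_along(pop_names), function(p) {
    region <- region_of[p]
    gT <- if (region %in% c("GPe", "STN")) 0.06 else 0
    np <- neuron_params(gT = gT)
    list(name = pop_names[p], n = as.integer(n_of[p]),
         params = c(np$C, np$gL, np$VL, np$Vh, np$VT, np$gT,
                    np$tau_h_minus, np$tau_h_plus, np$Vb, np$Vr))
  })

  structure(list(pops = pops, pop_names = pop_names,
                 region_of = region_of, channel_of = channel_of,
                 projections = projections,
                 bg_rate_hz = as.numeric(config$bg_rate_hz[region_of]),
                 bg_g = as.numeric(config$bg_g[region_of]),
                 config = config, seed = seed, condition = NULL),
            class = "cbgt_network")
}

#' @export
print.cbgt_network <- function(x, ...) {
  n <- sum(vapply(x$pops, `[[`, 0L, "n"))
  cat("CBGT network:", length(x$pops), "populations,", n, "neurons,",
      length(x$projections), "projections\n")
  if (!is.null(x$condition)) cat("  reward condition:", x$condition, "\n")
  invisible(x)
}

#' Apply a reward-probability condition to the corticostriatal weights
#'
#' Scales the effective Ctx->dMSN conductance per channel by the condition's
#' `phi` values; Ctx->iMSN conductances are unchanged (their `phi` is 1 in
#' every condition).
#'
#' @param net a [build_cbgt_network()] result
#' @param condition `"low"`, `"med"` or `"high"` (or a one-row data.frame
#'   with `phi_LD`, `phi_RD`, `phi_LI`, `phi_RI`)
#' @return the network with scaled conductances
#' @export
apply_reward_condition <- function(net, condition) {
  stopifnot(inherits(net, "cbgt_network"))
  if (is.character(condition)) {
    phi <- net$config$phi
    row <- phi[phi$condition == condition, , drop = FALSE]
    if (nrow(row) != 1) stop("unknown reward condition: ", condition)
  } else {
    row <- condition
    condition <- row$condition %||% "custom"
  }
  for (j in seq_along(net$projections)) {
    pr <- net$projections[[j]]
    if (pr$src_region == "Ctx" && pr$tgt_region %in% c("dMSN", "iMSN")) {
      phi_val <- if (pr$tgt_region == "dMSN") {
        if (pr$tgt_channel == "L") row$phi_LD else row$phi_RD
      } else {
        if (pr$tgt_channel == "L") row$phi_LI else row$phi_RI
      }
      net$projections[[j]]$g <- pr$base_g * phi_val
    }
  }
  net$condition <- condition
  net
}

#' Sample a "subject" network around the base connectivity
#'
#' Every connectivity-table row's efficacy is independently resampled as
#' `g(k) ~ N(g, sigma_frac * g)` (non-positive draws are rejected and
#' redrawn, with the count reported), the per-row weight `omega = P * g(k)`
#' is recorded, and a network is built from the sampled table.
#'
#' @param config a [cbgt_config()] whose connectivity supplies the means
#' @param subject_seed integer seed (also seeds the wiring)
#' @param sigma_frac sd as a fraction of the mean efficacy (default 0.05)
#' @param build build the network (set `FALSE` to return only the sampled
#'   configuration, e.g. to inspect the sampling distribution cheaply)
#' @return a `cbgt_network` with fields `subject_seed`, `sampled_conn` (the
#'   resampled table with `omega`), and `n_resampled`; or, with
#'   `build = FALSE`, the sampled `cbgt_config` with those fields attached
#' @export
sample_subject_network <- function(config = cbgt_config(), subject_seed = 1,
                                   sigma_frac = 0.05, build = TRUE) {
  stopifnot(inherits(config, "cbgt_config"), sigma_frac >= 0)
  set.seed(subject_seed)
  conn <- config$conn
  n_resampled <- 0L
  g_new <- conn$g
  for (i in seq_along(g_new)) {
    repeat {
      gi <- rnorm(1, conn$g[i], sigma_frac * conn$g[i])
      if (gi > 0) break
      n_resampled <- n_resampled + 1L
    }
    g_new[i] <- gi
  }
  conn$g <- g_new
  conn$omega <- conn$P * conn$g
  config$conn <- conn
  if (!build) {
    config$subject_seed <- subject_seed
    config$n_resampled <- n_resampled
    return(config)
  }
  net <- build_cbgt_network(config, seed = subject_seed)
  net$subject_seed <- subject_seed
  net$sampled_conn <- conn
  net$n_resampled <- n_resampled
  net
}
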