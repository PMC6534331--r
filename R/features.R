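## Trialwise striatal summary statistics: areas under the population
## firing-rate curves between stimulus onset and the RT, min-max normalized
## across all trials in all conditions, composed into the four regressors
## used downstream: D_L - D_R, D_L - I_L, I_L - I_R, and I_all (the mean of
## the two channels' normalized iMSN components).

#' Area under a firing-rate trace
#'
#' Trapezoidal integral of a binned population rate over `[t0, t1]`, with
#' linear interpolation at the window edges. Bin `i` of the trace is taken
#' as a sample at time `t_start + (i - 1) * bin_ms`.
#'
#' @param trace numeric vector of rates (Hz) in consecutive bins
#' @param t0,t1 integration window (ms), `t1 > t0`
#' @param bin_ms bin width (ms)
#' @param t_start time of the first sample (ms)
#' @return integral in Hz x ms
#' @export
trial_auc <- function(trace, t0, t1, bin_ms = 1, t_start = 0) {
  stopifnot(t1 > t0)
  times <- t_start + (seq_along(trace) - 1) * bin_ms
  stopifnot(t0 >= times[1], t1 <= times[length(times)])
  grid <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
  y <- stats::approx(times, trace, xout = grid)$y
  sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
}

#' Min-max normalization to the unit interval
#'
#' @param x numeric vector with at least two distinct values
#' @return `(x - min) / (max - min)`
#' @export
normalize_unit <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(diff(r)) || diff(r) == 0) {
    stop("normalization degenerate: component has no spread")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Trialwise striatal summary regressors from an experiment
#'
#' For every decided trial, the AUC of the dMSN and iMSN population rates in
#' each channel is computed between stimulus onset and that trial's RT; the
#' four raw AUC components are then min-max normalized *pooled over all
#' trials in all conditions* (normalize-then-difference: each population's
#' AUC is normalized before the between-population differences are formed);
#' and the summaries are composed. Undecided trials are dropped with a log
#' message.
#'
#' @param experiment a `cbgt_experiment` with traces kept
#' @param onset_ms stimulus onset (defaults to the experiment's)
#' @return data.frame: `condition`, `trial`, `choice`, `rt_ms`, raw AUCs,
#'   and the summaries `d_diff` (D_L - D_R), `d_minus_i` (D_L - I_L),
#'   `i_diff` (I_L - I_R), `i_all`
#' @export
striatal_summaries <- function(experiment, onset_ms = NULL) {
  stopifnot(inherits(experiment, "cbgt_experiment"),
            !is.null(experiment$traces))
  onset_ms <- onset_ms %||% experiment$onset_ms
  trials <- experiment$trials
  rows <- list()
  n_undecided <- 0L
  for (i in seq_len(nrow(trials))) {
    cond <- trials$condition[i]
    tr <- trials$trial[i]
    if (is.na(trials$choice[i]) || trials$choice[i] == "none") {
      n_undecided <- n_undecided + 1L
      next
    }
    rt <- trials$rt_ms[i]
    if (rt <= onset_ms + 1) {
      # threshold crossing at stimulus onset leaves no integration window
      n_undecided <- n_undecided + 1L
      next
    }
    traces <- experiment$traces[[cond]][[tr]]
    if (is.null(traces)) next
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, trial = tr, choice = trials$choice[i], rt_ms = rt,
      auc_dL = trial_auc(traces["dMSN_L", ], onset_ms, rt),
      auc_dR = trial_auc(traces["dMSN_R", ], onset_ms, rt),
      auc_iL = trial_auc(traces["iMSN_L", ], onset_ms, rt),
      auc_iR = trial_auc(traces["iMSN_R", ], onset_ms, rt),
      stringsAsFactors = FALSE)
  }
  if (n_undecided > 0) {
    message(n_undecided, " undecided trial(s) excluded from striatal summaries")
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 2) {
    stop("need at least two decided trials for pooled normalization")
  }
  nd_L <- normalize_unit(out$auc_dL)
  nd_R <- normalize_unit(out$auc_dR)
  ni_L <- normalize_unit(out$auc_iL)
  ni_R <- normalize_unit(out$auc_iR)
  out$d_diff <- nd_L - nd_R
  out$d_minus_i <- nd_L - ni_L
  out$i_diff <- ni_L - ni_R
  out$i_all <- (ni_L + ni_R) / 2
  out
}

## Tiny ridge-penalized logistic regression by iterated reweighted least
## squares; fallback when glm reports perfect separation.
.ridge_logistic <- function(X, y, lambda = 1e-2, n_iter = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(n_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  drop(beta)
}

#' Regress behaviour on the striatal summary statistics
#'
#' Logistic regression of choice (L = 1) on the between- and within-channel
#' direct-pathway summaries (`d_diff`, `d_minus_i`), and linear regression
#' of RT on the indirect-pathway summaries (`i_diff`, `i_all`) with a
#' condition covariate. The RT regression uses correct (L-choice) trials
#' only, matching the behavioural RT summaries. If the logistic fit is
#' perfectly separated, a ridge-penalized fit is reported instead (flagged
#' in the output).
#'
#' @param summaries output of [striatal_summaries()] (or any data.frame with
#'   the same columns)
#' @return list with `choice_fit` (coefficient table), `rt_fit`
#'   (coefficient table), and `penalized` flag
#' @export
regress_behavior <- function(summaries) {
  d <- summaries[!is.na(summaries$choice) & summaries$choice != "none", ,
                 drop = FALSE]
  stopifnot(nrow(d) > 8)
  y <- as.integer(d$choice == "L")
  penalized <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ d_diff + d_minus_i, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        penalized <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  eta_hat <- predict(fit)
  separated <- all((eta_hat > 7) == (y == 1)) && max(abs(eta_hat)) > 10
  if (penalized || !fit$converged || separated ||
      any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50)) {
    penalized <- TRUE
    beta <- .ridge_logistic(d[, c("d_diff", "d_minus_i")], y)
    choice_fit <- data.frame(term = c("(Intercept)", "d_diff", "d_minus_i"),
                             estimate = beta, stringsAsFactors = FALSE)
  } else {
    sm <- summary(fit)$coefficients
    choice_fit <- data.frame(term = rownames(sm), estimate = sm[, 1],
                             se = sm[, 2], p = sm[, 4],
                             stringsAsFactors = FALSE)
  }
  dl <- d[d$choice == "L", , drop = FALSE]
  rt_form <- if (length(unique(dl$condition)) > 1) {
    rt_ms ~ i_diff + i_all + condition
  } else {
    rt_ms ~ i_diff + i_all
  }
  lf <- lm(rt_form, data = dl)
  sml <- summary(lf)$coefficients
  rt_fit <- data.frame(term = rownames(sml), estimate = sml[, 1],
                       se = sml[, 2], p = sml[, 4], stringsAsFactors = FALSE)
  list(choice_fit = choice_fit, rt_fit = rt_fit, penalized = penalized)
}

#' Condition means of the striatal summaries
#'
#' Mean of each summary regressor per condition, in the given condition
#' order; these are the condition-level regressor values used to transform
#' regression-model posteriors into per-condition parameters.
#'
#' @param summaries output of [striatal_summaries()]
#' @param conditions condition order
#' @return data.frame of condition means
#' @export
summary_condition_means <- function(summaries,
                                    conditions = unique(summaries$condition)) {
  comp <- c("d_diff", "d_minus_i", "i_diff", "i_all")
  out <- do.call(rbind, lapply(conditions, function(cc) {
    d <- summaries[summaries$condition == cc, comp, drop = FALSE]
    cbind(data.frame(condition = cc, stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(d))))
  }))
  out
}
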