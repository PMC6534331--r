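## MCMC fitting of DDM specifications: adaptive Metropolis-within-Gibbs on
## the natural parameter scale, with proposals adapted during burn-in only.
## Flat fits treat the data as one pool; hierarchical fits give every
## subject its own copy of each base/condition/intercept parameter under
## group-level normal priors whose mean and spread are sampled, while
## regression slopes are shared across subjects (fixed effects).

.ddm_init_theta <- function(pt, data) {
  theta <- pt$init
  names(theta) <- pt$name
  tr_rows <- pt$base == "tr" & pt$role %in% c("shared", "cond")
  if (any(tr_rows)) {
    theta[tr_rows] <- min(0.3, 0.75 * min(data$rt))
  }
  theta
}

.adapt_sd <- function(sd, rate, target = 0.44) {
  fac <- exp(2 * (rate - target))
  pmin(pmax(sd * fac, 1e-5), 50)
}

## One flat adaptive MwG run.  Returns draws (retained x n_par), deviance
## per retained draw, acceptance rates and final proposal sds.
.mcmc_flat <- function(data, model, n_samples = 2000, burn = 1200,
                       seed = NULL, log_floor = -300, adapt_interval = 25,
                       progress = FALSE) {
  stopifnot(n_samples > burn, nrow(data) > 0)
  if (!is.null(seed)) set.seed(seed)
  cond_levels <- levels(factor(data$condition))
  ctx <- .ddm_ll_ctx(data, model, cond_levels)
  pt <- ctx$pt
  np <- nrow(pt)
  theta <- .ddm_init_theta(pt, data)
  ll <- .ddm_ll_eval(theta, ctx, log_floor)
  lp <- .ddm_log_prior(theta, pt)
  stopifnot(is.finite(ll + lp))
  prop_sd <- ifelse(pt$unit, 0.05, ifelse(pt$base == "tr", 0.02, 0.15))
  n_keep <- n_samples - burn
  draws <- matrix(NA_real_, n_keep, np, dimnames = list(NULL, pt$name))
  deviance <- numeric(n_keep)
  acc <- int <- numeric(np)
  acc_total <- trials_total <- numeric(np)
  for (it in seq_len(n_samples)) {
    for (i in seq_len(np)) {
      prop <- theta
      prop[i] <- theta[i] + rnorm(1, 0, prop_sd[i])
      lp_new <- .ddm_log_prior(prop, pt)
      if (is.finite(lp_new)) {
        ll_new <- .ddm_ll_eval(prop, ctx, log_floor)
        if (log(runif(1)) < (ll_new + lp_new) - (ll + lp)) {
          theta <- prop; ll <- ll_new; lp <- lp_new
          acc[i] <- acc[i] + 1
          acc_total[i] <- acc_total[i] + 1
        }
      }
      int[i] <- int[i] + 1
      trials_total[i] <- trials_total[i] + 1
    }
    if (it <= burn && it %% adapt_interval == 0) {
      prop_sd <- .adapt_sd(prop_sd, acc / int)
      acc[] <- 0; int[] <- 0
    }
    if (it == burn) { acc_total[] <- 0; trials_total[] <- 0 }
    if (it > burn) {
      draws[it - burn, ] <- theta
      deviance[it - burn] <- -2 * as.numeric(ll)
    }
    if (progress && it %% 500 == 0) {
      message(sprintf("  iter %d / %d", it, n_samples))
    }
  }
  if (any(!is.finite(deviance))) stop("divergent deviance in MCMC chain")
  rates <- acc_total / pmax(trials_total, 1)
  if (any(rates < 0.1 | rates > 0.9)) {
    warning(sprintf(
      "post-adaptation acceptance rate outside [0.1, 0.9] for: %s",
      paste(pt$name[rates < 0.1 | rates > 0.9], collapse = ", ")))
  }
  list(draws = draws, deviance = deviance, accept = rates,
       prop_sd = prop_sd, par_table = pt, cond_levels = cond_levels)
}

## Hierarchical adaptive MwG: subject-level copies of every non-slope
## parameter with sampled group mean/sd; slopes are fixed effects.
.mcmc_hier <- function(data, model, n_samples = 2000, burn = 1200,
                       seed = NULL, log_floor = -300, adapt_interval = 25,
                       progress = FALSE) {
  stopifnot(n_samples > burn, "subject" %in% names(data))
  if (!is.null(seed)) set.seed(seed)
  subjects <- sort(unique(data$subject))
  K <- length(subjects)
  stopifnot(K >= 2)
  cond_levels <- levels(factor(data$condition))
  pt <- .ddm_par_table(model, cond_levels)
  np <- nrow(pt)
  varying <- pt$role != "slope"
  dat_k <- lapply(subjects, function(s) data[data$subject == s, , drop = FALSE])
  ctx_k <- lapply(dat_k, .ddm_ll_ctx, model = model,
                  cond_levels = cond_levels)
  mu <- .ddm_init_theta(pt, data)
  sig <- ifelse(pt$unit | pt$base == "tr", 0.05, 0.2)
  hyper_mean <- c(a = 1, v = 0, z = 0.5, tr = 0.3)
  mu_prior_mean <- ifelse(pt$role == "intercept" | pt$role %in%
                            c("shared", "cond"),
                          hyper_mean[pt$base], 0)
  Theta <- matrix(rep(mu, K), np, K, dimnames = list(pt$name, subjects))
  ll_k <- vapply(seq_len(K), function(k)
    .ddm_ll_eval(Theta[, k], ctx_k[[k]], log_floor), 0)
  stopifnot(all(is.finite(ll_k)))
  prop_sd_sub <- matrix(ifelse(pt$unit, 0.05,
                               ifelse(pt$base == "tr", 0.02, 0.15)), np, K)
  prop_sd_fix <- rep(0.1, np)
  prop_sd_sig <- rep(0.3, np)
  n_keep <- n_samples - burn
  gnames <- c(paste0("mu_", pt$name[varying]),
              paste0("sig_", pt$name[varying]), pt$name[!varying])
  gdraws <- matrix(NA_real_, n_keep, length(gnames),
                   dimnames = list(NULL, gnames))
  sdraws <- array(NA_real_, c(n_keep, np, K),
                  dimnames = list(NULL, pt$name, subjects))
  deviance <- numeric(n_keep)
  acc_sub <- int_sub <- matrix(0, np, K)
  acc_sig <- int_sig <- acc_fix <- int_fix <- numeric(np)
  vidx <- which(varying); fidx <- which(!varying)
  for (it in seq_len(n_samples)) {
    ## subject-level parameters
    for (k in seq_len(K)) {
      for (i in vidx) {
        prop <- Theta[, k]
        prop[i] <- prop[i] + rnorm(1, 0, prop_sd_sub[i, k])
        lpr_new <- dnorm(prop[i], mu[i], sig[i], log = TRUE)
        lpr_old <- dnorm(Theta[i, k], mu[i], sig[i], log = TRUE)
        ll_new <- .ddm_ll_eval(prop, ctx_k[[k]], log_floor)
        if (is.finite(ll_new) &&
            log(runif(1)) < (ll_new + lpr_new) - (ll_k[k] + lpr_old)) {
          Theta[, k] <- prop; ll_k[k] <- ll_new
          acc_sub[i, k] <- acc_sub[i, k] + 1
        }
        int_sub[i, k] <- int_sub[i, k] + 1
      }
    }
    ## fixed-effect slopes
    for (i in fidx) {
      newval <- Theta[i, 1] + rnorm(1, 0, prop_sd_fix[i])
      lp_new <- .ddm_log_prior_one(newval, pt$prior[i])
      if (is.finite(lp_new)) {
        lp_old <- .ddm_log_prior_one(Theta[i, 1], pt$prior[i])
        ll_new_k <- numeric(K)
        ok <- TRUE
        for (k in seq_len(K)) {
          cand <- Theta[, k]; cand[i] <- newval
          v <- .ddm_ll_eval(cand, ctx_k[[k]], log_floor)
          if (!is.finite(v)) { ok <- FALSE; break }
          ll_new_k[k] <- v
        }
        if (ok && log(runif(1)) <
            (sum(ll_new_k) + lp_new) - (sum(ll_k) + lp_old)) {
          Theta[i, ] <- newval; ll_k <- ll_new_k
          acc_fix[i] <- acc_fix[i] + 1
        }
      }
      int_fix[i] <- int_fix[i] + 1
    }
    ## group means: conjugate normal update (prior N(m0, 5))
    for (i in vidx) {
      prec <- K / sig[i]^2 + 1 / 25
      m <- (sum(Theta[i, ]) / sig[i]^2 + mu_prior_mean[i] / 25) / prec
      mu[i] <- rnorm(1, m, sqrt(1 / prec))
    }
    ## group sds: MH on log scale, half-normal(0, 2.5) prior
    for (i in vidx) {
      prop_sig <- sig[i] * exp(rnorm(1, 0, prop_sd_sig[i]))
      lr <- sum(dnorm(Theta[i, ], mu[i], prop_sig, log = TRUE)) -
        sum(dnorm(Theta[i, ], mu[i], sig[i], log = TRUE)) +
        dnorm(prop_sig, 0, 2.5, log = TRUE) -
        dnorm(sig[i], 0, 2.5, log = TRUE) +
        log(prop_sig) - log(sig[i])   # Jacobian of the log transform
      if (log(runif(1)) < lr) {
        sig[i] <- prop_sig
        acc_sig[i] <- acc_sig[i] + 1
      }
      int_sig[i] <- int_sig[i] + 1
    }
    if (it <= burn && it %% adapt_interval == 0) {
      prop_sd_sub <- matrix(.adapt_sd(prop_sd_sub, acc_sub / pmax(int_sub, 1)),
                            np, K)
      prop_sd_fix <- .adapt_sd(prop_sd_fix, acc_fix / pmax(int_fix, 1))
      prop_sd_sig <- .adapt_sd(prop_sd_sig, acc_sig / pmax(int_sig, 1),
                               target = 0.3)
      acc_sub[] <- 0; int_sub[] <- 0; acc_fix[] <- 0; int_fix[] <- 0
      acc_sig[] <- 0; int_sig[] <- 0
    }
    if (it > burn) {
      row <- it - burn
      gdraws[row, ] <- c(mu[vidx], sig[vidx], Theta[fidx, 1])
      sdraws[row, , ] <- Theta
      deviance[row] <- -2 * sum(ll_k)
    }
    if (progress && it %% 200 == 0) {
      message(sprintf("  hier iter %d / %d", it, n_samples))
    }
  }
  if (any(!is.finite(deviance))) stop("divergent deviance in MCMC chain")
  list(draws = gdraws, subject_draws = sdraws, deviance = deviance,
       accept = NULL, par_table = pt, cond_levels = cond_levels,
       subjects = subjects)
}

#' Fit a drift-diffusion model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampling of the joint posterior of a DDM
#' specification given a choice/RT table. `n_samples` MCMC samples are drawn
#' in total and the first `burn` are discarded (proposal scales adapt during
#' burn-in only). With `hierarchical = TRUE` (requires a `subject` column and
#' at least two subjects), every non-slope parameter receives subject-level
#' copies under sampled group-level normal priors, and regression slopes are
#' estimated as fixed effects shared across subjects.
#'
#' @param data behaviour table: columns `rt` (seconds), `response`
#'   (`"upper"`/`"lower"`; the upper boundary is the L, higher-reward,
#'   choice), `condition`, optionally `subject` and regressor columns
#' @param model a [ddm_model()]
#' @param n_samples total MCMC samples (default 2000)
#' @param burn burn-in samples discarded (default 1200)
#' @param hierarchical fit subject-level parameters under group priors
#' @param seed integer seed for reproducibility
#' @param log_floor floor on per-trial log-densities
#' @param progress print progress messages
#' @return an object of class `ddm_fit` with `print`, `summary`, `coef`,
#'   `simulate`, `predict` and `plot` methods
#' @export
#' @examples
#' \donttest{
#' d <- simulate_ddm(200, a = 1, v = 1.5, z_rel = 0.5, tr = 0.25, seed = 1)
#' d$condition <- "one"
#' fit <- ddm_fit(d, ddm_model(), n_samples = 400, burn = 200, seed = 1)
#' coef(fit)
#' }
ddm_fit <- function(data, model = ddm_model(), n_samples = 2000, burn = 1200,
                    hierarchical = FALSE, seed = NULL, log_floor = -300,
                    progress = FALSE) {
  stopifnot(inherits(model, "ddm_model"))
  data <- data[!is.na(data$response) & !is.na(data$rt), , drop = FALSE]
  stopifnot(nrow(data) > 0)
  if (hierarchical && (!"subject" %in% names(data) ||
                       length(unique(data$subject)) < 2)) {
    warning("hierarchical fit requires >= 2 subjects; falling back to a flat fit")
    hierarchical <- FALSE
  }
  res <- if (hierarchical) {
    .mcmc_hier(data, model, n_samples, burn, seed, log_floor,
               progress = progress)
  } else {
    .mcmc_flat(data, model, n_samples, burn, seed, log_floor,
               progress = progress)
  }
  fit <- structure(
    list(model = model, draws = res$draws, deviance = res$deviance,
         subject_draws = res$subject_draws, accept = res$accept,
         par_table = res$par_table, cond_levels = res$cond_levels,
         subjects = res$subjects, hierarchical = hierarchical,
         n_samples = n_samples, burn = burn, seed = seed, data = data,
         call = match.call()),
    class = "ddm_fit")
  fit$dic <- compute_dic(fit)
  fit
}

#' Deviance information criterion of a fitted DDM
#'
#' `DIC = D(theta_bar) + 2 pD` with `pD = mean(D) - D(theta_bar)`
#' (equivalently `mean(D) + pD`), where `D` is the per-draw deviance and
#' `theta_bar` the posterior mean. A negative `pD` is reported, not clamped.
#'
#' @param fit a `ddm_fit`
#' @param null optional reference fit; if given, `delta_dic = DIC - DIC_null`
#'   is included
#' @return list with `dic`, `pD`, `mean_deviance`, `deviance_at_mean`, and
#'   optionally `delta_dic`
#' @export
compute_dic <- function(fit, null = NULL) {
  stopifnot(inherits(fit, "ddm_fit") || is.list(fit))
  mean_dev <- mean(fit$deviance)
  if (isTRUE(fit$hierarchical)) {
    theta_bar <- apply(fit$subject_draws, c(2, 3), mean)
    subjects <- fit$subjects
    dev_at_mean <- -2 * sum(vapply(seq_along(subjects), function(k) {
      dk <- fit$data[fit$data$subject == subjects[k], , drop = FALSE]
      as.numeric(ddm_loglik(theta_bar[, k], dk, fit$model))
    }, 0))
  } else {
    theta_bar <- colMeans(fit$draws)
    dev_at_mean <- -2 * as.numeric(ddm_loglik(theta_bar, fit$data, fit$model))
  }
  pD <- mean_dev - dev_at_mean
  out <- list(dic = dev_at_mean + 2 * pD, pD = pD, mean_deviance = mean_dev,
              deviance_at_mean = dev_at_mean)
  if (!is.null(null)) out$delta_dic <- out$dic - compute_dic(null)$dic
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Drift-diffusion model fit (", if (x$hierarchical) "hierarchical"
      else "flat", ")\n", sep = "")
  cat("  model:     ", x$model$label, "\n")
  cat("  trials:    ", nrow(x$data), "  conditions: ",
      paste(x$cond_levels, collapse = ", "), "\n", sep = "")
  cat(sprintf("  samples:    %d (burn-in %d)\n", x$n_samples, x$burn))
  cat(sprintf("  DIC:        %.2f  (pD = %.2f)\n", x$dic$dic, x$dic$pD))
  cat("  posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) colMeans(object$draws)

#' @export
summary.ddm_fit <- function(object, ...) {
  qs <- t(apply(object$draws, 2, quantile, c(0.025, 0.5, 0.975)))
  out <- data.frame(mean = colMeans(object$draws),
                    sd = apply(object$draws, 2, sd),
                    q025 = qs[, 1], median = qs[, 2], q975 = qs[, 3])
  n <- nrow(object$draws)
  out$lag1_acf <- apply(object$draws, 2, function(x) {
    if (sd(x) == 0) return(NA_real_)
    stats::cor(x[-1], x[-n])
  })
  if (!is.null(object$accept)) out$accept <- object$accept
  out
}

#' Posterior-predictive simulation from a fitted DDM
#'
#' Draws `nsim` parameter vectors from the posterior and simulates one
#' synthetic dataset per draw with the design (condition labels and
#' regressor values) of the fitted data.
#'
#' @param object a `ddm_fit`
#' @param nsim number of posterior draws / datasets
#' @param seed optional seed
#' @param ... unused
#' @return list of data.frames with columns `rt`, `response`, `condition`
#' @export
simulate.ddm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cond_idx <- as.integer(factor(object$data$condition,
                                levels = object$cond_levels))
  rows <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(rows, function(r) {
    tp <- .ddm_trial_params(object$draws[r, ], object$par_table,
                            object$model, cond_idx, object$data)
    if (is.null(tp)) stop("invalid posterior draw for simulation")
    sim <- simulate_ddm(length(cond_idx), a = tp$a, v = tp$v, z_rel = tp$z,
                        tr = tp$tr)
    sim$condition <- object$data$condition
    sim
  })
}

#' Transform regression-model posteriors into per-condition parameters
#'
#' For a regression DDM, the per-condition parameter posterior is the affine
#' transform of the intercept and slope draws by the condition-mean regressor
#' value: e.g. `a_j = beta0_a + beta_a[j] * I_j` and
#' `v_j = beta0_v + beta_v[j] * dD_j`. For condition-free ("free") models the
#' per-condition draws are returned directly.
#'
#' @param fit a `ddm_fit`
#' @param cond_means named list: for each regressed parameter, the vector of
#'   condition-mean regressor values (one per condition, in the order of
#'   `fit$cond_levels`); ignored for non-regression parameters
#' @return list with one element per transformed parameter: a draws matrix
#'   (columns = conditions) plus a `summary` data.frame
#' @export
posterior_to_condition_params <- function(fit, cond_means = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  out <- list()
  nc <- length(fit$cond_levels)
  for (p in unique(fit$par_table$base)) {
    rows <- fit$par_table$base == p
    roles <- fit$par_table$role[rows]
    if (any(roles == "slope")) {
      reg <- fit$model$regress[[p]]
      if (is.null(cond_means) || is.null(cond_means[[p]])) {
        stop("cond_means must supply condition-mean regressor values for ", p)
      }
      m <- cond_means[[p]]
      stopifnot(length(m) == nc)
      b0 <- fit$draws[, fit$par_table$name[rows][roles == "intercept"]]
      sl <- fit$draws[, fit$par_table$name[rows][roles == "slope"],
                      drop = FALSE]
      draws <- b0 + sweep(sl, 2, m, `*`)
    } else if (any(roles == "cond")) {
      draws <- fit$draws[, fit$par_table$name[rows], drop = FALSE]
    } else {
      next
    }
    colnames(draws) <- fit$cond_levels
    out[[p]] <- list(
      draws = draws,
      summary = data.frame(condition = fit$cond_levels,
                           mean = colMeans(draws),
                           sd = apply(draws, 2, sd)))
  }
  out
}

#' @export
predict.ddm_fit <- function(object, cond_means = NULL, ...) {
  posterior_to_condition_params(object, cond_means)
}

#' @export
plot.ddm_fit <- function(x, pars = NULL, ...) {
  pars <- pars %||% head(colnames(x$draws), 6)
  old <- graphics::par(mfrow = c(length(pars), 2), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(x$draws[, p], type = "l", ylab = p, xlab = "")
    graphics::plot(density(x$draws[, p]), main = "", xlab = p)
  }
  invisible(x)
}
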