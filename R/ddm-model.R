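## DDM model specifications and the (regression-)DDM likelihood.
##
## A model is defined by which of the four parameters (a, v, z, tr) vary by
## condition ("free") and which are driven by a trialwise neural regressor
## ("regress"), in which case the parameter on trial t in condition j is
##   p_t = beta0_p + beta_pj * X_t
## with a shared intercept and one slope per condition.  All remaining
## parameters are shared across conditions.  The diffusion coefficient is
## fixed at sigma = 1 (the scaling convention all drift/boundary values in
## this package are reported on).

#' Specify a drift-diffusion model
#'
#' @param free character vector, subset of `c("a", "v", "z", "tr")`: parameters
#'   that take an independent value in every condition
#' @param regress named list mapping a parameter (`"v"`, `"a"`, or `"z"`) to
#'   the name of a trialwise regressor column; the parameter then becomes an
#'   affine function of the regressor with a shared intercept and
#'   per-condition slopes
#' @param label optional model label
#' @return object of class `ddm_model`
#' @export
#' @examples
#' ddm_model(free = "v")                             # drift varies by condition
#' ddm_model(regress = list(v = "d_diff", a = "i_all"))  # regression model
ddm_model <- function(free = character(), regress = list(), label = NULL) {
  pars <- c("a", "v", "z", "tr")
  stopifnot(all(free %in% pars))
  if (length(regress)) {
    stopifnot(!is.null(names(regress)),
              all(names(regress) %in% c("a", "v", "z")),
              !any(names(regress) %in% free))
  }
  if (is.null(label)) {
    label <- if (!length(free) && !length(regress)) "null" else {
      bits <- c(free, vapply(names(regress),
                             function(p) paste0(p, "~", regress[[p]]), ""))
      paste(bits, collapse = ",")
    }
  }
  structure(list(free = free, regress = regress, label = label),
            class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("DDM model:", x$label, "\n")
  invisible(x)
}

## Build the scalar-parameter table for a model given the condition levels.
## Roles: shared, cond (one per condition), intercept, slope (one per
## condition).
.ddm_par_table <- function(model, cond_levels) {
  rows <- list()
  add <- function(name, base, role, cond, prior, init, positive = FALSE,
                  unit = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, base = base, role = role,
      cond = if (is.null(cond)) NA_integer_ else cond,
      prior = prior, init = init, positive = positive, unit = unit,
      stringsAsFactors = FALSE)
  }
  inits <- c(a = 1.2, v = 1, z = 0.5, tr = 0.3)
  priors <- c(a = "halfnormal", v = "normal", z = "unif01", tr = "trnorm")
  for (p in c("a", "v", "z", "tr")) {
    if (p %in% model$free) {
      for (j in seq_along(cond_levels)) {
        add(sprintf("%s[%s]", p, cond_levels[j]), p, "cond", j, priors[[p]],
            inits[[p]], positive = p %in% c("a", "tr"), unit = p == "z")
      }
    } else if (p %in% names(model$regress)) {
      add(sprintf("%s_int", p), p, "intercept", NULL,
          if (p == "a") "halfnormal" else "normal", inits[[p]],
          positive = FALSE, unit = FALSE)
      for (j in seq_along(cond_levels)) {
        add(sprintf("%s_slope[%s]", p, cond_levels[j]), p, "slope", j,
            "normal", 0)
      }
    } else {
      add(p, p, "shared", NULL, priors[[p]], inits[[p]],
          positive = p %in% c("a", "tr"), unit = p == "z")
    }
  }
  do.call(rbind, rows)
}

.ddm_log_prior_one <- function(x, type) {
  switch(type,
         normal = dnorm(x, 0, 5, log = TRUE),
         halfnormal = if (x <= 0) -Inf else dnorm(x, 0, 5, log = TRUE) + log(2),
         unif01 = if (x <= 0 || x >= 1) -Inf else 0,
         trnorm = if (x < 0) -Inf else
           dnorm(x, 0.3, 0.25, log = TRUE) - pnorm(0, 0.3, 0.25,
                                                   lower.tail = FALSE,
                                                   log.p = TRUE),
         stop("unknown prior type: ", type))
}

.ddm_log_prior <- function(theta, par_table) {
  lp <- 0
  for (i in seq_along(theta)) {
    lp <- lp + .ddm_log_prior_one(theta[i], par_table$prior[i])
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

## Assemble per-trial parameter vectors from a scalar parameter vector.
## Returns NULL if the assembled values are invalid (non-positive boundary,
## start point outside (0,1), negative non-decision time).
.ddm_trial_params <- function(theta, par_table, model, cond_idx, X) {
  n <- length(cond_idx)
  out <- list()
  for (p in c("a", "v", "z", "tr")) {
    rows <- par_table$base == p
    if (p %in% model$free) {
      vals <- theta[rows][match(cond_idx, par_table$cond[rows])]
    } else if (p %in% names(model$regress)) {
      b0 <- theta[rows & par_table$role == "intercept"]
      slopes <- theta[rows & par_table$role == "slope"]
      vals <- b0 + slopes[cond_idx] * X[[model$regress[[p]]]]
    } else {
      vals <- rep_len(theta[rows], n)
    }
    out[[p]] <- vals
  }
  if (any(out$a <= 0) || any(out$z <= 0) || any(out$z >= 1) ||
      any(out$tr < 0)) {
    return(NULL)
  }
  out
}

## Vectorized boundary-specific log-density with per-trial parameters.
## Structural zeros (rt <= tr) yield -Inf; genuine numerical underflow is
## floored at `log_floor` and counted.
.wfpt_logdens <- function(rt, upper, a, v, z, tr, eps = 1e-7,
                          log_floor = -300) {
  z2 <- ifelse(upper, 1 - z, z)
  v2 <- ifelse(upper, -v, v)
  tt <- rt - tr
  ld <- rep(-Inf, length(rt))
  ok <- tt > 0
  n_floor <- 0L
  if (any(ok)) {
    u <- tt[ok] / a[ok]^2
    kern <- .wfpt_kernel(u, z2[ok], eps)
    val <- log(kern) - 2 * log(a[ok]) - v2[ok] * a[ok] * z2[ok] -
      v2[ok]^2 * tt[ok] / 2
    flo <- !is.finite(val) | val < log_floor
    n_floor <- sum(flo)
    val[flo] <- log_floor
    ld[ok] <- val
  }
  structure(ld, n_floored = n_floor)
}

## Precompute everything the likelihood needs so MCMC sweeps avoid repeated
## factor/table construction.
.ddm_ll_ctx <- function(data, model, cond_levels = NULL) {
  cond_levels <- cond_levels %||% levels(factor(data$condition))
  pt <- .ddm_par_table(model, cond_levels)
  X <- list()
  for (p in names(model$regress)) {
    col <- model$regress[[p]]
    if (is.null(data[[col]])) stop("missing regressor column: ", col)
    X[[col]] <- data[[col]]
  }
  list(pt = pt, cond_levels = cond_levels,
       cond_idx = as.integer(factor(data$condition, levels = cond_levels)),
       rt = data$rt, upper = data$response == "upper", X = X,
       model = model)
}

.ddm_ll_eval <- function(theta, ctx, log_floor = -300) {
  tp <- .ddm_trial_params(theta, ctx$pt, ctx$model, ctx$cond_idx, ctx$X)
  if (is.null(tp)) return(-Inf)
  ld <- .wfpt_logdens(ctx$rt, ctx$upper, tp$a, tp$v, tp$z, tp$tr,
                      log_floor = log_floor)
  sum(ld)
}

#' Log-likelihood of a choice/RT table under a DDM model specification
#'
#' Per-trial parameter values are assembled from the scalar parameter vector
#' (shared values, per-condition values, or regression intercept + condition
#' slope times the trial regressor), and boundary-specific Wiener
#' first-passage log-densities are summed. Trials with `rt <= tr` make the
#' likelihood `-Inf`; numerical underflow in admissible trials is floored at
#' `log_floor` (the number of floored trials is reported as an attribute).
#'
#' @param theta named numeric vector of scalar parameters, in the order of the
#'   model's parameter table (see [ddm_fit()] for the fitted interface)
#' @param data behaviour table with columns `rt` (s), `response`
#'   (`"upper"`/`"lower"`), `condition`, and any regressor columns the model
#'   names
#' @param model a [ddm_model()]
#' @param log_floor floor for per-trial log-densities
#' @return scalar log-likelihood with attribute `n_floored`
#' @export
ddm_loglik <- function(theta, data, model, log_floor = -300) {
  cond_levels <- levels(factor(data$condition))
  pt <- .ddm_par_table(model, cond_levels)
  stopifnot(length(theta) == nrow(pt))
  cond_idx <- as.integer(factor(data$condition, levels = cond_levels))
  tp <- .ddm_trial_params(theta, pt, model, cond_idx, data)
  if (is.null(tp)) return(structure(-Inf, n_floored = 0L))
  ld <- .wfpt_logdens(data$rt, data$response == "upper",
                      tp$a, tp$v, tp$z, tp$tr, log_floor = log_floor)
  structure(sum(ld), n_floored = attr(ld, "n_floored"))
}
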