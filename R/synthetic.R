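## Synthetic choice/RT datasets with known ground truth, emulating the
## statistical structure of the CBGT-derived behaviour tables: per-condition
## Wiener-process choice/RT data plus trialwise striatal-summary regressors
## that couple linearly to drift rate and boundary height.  These stand in
## for network output so the DDM stage can be tested without simulating the
## spiking model.

#' Design for a synthetic DDM dataset
#'
#' Two generating modes. In *regression* mode (the default), each trial's
#' drift and boundary are affine functions of trialwise regressors,
#' `v_t = beta0_v + beta_v[j] * dD_t` and `a_t = beta0_a + beta_a[j] * I_t`,
#' with regressors drawn from per-condition Beta distributions (bounded in
#' \[0, 1\] like the normalized striatal summaries). In *fixed-parameter*
#' mode (`params_by_cond` supplied), each condition has its own generating
#' `(a, v, z, tr)` and regressors are still emitted but uncoupled.
#'
#' Default condition means mirror the fitted values reported for the
#' best regression model: condition drift around 1.4 / 3.6 / 5.1 and
#' boundary around 0.93 / 1.03 / 1.02 across low / med / high.
#'
#' @param conditions condition labels, ordered
#' @param trials_per_cond trials per condition
#' @param beta0_v,beta_v drift intercept and per-condition slopes on `d_diff`
#' @param beta0_a,beta_a boundary intercept and per-condition slopes on `i_all`
#' @param z_rel,tr shared start point and non-decision time (s)
#' @param regressor_means list of per-condition mean vectors for the four
#'   components `d_diff`, `d_minus_i`, `i_diff`, `i_all`
#' @param regressor_conc Beta concentration (larger = tighter regressors)
#' @param params_by_cond optional list (one element per condition) of lists
#'   with entries `a`, `v`, `z_rel`, `tr`; switches to fixed-parameter mode
#' @return object of class `synthetic_design`
#' @export
synthetic_design <- function(conditions = c("low", "med", "high"),
                             trials_per_cond = 200,
                             beta0_v = 0.2,
                             beta_v = c(12.3, 13.7, 12.25),
                             beta0_a = 0.75,
                             beta_a = c(0.40, 0.51, 0.54),
                             z_rel = 0.5, tr = 0.3,
                             regressor_means = list(
                               d_diff = c(0.10, 0.25, 0.40),
                               d_minus_i = c(0.15, 0.30, 0.45),
                               i_diff = c(0.10, 0.20, 0.30),
                               i_all = c(0.45, 0.55, 0.50)),
                             regressor_conc = 30,
                             params_by_cond = NULL) {
  nc <- length(conditions)
  stopifnot(nc >= 1, trials_per_cond >= 0,
            length(beta_v) == nc, length(beta_a) == nc,
            all(vapply(regressor_means, length, 0L) == nc),
            z_rel > 0, z_rel < 1, tr >= 0)
  if (!is.null(params_by_cond)) stopifnot(length(params_by_cond) == nc)
  structure(list(conditions = conditions,
                 trials_per_cond = trials_per_cond,
                 beta0_v = beta0_v, beta_v = beta_v,
                 beta0_a = beta0_a, beta_a = beta_a,
                 z_rel = z_rel, tr = tr,
                 regressor_means = regressor_means,
                 regressor_conc = regressor_conc,
                 params_by_cond = params_by_cond),
            class = "synthetic_design")
}

.rbeta_mean <- function(n, mean, conc) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Generate a synthetic behaviour table with ground truth
#'
#' Draws trialwise regressors, forms per-trial drift/boundary via the
#' design's regression structure (or uses fixed per-condition parameters),
#' and simulates one first passage per trial by Euler-Maruyama. The upper
#' boundary corresponds to the L (correct, higher-reward) response.
#'
#' @param design a [synthetic_design()]
#' @param seed integer seed (the generator is fully seed-deterministic)
#' @return list with `data` (behaviour table: `condition`, `response`, `rt`,
#'   the four regressor columns, `correct`) and `truth` (the design plus the
#'   realized per-condition parameter means)
#' @export
generate_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  if (!is.null(seed)) set.seed(seed)
  nc <- length(design$conditions)
  n <- design$trials_per_cond * nc
  cond_idx <- rep(seq_len(nc), each = design$trials_per_cond)
  comp <- lapply(names(design$regressor_means), function(nm) {
    .rbeta_mean(n, design$regressor_means[[nm]][cond_idx],
                design$regressor_conc)
  })
  names(comp) <- names(design$regressor_means)
  if (is.null(design$params_by_cond)) {
    v_t <- design$beta0_v + design$beta_v[cond_idx] * comp$d_diff
    a_t <- design$beta0_a + design$beta_a[cond_idx] * comp$i_all
    z_t <- rep(design$z_rel, n)
    tr_t <- rep(design$tr, n)
  } else {
    pc <- design$params_by_cond
    a_t <- vapply(pc, `[[`, 0, "a")[cond_idx]
    v_t <- vapply(pc, `[[`, 0, "v")[cond_idx]
    z_t <- vapply(pc, `[[`, 0, "z_rel")[cond_idx]
    tr_t <- vapply(pc, `[[`, 0, "tr")[cond_idx]
  }
  stopifnot(all(a_t > 0))
  if (n > 0) {
    sim <- simulate_ddm(n, a = a_t, v = v_t, z_rel = z_t, tr = tr_t)
  } else {
    sim <- data.frame(rt = numeric(0), response = character(0))
  }
  data <- data.frame(condition = design$conditions[cond_idx],
                     response = sim$response, rt = sim$rt,
                     stringsAsFactors = FALSE)
  for (nm in names(comp)) data[[nm]] <- comp[[nm]]
  data$correct <- data$response == "upper"
  truth <- list(design = design,
                cond_param_means = data.frame(
                  condition = design$conditions,
                  v = vapply(seq_len(nc), function(j)
                    mean(v_t[cond_idx == j]), 0),
                  a = vapply(seq_len(nc), function(j)
                    mean(a_t[cond_idx == j]), 0),
                  z_rel = vapply(seq_len(nc), function(j)
                    mean(z_t[cond_idx == j]), 0),
                  tr = vapply(seq_len(nc), function(j)
                    mean(tr_t[cond_idx == j]), 0)))
  list(data = data, truth = truth)
}

#' Generate a multi-subject synthetic dataset
#'
#' Subject-level drift and boundary intercepts are drawn around the group
#' values with the given between-subject standard deviations; slopes and the
#' remaining parameters are shared, mirroring a fixed-effects regression
#' structure. With `sd_v = sd_a = 0` all subjects share the group truth.
#'
#' @param design a [synthetic_design()]
#' @param n_subjects number of subjects
#' @param sd_v,sd_a between-subject sd of the drift and boundary intercepts
#' @param seed integer seed
#' @return list with `data` (stacked behaviour table with a `subject`
#'   column) and `truth` (group design plus per-subject intercepts)
#' @export
generate_subjects <- function(design, n_subjects = 15, sd_v = 0.2,
                              sd_a = 0.05, seed = NULL) {
  stopifnot(inherits(design, "synthetic_design"), n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- derive_seeds(seed %||% 1L, n_subjects)
  b0v <- rnorm(n_subjects, design$beta0_v, sd_v)
  b0a <- pmax(rnorm(n_subjects, design$beta0_a, sd_a), 0.05)
  out <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    dk <- design
    dk$beta0_v <- b0v[k]
    dk$beta0_a <- b0a[k]
    g <- generate_dataset(dk, seed = seeds[k])
    g$data$subject <- k
    out[[k]] <- g$data
  }
  list(data = do.call(rbind, out),
       truth = list(design = design, beta0_v = b0v, beta0_a = b0a))
}
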