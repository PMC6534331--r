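## Wiener first-passage-time (Navarro-Fuss) density for the drift diffusion
## model
##
##   d theta = v dt + sigma dW,   theta(t <= tr) = z * a,
##
## absorbing boundaries at 0 (lower, "R") and a (upper, "L").  The
## lower-boundary density is evaluated through the series
##
##   f(t) = pi/a^2 exp(-v z - v^2 (t - tr)/2)
##          * sum_k k exp(-k^2 pi^2 (t - tr) / (2 a^2)) sin(k pi z / a),
##
## with the upper-boundary density obtained by the reflection z -> a - z,
## v -> -v.  Two equivalent expansions of the scale-free kernel exist: the
## series above converges quickly for large normalized time u = (t - tr)/a^2
## while an image-charge expansion converges quickly for small u; the
## implementation picks whichever needs fewer terms at the requested error
## bound (Navarro & Fuss 2009).

## Number of terms needed at normalized time u for tolerance eps.
.wfpt_k_large <- function(u, eps) {
  k <- ifelse(pi * u * eps < 1,
              sqrt(-2 * log(pi * u * eps) / (pi^2 * u)),
              1 / (pi * sqrt(u)))
  pmax(ceiling(k), 1)
}

.wfpt_k_small <- function(u, eps) {
  b <- 2 * eps * sqrt(2 * pi * u)
  k <- ifelse(b < 1,
              2 + sqrt(-2 * u * log(b)),
              2)
  pmax(ceiling(k), 2)
}

## Scale-free kernel f(u, w): density of first passage through 0 at
## normalized time u for a zero-drift unit-diffusion process started at w in
## (0, 1) with boundaries {0, 1}.  `w` may be scalar or of the same length
## as `u`.
.wfpt_kernel <- function(u, w, eps) {
  n <- length(u)
  w <- rep_len(w, n)
  out <- numeric(n)
  kl <- .wfpt_k_large(u, eps)
  ks <- .wfpt_k_small(u, eps)
  if (any(pmin(kl, ks) > 1e5)) {
    bad <- which(pmin(kl, ks) > 1e5)[1]
    stop(sprintf(
      "wfpt series did not converge at tolerance %g (normalized time u = %g)",
      eps, u[bad]))
  }
  use_small <- ks < kl
  if (any(use_small)) {
    us <- u[use_small]
    ws <- w[use_small]
    K <- max(ks[use_small])
    ks_idx <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    acc <- 0
    for (k in ks_idx) {
      acc <- acc + (ws + 2 * k) * exp(-(ws + 2 * k)^2 / (2 * us))
    }
    out[use_small] <- acc / sqrt(2 * pi * us^3)
  }
  if (any(!use_small)) {
    ul <- u[!use_small]
    wl <- w[!use_small]
    K <- max(kl[!use_small])
    acc <- 0
    for (k in seq_len(K)) {
      acc <- acc + k * exp(-k^2 * pi^2 * ul / 2) * sin(k * pi * wl)
    }
    out[!use_small] <- pi * acc
  }
  pmax(out, 0)
}

#' Wiener first-passage-time density
#'
#' Boundary-specific response-time density of the drift diffusion model with
#' drift `v`, boundary separation `a`, relative start point `z_rel`, and
#' non-decision time `tr`. Density is zero for `t <= tr`. The diffusion
#' coefficient defaults to `sigma = 1`; all drift and boundary values in this
#' package are on that scale.
#'
#' @param t response time in seconds (vectorized)
#' @param a boundary separation (> 0)
#' @param v drift rate
#' @param z_rel relative start point z/a in (0, 1)
#' @param tr non-decision time in seconds (>= 0)
#' @param boundary `"lower"` or `"upper"`; the upper boundary corresponds to
#'   the L (higher-reward) response in the behavioural mapping
#' @param sigma diffusion coefficient (fixed scaling constant)
#' @param eps truncation error bound for the series
#' @return vector of densities (1/s)
#' @export
#' @examples
#' dwfpt(0.5, a = 1, v = 2, z_rel = 0.5, tr = 0.2, boundary = "upper")
dwfpt <- function(t, a, v, z_rel, tr, boundary = c("lower", "upper"),
                  sigma = 1, eps = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(a > 0, z_rel > 0, z_rel < 1, tr >= 0, sigma > 0, all(is.finite(t)))
  if (boundary == "upper") {
    z_rel <- 1 - z_rel
    v <- -v
  }
  ## rescale to unit diffusion
  a <- a / sigma
  v <- v / sigma
  out <- numeric(length(t))
  pos <- t > tr
  if (any(pos)) {
    tt <- t[pos] - tr
    u <- tt / a^2
    kern <- .wfpt_kernel(u, z_rel, eps)
    out[pos] <- kern / a^2 * exp(-v * a * z_rel - v^2 * tt / 2)
  }
  out
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form absorption probability for the drift diffusion process,
#' `(1 - exp(-2 v z / sigma^2)) / (1 - exp(-2 v a / sigma^2))` with
#' `z = z_rel * a`, reducing to `z_rel` when `v = 0`.
#'
#' @inheritParams dwfpt
#' @return probability of terminating at the upper boundary
#' @export
ddm_choice_prob <- function(v, a, z_rel, sigma = 1) {
  stopifnot(a > 0, z_rel > 0, z_rel < 1)
  z <- z_rel * a
  ifelse(abs(v) < 1e-10,
         z_rel,
         (1 - exp(-2 * v * z / sigma^2)) / (1 - exp(-2 * v * a / sigma^2)))
}

#' Simulate first passages of the drift diffusion model
#'
#' Euler-Maruyama integration of the diffusion from `z_rel * a` until
#' absorption at 0 or `a`; the returned RT is `tr` plus the passage time.
#' Paths still unabsorbed at `t_max` are censored and flagged with
#' `response = NA`.
#'
#' @inheritParams dwfpt
#' @param n number of trials
#' @param dt integration step (s)
#' @param t_max simulation horizon for the accumulation stage (s)
#' @param seed optional integer seed
#' @return data.frame with columns `rt` (s) and `response`
#'   (`"upper"`/`"lower"`, `NA` if censored)
#' @export
simulate_ddm <- function(n, a, v, z_rel, tr, sigma = 1, dt = 1e-4,
                         t_max = 20, seed = NULL) {
  stopifnot(n >= 1, all(a > 0), all(z_rel > 0), all(z_rel < 1), all(tr >= 0),
            dt > 0)
  if (!is.null(seed)) set.seed(seed)
  sim <- ddm_sim_cpp(as.integer(n), rep_len(a, n), rep_len(v, n),
                     rep_len(z_rel, n), sigma, dt, t_max)
  resp <- ifelse(is.na(sim$upper), NA_character_,
                 ifelse(sim$upper == 1L, "upper", "lower"))
  data.frame(rt = rep_len(tr, n) + sim$t, response = resp,
             stringsAsFactors = FALSE)
}
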