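#' @useDynLib cbgtddm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom quantile sd glm lm
#'   binomial coef plogis qlogis aggregate complete.cases rbeta setNames
#'   simulate predict density
#' @importFrom utils write.csv head
NULL

#' Draw from a truncated normal distribution by rejection
#'
#' Rejection sampling against the untruncated normal; exact, and cheap for the
#' mild truncations used here (e.g. the per-trial cortical drive, which is
#' N(2.5, 0.06) clipped to \[2.4, 2.6\]).
#'
#' @param n number of draws
#' @param mean,sd normal parameters
#' @param lower,upper truncation bounds
#' @return numeric vector of length `n`
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, sd >= 0)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

## Derive a stream of per-trial seeds from one master seed, keeping everything
## inside the 32-bit integer range R requires.
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
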