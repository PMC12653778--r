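#' Truncated-normal sampler
#'
#' Draws from N(mean, sd^2) truncated to `(lower, upper)`. The same sampler
#' the Gibbs chain uses for liability augmentation: inverse-CDF in the
#' central region, exponential-rejection in far tails, guarded so that a
#' numerically empty interval still returns a finite value inside it.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds (may be infinite).
#' @return Numeric vector of draws, all inside `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, sd > 0)
  rtnorm_cpp(as.integer(n), mean, sd, lower, upper)
}
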