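#' Posterior summary of a draw vector
#'
#' Mean, median (midpoint rule on even counts, as `stats::median`) and
#' sample standard deviation.
#'
#' @param samples numeric vector with at least 2 draws.
#' @return Named numeric vector `c(mean, median, sd)`.
#' @export
summarize_draws <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 draws")
  c(mean = mean(samples), median = median(samples), sd = sd(samples))
}

#' Empirical highest-posterior-density interval
#'
#' Shortest contiguous window over the sorted draws containing
#' `ceiling(mass * n)` draws; ties between equally short windows are broken
#' towards the lowest window. Deterministic, no density estimate involved.
#'
#' @param samples numeric draw vector (>= 20 draws).
#' @param mass interval probability mass in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  n <- length(samples)
  if (n < 20L) stop("need at least 20 draws for an HPD interval")
  x <- sort(samples)
  k <- ceiling(mass * n - 1e-9)   # draws in the window; guard float fuzz
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(widths)          # which.min takes the first = lowest window
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Does an interval exclude zero?
#'
#' Boundary convention: an interval touching zero does not exclude it
#' (conservative screening).
#'
#' @param interval numeric `c(lower, upper)` with lower <= upper.
#' @return `TRUE` iff 0 < lower or 0 > upper.
#' @export
interval_excludes_zero <- function(interval) {
  stopifnot(length(interval) == 2L, interval[1L] <= interval[2L])
  unname(interval[1L] > 0 | interval[2L] < 0)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardized by their spectral variance estimates
#' (batch-mean approximation). |z| well above 2 flags non-convergence; this
#' is a reported diagnostic, not an enforced gate.
#'
#' @param samples numeric draw vector.
#' @param frac1,frac2 fractions of the chain used for the two windows.
#' @return z-score (numeric scalar).
#' @export
geweke_z <- function(samples, frac1 = 0.1, frac2 = 0.5) {
  n <- length(samples)
  a <- samples[seq_len(max(2L, floor(frac1 * n)))]
  b <- samples[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  bm_var <- function(x) {
    nb <- max(2L, floor(sqrt(length(x))))
    bs <- floor(length(x) / nb)
    means <- vapply(seq_len(nb), function(i) {
      mean(x[((i - 1L) * bs + 1L):(i * bs)])
    }, numeric(1))
    var(means) / nb
  }
  va <- bm_var(a); vb <- bm_var(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Summary table for a set of posterior draw vectors
#'
#' @param draws named list or data.frame/matrix of draw vectors (columns =
#'   parameters).
#' @param mass HPD mass (default 0.95).
#' @return Data frame `parameter, mean, median, sd, hpd_low, hpd_high`.
#' @export
posterior_summary <- function(draws, mass = 0.95) {
  if (is.matrix(draws) || is.data.frame(draws)) {
    draws <- as.list(as.data.frame(draws))
  }
  out <- do.call(rbind, lapply(names(draws), function(p) {
    x <- draws[[p]]
    s <- summarize_draws(x)
    h <- hpd_interval(x, mass)
    data.frame(parameter = p, mean = s[["mean"]], median = s[["median"]],
               sd = s[["sd"]], hpd_low = h[["lower"]], hpd_high = h[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read posterior summary CSVs
#'
#' Round-trip is value-identical: numbers are written with full precision.
#'
#' @param summary data frame from [posterior_summary()].
#' @param path file path.
#' @export
write_posterior_summary <- function(summary, path) {
  out <- summary
  num <- vapply(out, is.numeric, logical(1))
  # %.17g guarantees the printed decimal parses back to the same double
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @export
read_posterior_summary <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
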