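# ESS, Monte-Carlo error, HPD intervals and demographic-trajectory
# summaries -- the currency in which sampler efficiency is compared.

# autocovariances c_0..c_{n-1} via FFT, O(n log n)
.autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, npad - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / npad
  ac[seq_len(n)] / n
}

#' Effective sample size (Geyer initial monotone positive sequence)
#'
#' Estimates the number of independent draws an autocorrelated series is
#' worth: `n / IACT`, where the integrated autocorrelation time is built
#' from sums of adjacent autocovariance pairs `Gamma_m = c_{2m} + c_{2m+1}`,
#' truncated at the first non-positive pair and forced nonincreasing
#' (Geyer's initial monotone positive sequence estimator, valid for
#' reversible chains).
#'
#' @param series numeric vector, length >= 10.
#' @return ESS estimate (numeric scalar).
#' @examples
#' set.seed(1); ess(rnorm(1000))  # close to 1000
#' @export
ess <- function(series) {
  n <- length(series)
  if (n < 10L) stop("series must have length >= 10")
  if (sd(series) == 0 || !is.finite(sd(series)))
    stop("zero-variance series: degenerate chain")
  ac <- .autocov(series)
  nPairs <- floor(n / 2)
  m <- seq_len(nPairs)
  Gam <- ac[2 * m - 1] + ifelse(2 * m <= n, ac[2 * m], 0)
  pos <- which(Gam <= 0)
  K <- if (length(pos)) pos[1] - 1L else nPairs
  if (K < 1L) K <- 1L
  Gam <- cummin(Gam[seq_len(K)])  # enforce monotone nonincreasing
  varEst <- -ac[1] + 2 * sum(Gam)
  n * ac[1] / varEst
}

#' ESS per unit wall-clock time of a trace
#'
#' Per-parameter ESS of the log population sizes divided by the recorded
#' wall time, summarised by their minimum and median, with the precision
#' parameter reported separately -- the standard way sampler efficiency on
#' the skygrid is compared.
#'
#' @param trace a [Trace-class] with `wallTime` recorded.
#' @param discard fraction of initial retained states dropped as burn-in
#'   before estimating ESS (default 0).
#' @return list with `min`, `median`, `perParameter` (gamma components),
#'   `tau` (all ESS/second), and the raw `essGamma`, `essTau`, `wallTime`.
#' @export
essPerTime <- function(trace, discard = 0) {
  wt <- trace@wallTime
  if (!length(wt) || !is.finite(wt))
    stop("trace has no recorded wall time")
  g <- trace@gamma
  tv <- trace@tau
  if (discard > 0) {
    from <- floor(discard * nrow(g)) + 1L
    g <- g[from:nrow(g), , drop = FALSE]
    tv <- tv[from:length(tv)]
  }
  essG <- apply(g, 2, ess)
  essT <- ess(tv)
  list(min = min(essG) / wt, median = median(essG) / wt,
       perParameter = essG / wt, tau = essT / wt,
       essGamma = essG, essTau = essT, wallTime = wt)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(level * n)` of the
#' sorted sample points.
#'
#' @param series numeric vector (nonempty).
#' @param level coverage level in (0, 1).
#' @return numeric vector `c(low, high)`.
#' @export
hpdInterval <- function(series, level = 0.95) {
  n <- length(series)
  if (n == 0L) stop("empty series")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  s <- sort(series)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1L])
}

#' Posterior summary of the demographic trajectory
#'
#' One row per demographic interval with the posterior mean, median and HPD
#' bounds of the effective population size `theta_k = exp(gamma_k)` (HPD
#' computed on the theta scale), plus the gamma-scale median.
#'
#' @param trace a [Trace-class].
#' @param grid the [GridSpec-class] used in the analysis.
#' @param level HPD coverage level.
#' @param discard fraction of initial retained states dropped as burn-in.
#' @return data.frame with columns `interval`, `t_start`, `t_end`, `mean`,
#'   `median`, `hpd_low`, `hpd_high`, `log_median`.
#' @export
trajectorySummary <- function(trace, grid, level = 0.95, discard = 0) {
  g <- trace@gamma
  if (!nrow(g)) stop("empty trace")
  if (discard > 0)
    g <- g[(floor(discard * nrow(g)) + 1L):nrow(g), , drop = FALSE]
  x <- grid@gridPoints
  nInt <- grid@M + 1L
  starts <- c(0, x)
  ends <- c(x, Inf)
  rows <- lapply(seq_len(nInt), function(k) {
    th <- exp(g[, k])
    h <- if (nrow(g) > 1L) hpdInterval(th, level) else c(th[1], th[1])
    data.frame(interval = k, t_start = starts[k], t_end = ends[k],
               mean = mean(th), median = median(th),
               hpd_low = h[1], hpd_high = h[2],
               log_median = median(g[, k]))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo standard error of a series mean
#'
#' `sd(series) / sqrt(ess(series))` -- the ESS-based standard error used in
#' sampler-agreement checks.
#'
#' @param series numeric vector.
#' @return numeric scalar.
#' @export
mcse <- function(series) sd(series) / sqrt(ess(series))
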