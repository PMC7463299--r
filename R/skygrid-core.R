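# Skygrid coalescent likelihood, GMRF prior, posterior and gradient.
#
# The demographic function is piecewise constant on intervals
# [x_{k-1}, x_k), k = 1..M (x_0 = 0), and constant for t >= x_M. All
# likelihood terms drop gamma-independent constants (the binomial factors of
# the interval likelihood), which leaves the posterior unchanged.

# Interval index of a backwards time t under the half-open convention
# [x_{k-1}, x_k): a time exactly on a grid point belongs to the older
# interval. Vectorised.
.intervalIndex <- function(t, gridPts) {
  findInterval(t, gridPts, left.open = FALSE, rightmost.closed = FALSE) + 1L
}

#' Per-interval sufficient statistics from event sequences
#'
#' Splits every inter-event span of each locus at the grid points and
#' accumulates, per demographic interval, the coalescent-event count `c_k`
#' and the lineage-pair weighted waiting time
#' `S_k = sum v(v-1) dt / 2`, summed over loci. These two vectors fully
#' determine the coalescent likelihood.
#'
#' @param seqs an [EventSequence-class] or a list of them (one per locus).
#' @param grid a [GridSpec-class].
#' @return A [SuffStats-class] with vectors of length `M + 1`.
#' @export
sufficientStatistics <- function(seqs, grid) {
  if (is(seqs, "EventSequence")) seqs <- list(seqs)
  x <- grid@gridPoints
  nInt <- grid@M + 1L
  cTot <- numeric(nInt)
  sTot <- numeric(nInt)
  for (es in seqs) {
    t <- es@times
    lin <- cumsum(ifelse(es@kinds == "sampling", 1, -1))
    # coalescent counts: a coalescence exactly on x_k belongs to interval k+1
    ct <- t[es@kinds == "coalescent"]
    if (length(ct)) {
      idx <- .intervalIndex(ct, x)
      cTot <- cTot + tabulate(idx, nbins = nInt)
    }
    # waiting weights: merge event times with interior grid points
    inner <- x[x > t[1] & x < t[length(t)]]
    bp <- sort(c(t, inner))
    a <- bp[-length(bp)]
    b <- bp[-1L]
    # lineage count on [a, b): count after the last event at time <= a;
    # on exact sampling/coalescent ties at a the cumulative count applies
    vAt <- lin[findInterval(a, t)]
    w <- vAt * (vAt - 1) / 2 * (b - a)
    idx <- .intervalIndex(a, x)
    keep <- w > 0  # zero-length pieces contribute nothing
    if (any(keep)) {
      agg <- vapply(split(w[keep], idx[keep]), sum, numeric(1))
      sTot[as.integer(names(agg))] <- sTot[as.integer(names(agg))] + agg
    }
  }
  new("SuffStats", c = cTot, S = sTot)
}

#' Skygrid coalescent log likelihood from sufficient statistics
#'
#' \eqn{\log P(g | \gamma) = \sum_k [-\gamma_k c_k - S_k e^{-\gamma_k}]}
#' (up to a gamma-independent constant).
#'
#' @param stats a [SuffStats-class].
#' @param gamma numeric vector of log population sizes, length `M + 1`.
#' @return log likelihood (numeric scalar).
#' @export
coalescentLogLik <- function(stats, gamma) {
  if (length(gamma) != length(stats@c))
    stop("gamma length must equal the number of demographic intervals")
  sum(-gamma * stats@c - stats@S * exp(-gamma))
}

#' Direct per-interval coalescent log likelihood (oracle path)
#'
#' Evaluates the product of per-span exponential survival terms and
#' per-coalescence `1/theta` factors by walking the ordered grid, sampling
#' and coalescent times of one locus, without precomputing sufficient
#' statistics. Must agree with
#' `coalescentLogLik(sufficientStatistics(seq, grid), gamma)` to 1e-10.
#'
#' @param seq an [EventSequence-class].
#' @param grid a [GridSpec-class].
#' @param gamma numeric vector of log population sizes.
#' @return log likelihood (numeric scalar, same constant convention as
#'   [coalescentLogLik()]).
#' @export
intervalLogLikDirect <- function(seq, grid, gamma) {
  if (length(gamma) != grid@M + 1L)
    stop("gamma length must equal the number of demographic intervals")
  x <- grid@gridPoints
  theta <- exp(gamma)
  t <- seq@times
  kinds <- seq@kinds
  ll <- 0
  v <- 0
  for (j in seq_along(t)) {
    if (j > 1L) {
      # survival term over [t[j-1], t[j]] with v lineages, split at grid pts
      a <- t[j - 1L]
      endT <- t[j]
      while (a < endT) {
        k <- .intervalIndex(a, x)
        pieceEnd <- if (k <= length(x)) min(x[k], endT) else endT
        ll <- ll - v * (v - 1) * (pieceEnd - a) / (2 * theta[k])
        a <- pieceEnd
      }
    }
    if (kinds[j] == "sampling") v <- v + 1 else {
      k <- .intervalIndex(t[j], x)
      ll <- ll - gamma[k]  # the 1/theta_k factor per coalescence
      v <- v - 1
    }
  }
  ll
}

#' GMRF log prior on the log population sizes
#'
#' \eqn{(M/2)\log\tau - (\tau/2)\gamma'Q\gamma} (unnormalised), with
#' \eqn{\gamma'Q\gamma = \sum (\gamma_{i+1}-\gamma_i)^2}. Penalises rough
#' trajectories; uninformative about the overall level.
#'
#' @param gamma numeric vector of length `M + 1`.
#' @param tau positive GMRF precision.
#' @param spec a [GMRFSpec-class].
#' @return log prior density (numeric scalar, constant omitted).
#' @export
gmrfLogPrior <- function(gamma, tau, spec) {
  if (tau <= 0) stop("tau must be > 0")
  if (length(gamma) != spec@M + 1L)
    stop("gamma length must equal M + 1")
  (spec@M / 2) * log(tau) - (tau / 2) * qQuadform(gamma)
}

#' Gamma log hyperprior on the GMRF precision
#'
#' \eqn{(a-1)\log\tau - b\tau} (unnormalised).
#'
#' @inheritParams gmrfLogPrior
#' @return log prior density (numeric scalar).
#' @export
tauLogPrior <- function(tau, spec) {
  if (tau <= 0) stop("tau must be > 0")
  (spec@a - 1) * log(tau) - spec@b * tau
}

#' Unnormalised log posterior of the skygrid model
#'
#' Sum of the coalescent log likelihood, the GMRF log prior and the gamma
#' log hyperprior on the precision.
#'
#' @param state a [SkygridState-class] (or pass `gamma` and `tau`).
#' @param stats a [SuffStats-class].
#' @param spec a [GMRFSpec-class].
#' @param gamma,tau alternative to `state`.
#' @return log posterior (numeric scalar).
#' @export
logPosterior <- function(state = NULL, stats, spec,
                         gamma = state@gamma, tau = state@tau) {
  coalescentLogLik(stats, gamma) + gmrfLogPrior(gamma, tau, spec) +
    tauLogPrior(tau, spec)
}

#' Gradient of the log posterior in gamma
#'
#' Component k: \eqn{-c_k + S_k e^{-\gamma_k} - \tau (Q\gamma)_k}.
#'
#' @inheritParams logPosterior
#' @return numeric vector of length `M + 1`.
#' @export
gradGamma <- function(state = NULL, stats, spec,
                      gamma = state@gamma, tau = state@tau) {
  -stats@c + stats@S * exp(-gamma) - tau * qProd(gamma)
}

#' Full conditional of the GMRF precision
#'
#' By gamma-GMRF conjugacy,
#' \eqn{\tau | \gamma \sim \mathrm{Gamma}(a + M/2,\; b + \gamma'Q\gamma/2)}.
#'
#' @param gamma numeric vector of length `M + 1`.
#' @param spec a [GMRFSpec-class].
#' @return list with elements `shape` and `rate`.
#' @export
tauFullConditional <- function(gamma, spec) {
  list(shape = spec@a + spec@M / 2,
       rate = spec@b + qQuadform(gamma) / 2)
}
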