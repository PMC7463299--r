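# Constructors, accessors and show() methods for the core classes.

#' Construct a skygrid temporal grid
#'
#' With only `cutoff` and `M` given, grid points are evenly spaced:
#' `x_k = k * cutoff / M`, so `x_M == cutoff` exactly. A custom nondecreasing
#' vector of grid points ending at `cutoff` may be supplied instead.
#'
#' @param cutoff positive time (same units as the genealogy branch lengths);
#'   the last grid point.
#' @param M integer >= 1, number of grid points (yielding `M + 1`
#'   population-size parameters).
#' @param gridPoints optional custom grid point vector (length `M`).
#' @return A [GridSpec-class] object.
#' @examples
#' buildGrid(40, 4)   # grid points 10, 20, 30, 40
#' @export
buildGrid <- function(cutoff, M, gridPoints = NULL) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be a single positive number")
  if (length(M) != 1L || !is.finite(M) || M < 1)
    stop("M must be a single integer >= 1")
  M <- as.integer(M)
  if (is.null(gridPoints)) {
    gridPoints <- seq_len(M) * (cutoff / M)
    gridPoints[M] <- cutoff  # guard against cumulative rounding
  }
  new("GridSpec", M = M, cutoff = as.numeric(cutoff),
      gridPoints = as.numeric(gridPoints))
}

#' @describeIn buildGrid grid point vector `x_1, ..., x_M`.
#' @param x a `GridSpec`.
#' @export
gridPoints <- function(x) x@gridPoints

#' @describeIn buildGrid the cutoff `x_M`.
#' @export
gridCutoff <- function(x) x@cutoff

#' @describeIn buildGrid number of demographic intervals, `M + 1`.
#' @export
nIntervals <- function(x) x@M + 1L

#' GMRF prior specification
#'
#' @param a,b shape and rate of the gamma hyperprior on the precision
#'   `tau`. The defaults 0.001/0.001 are relatively uninformative.
#' @param M number of grid points (the structure matrix Q is
#'   `(M+1) x (M+1)`).
#' @return A [GMRFSpec-class] object.
#' @export
gmrfSpec <- function(M, a = 0.001, b = 0.001)
  new("GMRFSpec", a = as.numeric(a), b = as.numeric(b), M = as.integer(M))

#' Dense GMRF structure matrix Q
#'
#' Tridiagonal with diagonal (1, 2, ..., 2, 1) and off-diagonals -1;
#' satisfies \eqn{\gamma' Q \gamma = \sum (\gamma_{i+1} - \gamma_i)^2}.
#'
#' @param spec a [GMRFSpec-class].
#' @return a `(M+1) x (M+1)` matrix.
#' @export
gmrfQ <- function(spec) {
  d <- spec@M + 1L
  Q <- diag(c(1, rep(2, d - 2L), 1))
  Q[cbind(seq_len(d - 1L), seq_len(d - 1L) + 1L)] <- -1
  Q[cbind(seq_len(d - 1L) + 1L, seq_len(d - 1L))] <- -1
  Q
}

#' Skygrid sampler state
#'
#' @param gamma numeric vector of log effective population sizes
#'   (length `M + 1`).
#' @param tau positive GMRF precision.
#' @return A [SkygridState-class].
#' @export
skygridState <- function(gamma, tau)
  new("SkygridState", gamma = as.numeric(gamma), tau = as.numeric(tau))

#' @describeIn skygridState log population sizes of a state.
#' @param x a `SkygridState`.
#' @export
logPopSizes <- function(x) x@gamma

#' @describeIn skygridState GMRF precision of a state.
#' @export
precisionParam <- function(x) x@tau

#' Block-updating MCMC settings
#'
#' @param F tuning constant (> 1) of the multiplicative precision proposal;
#'   proposed scale factors live in `[1/F, F]`.
#' @param nrTol max-norm gradient tolerance for the Newton-Raphson mode
#'   search.
#' @param nrMaxiter Newton-Raphson iteration cap; non-convergence makes the
#'   kernel reject the proposal rather than abort.
#' @return A [BUMCMCSettings-class].
#' @export
bumcmcSettings <- function(F = 2.0, nrTol = 1e-6, nrMaxiter = 50L)
  new("BUMCMCSettings", F = as.numeric(F), nrTol = as.numeric(nrTol),
      nrMaxiter = as.integer(nrMaxiter))

#' Hamiltonian Monte Carlo settings
#'
#' @param epsilon leapfrog step size; `NULL` selects `0.1 / sqrt(d)` at run
#'   time (d = dimension of the position vector).
#' @param nLeapfrog leapfrog steps per proposal.
#' @param massDiagonal diagonal of the mass matrix; default identity.
#' @param targetAccept dual-averaging target acceptance probability.
#' @param warmupFraction fraction of iterations with step-size adaptation.
#' @param tauUpdate `"gibbs"` (HMC on gamma only, conjugate tau draw) or
#'   `"joint"` (HMC on `(gamma, log tau)` with the log-transform Jacobian).
#' @return An [HMCSettings-class].
#' @export
hmcSettings <- function(epsilon = NULL, nLeapfrog = 20L,
                        massDiagonal = numeric(0), targetAccept = 0.8,
                        warmupFraction = 0.1, tauUpdate = "gibbs")
  new("HMCSettings",
      epsilon = if (is.null(epsilon)) numeric(0) else as.numeric(epsilon),
      nLeapfrog = as.integer(nLeapfrog),
      massDiagonal = as.numeric(massDiagonal),
      targetAccept = as.numeric(targetAccept),
      warmupFraction = as.numeric(warmupFraction),
      tauUpdate = tauUpdate)

#' Trace accessors
#'
#' @param x a [Trace-class].
#' @return `gammaSamples`: matrix of retained log population sizes;
#'   `tauSamples`: retained precision values; `logPosteriors`: log posterior
#'   per retained state; `acceptanceRate`, `wallTime`, `thinStride`:
#'   scalars.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
gammaSamples <- function(x) x@gamma

#' @rdname trace-accessors
#' @export
tauSamples <- function(x) x@tau

#' @rdname trace-accessors
#' @export
logPosteriors <- function(x) x@logPosteriors

#' @rdname trace-accessors
#' @export
acceptanceRate <- function(x) x@acceptanceRate

#' @rdname trace-accessors
#' @export
wallTime <- function(x) x@wallTime

#' @rdname trace-accessors
#' @export
thinStride <- function(x) x@iterationStride

setMethod("show", "GridSpec", function(object) {
  cat("Skygrid grid:", object@M, "grid points, cutoff", object@cutoff,
      "->", object@M + 1L, "demographic intervals\n")
})

setMethod("show", "EventSequence", function(object) {
  cat("EventSequence:", object@nTips, "tips,",
      sum(object@kinds == "coalescent"), "coalescences, offset",
      object@offset, ", span [", min(object@times), ",",
      max(object@times), "]\n")
})

setMethod("show", "SuffStats", function(object) {
  cat("Skygrid sufficient statistics over", length(object@c),
      "intervals:\n  c:", paste(signif(object@c, 4), collapse = " "),
      "\n  S:", paste(signif(object@S, 4), collapse = " "), "\n")
})

setMethod("show", "SkygridState", function(object) {
  cat("SkygridState: gamma =", paste(signif(object@gamma, 4), collapse = " "),
      "; tau =", signif(object@tau, 4), "\n")
})

setMethod("show", "Trace", function(object) {
  cat("Trace (", object@sampler, "): ", nrow(object@gamma),
      " retained states x ", ncol(object@gamma),
      " log population sizes + precision; acceptance ",
      round(object@acceptanceRate, 3), "; thin ", object@iterationStride,
      if (is.finite(object@wallTime))
        paste0("; ", round(object@wallTime, 2), " s") else "", "\n", sep = "")
})

setMethod("show", "DatedGenealogy", function(object) {
  ntip <- length(object@tree$tip.label)
  if (length(object@tipDates) && !anyNA(object@tipDates))
    cat("DatedGenealogy:", ntip, "tips, dates in [",
        min(object@tipDates), ",", max(object@tipDates), "]\n")
  else cat("DatedGenealogy:", ntip, "tips (undated)\n")
})

#' Coalescent counts / waiting weights of a SuffStats object
#' @param x a [SuffStats-class].
#' @export
coalCounts <- function(x) x@c

#' @rdname coalCounts
#' @export
waitSums <- function(x) x@S
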