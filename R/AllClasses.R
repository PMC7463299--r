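#' @import methods
#' @importFrom stats rexp rgamma rnorm runif median sd fft
#' @importFrom utils write.table write.csv read.delim packageVersion
NULL

setOldClass("phylo")

#' Temporal grid for the skygrid demographic function
#'
#' A grid of `M` time points `x_1 <= ... <= x_M` (backwards time, 0 = most
#' recent sample) partitioning the past into `M + 1` intervals on which the
#' effective population size is constant. `x_M` is the cutoff: the time
#' furthest into the past at which the population size may change; beyond it
#' a single value applies. Note that `M` grid points always yield `M + 1`
#' population-size parameters.
#'
#' @slot M integer, number of grid points (>= 1).
#' @slot cutoff numeric, the last grid point `x_M` (> 0).
#' @slot gridPoints numeric vector of length `M`, nondecreasing, ending at
#'   `cutoff`.
#' @export
setClass("GridSpec",
  representation(M = "integer", cutoff = "numeric", gridPoints = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@M) != 1L || object@M < 1L)
      msg <- c(msg, "M must be a single integer >= 1")
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
        object@cutoff <= 0)
      msg <- c(msg, "cutoff must be a single positive number")
    x <- object@gridPoints
    if (length(x) != object@M)
      msg <- c(msg, "gridPoints must have length M")
    else {
      if (x[1] <= 0) msg <- c(msg, "first grid point must be > 0")
      if (is.unsorted(x)) msg <- c(msg, "grid points must be nondecreasing")
      if (abs(x[length(x)] - object@cutoff) > 1e-12 * max(1, object@cutoff))
        msg <- c(msg, "last grid point must equal the cutoff")
    }
    if (length(msg)) msg else TRUE
  })

#' Ordered sampling/coalescent events of one genealogy on the shared
#' backwards timeline
#'
#' Times are measured backwards from a global reference (usually the most
#' recent tip over all loci). The first event is always a sampling event at
#' `offset`, the gap between the global reference and this locus's most
#' recent tip. Sampling events add a lineage, coalescent events remove one;
#' the running lineage count stays >= 1 and ends at 1.
#'
#' @slot times numeric, nondecreasing backwards times (>= 0).
#' @slot kinds character, "sampling" or "coalescent" per event.
#' @slot offset numeric, backwards time of this locus's most recent tip.
#' @slot nTips integer, number of sampled tips.
#' @export
setClass("EventSequence",
  representation(times = "numeric", kinds = "character", offset = "numeric",
                 nTips = "integer"),
  validity = function(object) {
    msg <- character()
    t <- object@times; k <- object@kinds
    if (length(t) != length(k)) msg <- c(msg, "times/kinds length mismatch")
    if (!all(k %in% c("sampling", "coalescent")))
      msg <- c(msg, "kinds must be 'sampling' or 'coalescent'")
    if (length(t) && is.unsorted(t)) msg <- c(msg, "times must be nondecreasing")
    if (length(t)) {
      if (k[1] != "sampling" || abs(t[1] - object@offset) > 1e-9)
        msg <- c(msg, "first event must be a sampling event at the offset")
      lin <- cumsum(ifelse(k == "sampling", 1L, -1L))
      if (any(lin < 1L)) msg <- c(msg, "lineage count drops below 1")
      if (lin[length(lin)] != 1L) msg <- c(msg, "final lineage count must be 1")
      if (sum(k == "coalescent") != object@nTips - 1L)
        msg <- c(msg, "need n_tips - 1 coalescent events")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-interval sufficient statistics of the skygrid coalescent likelihood
#'
#' `c[k]` counts coalescent events in demographic interval `k` and `S[k]`
#' accumulates the lineage-pair weighted waiting time
#' \eqn{\sum v(v-1)\Delta t / 2} spent in that interval, summed over loci.
#' Together they fully determine the coalescent likelihood.
#'
#' @slot c numeric (nonnegative integers), length `M + 1`.
#' @slot S numeric (nonnegative), length `M + 1`.
#' @export
setClass("SuffStats",
  representation(c = "numeric", S = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@c) != length(object@S))
      msg <- c(msg, "c and S must have equal length")
    if (any(object@c < 0) || any(object@S < 0))
      msg <- c(msg, "c and S must be nonnegative")
    if (any(abs(object@c - round(object@c)) > 1e-9))
      msg <- c(msg, "c must be integer-valued")
    # note: S_k == 0 with c_k > 0 is possible only in the measure-zero case
    # of a coalescence landing exactly on a grid point (the event belongs to
    # the older interval while its waiting time lies in the younger one), so
    # it is deliberately not rejected here
    if (length(msg)) msg else TRUE
  })

#' GMRF smoothing prior specification
#'
#' Intrinsic first-difference Gaussian Markov random field prior on the log
#' population sizes with precision `tau`, plus a Gamma(a, b) hyperprior on
#' `tau`. The structure matrix Q is tridiagonal with diagonal
#' (1, 2, ..., 2, 1) and off-diagonals -1, so that
#' \eqn{\gamma' Q \gamma = \sum_i (\gamma_{i+1} - \gamma_i)^2}.
#'
#' @slot a numeric, gamma prior shape (> 0). Default 0.001.
#' @slot b numeric, gamma prior rate (> 0). Default 0.001.
#' @slot M integer, number of grid points; Q is (M+1) x (M+1).
#' @export
setClass("GMRFSpec",
  representation(a = "numeric", b = "numeric", M = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@a <= 0 || object@b <= 0) msg <- c(msg, "a and b must be > 0")
    if (object@M < 1L) msg <- c(msg, "M must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Current state of the skygrid sampler
#'
#' @slot gamma numeric vector of length `M + 1`, log effective population
#'   sizes per demographic interval.
#' @slot tau numeric, GMRF precision (> 0).
#' @export
setClass("SkygridState",
  representation(gamma = "numeric", tau = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@gamma))) msg <- c(msg, "gamma must be finite")
    if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0)
      msg <- c(msg, "tau must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Mode-centred Gaussian approximation to the full conditional of gamma
#'
#' Tridiagonal-precision Gaussian with precision
#' \eqn{\tau Q + \mathrm{Diag}(S_k e^{-\hat\gamma_k})}, stored as its
#' diagonal and (constant) off-diagonal together with a Cholesky factor so
#' that sampling and density evaluation are O(M).
#'
#' @slot precDiag numeric, precision diagonal.
#' @slot precOff numeric, precision off-diagonal (length d - 1).
#' @slot cholDiag numeric, lower-bidiagonal Cholesky diagonal.
#' @slot cholOff numeric, Cholesky sub-diagonal.
#' @slot mean numeric, mean vector.
#' @slot logNorm numeric, log normalising constant of the density.
#' @slot center numeric, the expansion point \eqn{\hat\gamma} used.
#' @export
setClass("GaussianApprox",
  representation(precDiag = "numeric", precOff = "numeric",
                 cholDiag = "numeric", cholOff = "numeric",
                 mean = "numeric", logNorm = "numeric", center = "numeric"),
  validity = function(object) {
    d <- length(object@precDiag)
    if (length(object@mean) != d || length(object@center) != d)
      return("mean/center length mismatch")
    if (length(object@precOff) != d - 1L || length(object@cholOff) != d - 1L)
      return("off-diagonal length mismatch")
    if (any(object@cholDiag <= 0)) return("precision not positive definite")
    TRUE
  })

#' Settings of the block-updating MCMC kernel
#'
#' @slot F numeric > 1, tuning constant of the multiplicative precision
#'   proposal (support [1/F, F]).
#' @slot nrTol numeric > 0, max-norm gradient tolerance of the
#'   Newton-Raphson mode search.
#' @slot nrMaxiter integer >= 1, Newton-Raphson iteration cap.
#' @export
setClass("BUMCMCSettings",
  representation(F = "numeric", nrTol = "numeric", nrMaxiter = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@F <= 1) msg <- c(msg, "F must be > 1")
    if (object@nrTol <= 0) msg <- c(msg, "nrTol must be > 0")
    if (object@nrMaxiter < 1L) msg <- c(msg, "nrMaxiter must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Settings of the Hamiltonian Monte Carlo kernel
#'
#' @slot epsilon numeric > 0, leapfrog step size (initial value when
#'   adaptation is on).
#' @slot nLeapfrog integer >= 1, leapfrog steps per proposal.
#' @slot massDiagonal numeric, diagonal of the mass matrix; `numeric(0)`
#'   means identity.
#' @slot targetAccept numeric in (0, 1), dual-averaging target acceptance.
#' @slot warmupFraction numeric in [0, 1), fraction of iterations during
#'   which the step size adapts; frozen thereafter.
#' @slot tauUpdate character, "gibbs" (HMC on gamma, conjugate tau draw) or
#'   "joint" (HMC on (gamma, log tau)).
#' @export
setClass("HMCSettings",
  representation(epsilon = "numeric", nLeapfrog = "integer",
                 massDiagonal = "numeric", targetAccept = "numeric",
                 warmupFraction = "numeric", tauUpdate = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@epsilon) && object@epsilon <= 0)
      msg <- c(msg, "epsilon must be > 0")
    if (object@nLeapfrog < 1L) msg <- c(msg, "nLeapfrog must be >= 1")
    if (length(object@massDiagonal) && any(object@massDiagonal <= 0))
      msg <- c(msg, "massDiagonal must be strictly positive")
    if (object@targetAccept <= 0 || object@targetAccept >= 1)
      msg <- c(msg, "targetAccept must lie in (0, 1)")
    if (object@warmupFraction < 0 || object@warmupFraction >= 1)
      msg <- c(msg, "warmupFraction must lie in [0, 1)")
    if (!object@tauUpdate %in% c("gibbs", "joint"))
      msg <- c(msg, "tauUpdate must be 'gibbs' or 'joint'")
    if (length(msg)) msg else TRUE
  })

#' Thinned posterior sample of a skygrid sampler run
#'
#' Row 1 holds the initial state; subsequent rows are the states retained
#' every `iterationStride` iterations.
#'
#' @slot gamma numeric matrix, one row per retained state, one column per
#'   log population size.
#' @slot tau numeric vector of retained precision values.
#' @slot logPosteriors numeric vector of unnormalised log posterior values.
#' @slot acceptanceRate numeric in [0, 1].
#' @slot iterationStride integer, thinning interval.
#' @slot wallTime numeric, elapsed seconds (NA if not recorded).
#' @slot sampler character, kernel label.
#' @export
setClass("Trace",
  representation(gamma = "matrix", tau = "numeric", logPosteriors = "numeric",
                 acceptanceRate = "numeric", iterationStride = "integer",
                 wallTime = "numeric", sampler = "character"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@gamma)
    if (length(object@tau) != n || length(object@logPosteriors) != n)
      msg <- c(msg, "gamma, tau and logPosteriors must have matching lengths")
    if (object@acceptanceRate < 0 || object@acceptanceRate > 1)
      msg <- c(msg, "acceptanceRate must lie in [0, 1]")
    if (object@iterationStride < 1L) msg <- c(msg, "iterationStride must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' A rooted, dated genealogy
#'
#' Wraps an `ape::phylo` tree with per-tip calendar dates. Node times implied
#' by tip dates and branch lengths must be consistent across all root-to-tip
#' paths (tolerance 1e-6 time units); `nodeCalendarTimes` caches the implied
#' calendar time of every node. An undated genealogy (straight from Newick)
#' has `tipDates` full of NA.
#'
#' @slot tree a `phylo` object (rooted, binary, with branch lengths).
#' @slot tipDates named numeric, calendar date per tip (NA when undated).
#' @slot mostRecentTipDate numeric, max of tipDates (NA when undated).
#' @slot nodeCalendarTimes numeric, calendar time per node (tips then
#'   internals, ape numbering); length 0 when undated.
#' @export
setClass("DatedGenealogy",
  representation(tree = "phylo", tipDates = "numeric",
                 mostRecentTipDate = "numeric",
                 nodeCalendarTimes = "numeric"),
  validity = function(object) {
    tr <- object@tree
    msg <- character()
    ntip <- length(tr$tip.label)
    if (ntip < 2L) msg <- c(msg, "genealogy needs at least 2 tips")
    if (is.null(tr$edge.length)) msg <- c(msg, "branch lengths are required")
    if (length(object@tipDates) && length(object@tipDates) != ntip)
      msg <- c(msg, "tipDates must cover every tip")
    if (length(msg)) msg else TRUE
  })
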