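# Block-updating MCMC kernel: multiplicative precision proposal, mode
# finding by Newton-Raphson, mode-centred Gaussian approximation to the
# full conditional of gamma, and the Metropolis-Hastings correction.

#' Draw the multiplicative scale factor of the precision proposal
#'
#' Samples from the density proportional to `f + 1/f` on `[1/F, F]` by
#' composition: a mixture of the component proportional to `f` (mass
#' `(F^2 - F^-2)/2`, sampled by inverse CDF) and the component proportional
#' to `1/f` (mass `2 log F`, log-uniform).
#'
#' Note the density is not symmetric under `f -> 1/f` on the multiplicative
#' scale, so the precision proposal `tau* = tau f` carries a non-unit
#' Hastings factor `1/f`; [bumcmcStep()] applies the `-log f` correction.
#'
#' @param F tuning constant > 1.
#' @param n number of draws.
#' @return numeric vector of draws in `[1/F, F]`.
#' @export
sampleScaleFactor <- function(F, n = 1L) {
  if (F <= 1) stop("F must be > 1")
  massLin <- (F^2 - F^-2) / 2
  massInv <- 2 * log(F)
  pickLin <- runif(n) < massLin / (massLin + massInv)
  u <- runif(n)
  f <- numeric(n)
  f[pickLin] <- sqrt(F^-2 + u[pickLin] * (F^2 - F^-2))
  f[!pickLin] <- exp((2 * u[!pickLin] - 1) * log(F))
  f
}

# log density of the scale proposal at f (normalised), for reference/tests
scaleFactorLogDensity <- function(f, F) {
  z <- (F^2 - F^-2) / 2 + 2 * log(F)
  ifelse(f >= 1 / F & f <= F, log(f + 1 / f) - log(z), -Inf)
}

#' Newton-Raphson mode of the full conditional of gamma
#'
#' Maximises \eqn{f(\gamma) = -\tau\gamma'Q\gamma/2 -
#' \sum_k(\gamma_k c_k + S_k e^{-\gamma_k})}, the log full conditional of
#' gamma given the data and `tau` (up to a constant). The objective is
#' strictly concave whenever some `S_k > 0`, so the maximiser is unique.
#' Each Newton step solves a tridiagonal system; step halving guards
#' against overshoot far from the mode.
#'
#' @param gammaInit starting vector (conventionally the chain's current
#'   gamma).
#' @param tau positive GMRF precision.
#' @param stats a [SuffStats-class].
#' @param spec a [GMRFSpec-class].
#' @param settings a [BUMCMCSettings-class] (tolerance and iteration cap).
#' @return The mode, a numeric vector with max-norm gradient below
#'   `settings@nrTol`.
#' @section Errors: signals a condition of class `nrNonConvergence` when the
#'   iteration cap is reached or the objective degenerates; [bumcmcStep()]
#'   converts this into a rejected proposal.
#' @export
newtonRaphsonMode <- function(gammaInit, tau, stats, spec,
                              settings = bumcmcSettings()) {
  if (all(stats@S <= 0))
    stop(errorCondition("singular Hessian: no interval has positive waiting weight",
                        class = c("nrNonConvergence", "error", "condition")))
  g <- gammaInit
  obj <- function(gm) -(tau / 2) * qQuadform(gm) -
    sum(gm * stats@c + stats@S * exp(-gm))
  fcur <- obj(g)
  for (iter in seq_len(settings@nrMaxiter)) {
    expng <- stats@S * exp(-g)
    grad <- -tau * qProd(g) - stats@c + expng
    if (max(abs(grad)) < settings@nrTol) return(g)
    dg <- tau * c(1, rep(2, length(g) - 2L), 1) + expng
    off <- rep(-tau, length(g) - 1L)
    ch <- tryCatch(tridiagChol(dg, off), error = function(e)
      stop(errorCondition(conditionMessage(e),
                          class = c("nrNonConvergence", "error", "condition"))))
    step <- tridiagSolve(ch, grad)
    # step halving: the Newton direction is an ascent direction
    for (h in 0:30) {
      gNew <- g + step / 2^h
      fNew <- obj(gNew)
      if (is.finite(fNew) && fNew >= fcur - 1e-12) break
    }
    g <- gNew
    fcur <- fNew
  }
  expng <- stats@S * exp(-g)
  grad <- -tau * qProd(g) - stats@c + expng
  if (max(abs(grad)) < settings@nrTol) return(g)
  stop(errorCondition(
    sprintf("Newton-Raphson did not converge in %d iterations (|grad|_inf = %g)",
            settings@nrMaxiter, max(abs(grad))),
    class = c("nrNonConvergence", "error", "condition")))
}

#' Second-order Gaussian approximation to the full conditional of gamma
#'
#' Taylor-expands each likelihood term about `gammaHat`, giving a Gaussian
#' with tridiagonal precision \eqn{\tau Q + \mathrm{Diag}(S_k
#' e^{-\hat\gamma_k})} and linear term \eqn{b_k = -c_k + S_k
#' e^{-\hat\gamma_k}(1 + \hat\gamma_k)}; the mean solves `P mean = b`.
#' When `gammaHat` is the Newton-Raphson mode the mean equals `gammaHat`.
#'
#' @param gammaHat expansion point (usually the NR mode).
#' @inheritParams newtonRaphsonMode
#' @return A [GaussianApprox-class].
#' @export
gaussianApprox <- function(gammaHat, tau, stats, spec) {
  d <- length(gammaHat)
  expng <- stats@S * exp(-gammaHat)
  dg <- tau * c(1, rep(2, d - 2L), 1) + expng
  off <- rep(-tau, d - 1L)
  ch <- tridiagChol(dg, off)
  b <- -stats@c + expng * (1 + gammaHat)
  mu <- tridiagSolve(ch, b)
  logNorm <- 0.5 * tridiagLogDet(ch) - (d / 2) * log(2 * pi)
  new("GaussianApprox", precDiag = dg, precOff = off,
      cholDiag = ch$l, cholOff = ch$m, mean = mu, logNorm = logNorm,
      center = gammaHat)
}

#' Log density of a Gaussian approximation at a point
#'
#' @param approx a [GaussianApprox-class].
#' @param gamma evaluation point.
#' @return normalised log density (numeric scalar).
#' @export
approxLogDensity <- function(approx, gamma) {
  dev <- gamma - approx@mean
  approx@logNorm -
    0.5 * tridiagQuadform(approx@precDiag, approx@precOff, dev)
}

#' Sample from a Gaussian approximation
#'
#' @param approx a [GaussianApprox-class].
#' @return numeric vector draw.
#' @export
approxSample <- function(approx) {
  z <- rnorm(length(approx@mean))
  approx@mean + tridiagBacksolve(list(l = approx@cholDiag, m = approx@cholOff), z)
}

# Build the mode-centred approximation at a given tau (NR started at gamma0).
# Returns NULL on NR non-convergence.
.approxAtTau <- function(gamma0, tau, stats, spec, settings) {
  gh <- tryCatch(newtonRaphsonMode(gamma0, tau, stats, spec, settings),
                 nrNonConvergence = function(e) NULL)
  if (is.null(gh)) return(NULL)
  gaussianApprox(gh, tau, stats, spec)
}

#' One block-updating MCMC transition
#'
#' Proposes `tau* = tau f` with `f` from the scale proposal, builds the
#' mode-centred Gaussian approximation to `P(gamma | g, tau*)` (Newton-
#' Raphson started at the current gamma), samples `gamma*` from it, and
#' accepts with the Metropolis-Hastings probability. The log ratio combines
#' the posterior difference, the forward/reverse approximation densities
#' (the reverse uses the mode-centred approximation at the current `tau`,
#' which depends on `tau` only) and the `-log f` Hastings correction of the
#' multiplicative precision proposal. Newton-Raphson non-convergence
#' rejects the proposal.
#'
#' @param state current [SkygridState-class].
#' @param stats a [SuffStats-class].
#' @param spec a [GMRFSpec-class].
#' @param settings a [BUMCMCSettings-class].
#' @param approxCur optional cached [GaussianApprox-class] at the current
#'   `tau` (recomputed when `NULL`); callers running chains should pass the
#'   approximation returned by the previous step.
#' @return list with elements `state`, `accepted` (logical), `approx`
#'   (approximation at the returned state's tau, for caching), `logPost`
#'   (log posterior of the returned state) and `nonConverged` (logical).
#' @export
bumcmcStep <- function(state, stats, spec, settings = bumcmcSettings(),
                       approxCur = NULL) {
  f <- sampleScaleFactor(settings@F)
  tauStar <- state@tau * f
  approxStar <- .approxAtTau(state@gamma, tauStar, stats, spec, settings)
  if (is.null(approxCur))
    approxCur <- .approxAtTau(state@gamma, state@tau, stats, spec, settings)
  if (is.null(approxStar) || is.null(approxCur))
    return(list(state = state, accepted = FALSE, approx = approxCur,
                logPost = logPosterior(state, stats, spec),
                nonConverged = TRUE))
  gammaStar <- approxSample(approxStar)
  logRatio <- logPosterior(stats = stats, spec = spec,
                           gamma = gammaStar, tau = tauStar) -
    logPosterior(state, stats, spec) +
    approxLogDensity(approxCur, state@gamma) -
    approxLogDensity(approxStar, gammaStar) -
    log(f)  # Hastings factor of the multiplicative tau proposal
  if (is.finite(logRatio) && log(runif(1)) < logRatio) {
    newState <- skygridState(gammaStar, tauStar)
    list(state = newState, accepted = TRUE, approx = approxStar,
         logPost = logPosterior(newState, stats, spec), nonConverged = FALSE)
  } else {
    list(state = state, accepted = FALSE, approx = approxCur,
         logPost = logPosterior(state, stats, spec), nonConverged = FALSE)
  }
}

#' Run a block-updating MCMC chain
#'
#' @param init initial [SkygridState-class].
#' @param stats a [SuffStats-class].
#' @param spec a [GMRFSpec-class].
#' @param settings a [BUMCMCSettings-class].
#' @param iterations number of transitions (>= 0).
#' @param thin keep every `thin`-th state (the initial state is always row 1
#'   of the trace).
#' @param seed optional integer seed (`set.seed`) for reproducible chains.
#' @return A [Trace-class].
#' @export
runBUMCMC <- function(init, stats, spec, settings = bumcmcSettings(),
                      iterations = 1000L, thin = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  nKeep <- if (iterations >= thin) iterations %/% thin else 0L
  d <- length(init@gamma)
  gm <- matrix(NA_real_, nKeep + 1L, d)
  tv <- numeric(nKeep + 1L)
  lp <- numeric(nKeep + 1L)
  gm[1L, ] <- init@gamma; tv[1L] <- init@tau
  lp[1L] <- logPosterior(init, stats, spec)
  state <- init
  approx <- NULL
  nAcc <- 0L; nNon <- 0L
  row <- 1L
  if (iterations > 0) for (it in seq_len(iterations)) {
    res <- bumcmcStep(state, stats, spec, settings, approxCur = approx)
    state <- res$state
    approx <- res$approx
    nAcc <- nAcc + res$accepted
    nNon <- nNon + res$nonConverged
    if (it %% thin == 0L) {
      row <- row + 1L
      gm[row, ] <- state@gamma; tv[row] <- state@tau; lp[row] <- res$logPost
    }
  }
  tr <- new("Trace", gamma = gm, tau = tv, logPosteriors = lp,
            acceptanceRate = if (iterations > 0) nAcc / iterations else 0,
            iterationStride = as.integer(thin),
            wallTime = proc.time()[["elapsed"]] - t0, sampler = "bumcmc")
  attr(tr, "nonConvergenceCount") <- nNon
  tr
}
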