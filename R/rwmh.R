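# Reference univariate random-walk Metropolis-Hastings sampler. Deliberately
# simple and independent of the block-updating and HMC code paths: it serves
# as the arbiter in sampler-agreement tests.

#' Run a univariate random-walk Metropolis-Hastings chain
#'
#' Each iteration sweeps the log population sizes one component at a time
#' with Gaussian random-walk proposals (using the local likelihood and GMRF
#' terms only), then updates `tau` by a random walk on `log tau` with the
#' change-of-variables Jacobian. No Gaussian approximation, gradient or
#' conjugacy is used anywhere, which makes the chain a slow but transparent
#' reference for the other kernels.
#'
#' @inheritParams runBUMCMC
#' @param stepGamma random-walk standard deviation for each gamma component.
#' @param stepLogTau random-walk standard deviation on the log-precision.
#' @return A [Trace-class]; acceptance rate is averaged over all component
#'   updates.
#' @export
runRWMH <- function(init, stats, spec, iterations = 1000L, thin = 1L,
                    stepGamma = 0.5, stepLogTau = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  d <- length(init@gamma)
  cc <- stats@c; SS <- stats@S
  nKeep <- if (iterations >= thin) iterations %/% thin else 0L
  gm <- matrix(NA_real_, nKeep + 1L, d)
  tv <- numeric(nKeep + 1L)
  lp <- numeric(nKeep + 1L)
  gamma <- init@gamma; tau <- init@tau
  gm[1L, ] <- gamma; tv[1L] <- tau
  lp[1L] <- logPosterior(stats = stats, spec = spec, gamma = gamma, tau = tau)
  nAcc <- 0L; nProp <- 0L
  row <- 1L
  # local change in the GMRF quadratic form when component k moves
  localQuad <- function(gamma, k, val) {
    q <- 0
    if (k > 1L) q <- q + (val - gamma[k - 1L])^2
    if (k < d) q <- q + (gamma[k + 1L] - val)^2
    q
  }
  if (iterations > 0) for (it in seq_len(iterations)) {
    for (k in seq_len(d)) {
      prop <- gamma[k] + rnorm(1, sd = stepGamma)
      dLik <- -(prop - gamma[k]) * cc[k] -
        SS[k] * (exp(-prop) - exp(-gamma[k]))
      dPrior <- -(tau / 2) *
        (localQuad(gamma, k, prop) - localQuad(gamma, k, gamma[k]))
      nProp <- nProp + 1L
      if (log(runif(1)) < dLik + dPrior) {
        gamma[k] <- prop
        nAcc <- nAcc + 1L
      }
    }
    ltProp <- log(tau) + rnorm(1, sd = stepLogTau)
    tauProp <- exp(ltProp)
    dPost <- gmrfLogPrior(gamma, tauProp, spec) - gmrfLogPrior(gamma, tau, spec) +
      tauLogPrior(tauProp, spec) - tauLogPrior(tau, spec) +
      ltProp - log(tau)  # Jacobian of the log-scale proposal
    nProp <- nProp + 1L
    if (is.finite(dPost) && log(runif(1)) < dPost) {
      tau <- tauProp
      nAcc <- nAcc + 1L
    }
    if (it %% thin == 0L) {
      row <- row + 1L
      gm[row, ] <- gamma; tv[row] <- tau
      lp[row] <- logPosterior(stats = stats, spec = spec,
                              gamma = gamma, tau = tau)
    }
  }
  new("Trace", gamma = gm, tau = tv, logPosteriors = lp,
      acceptanceRate = if (nProp > 0) nAcc / nProp else 0,
      iterationStride = as.integer(thin),
      wallTime = proc.time()[["elapsed"]] - t0, sampler = "rwmh")
}
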