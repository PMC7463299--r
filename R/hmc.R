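# Hamiltonian Monte Carlo kernel: leapfrog integrator, accept/reject on the
# Hamiltonian, dual-averaging step-size adaptation, and a conjugate Gibbs
# update for the GMRF precision.

#' Leapfrog integration of Hamiltonian dynamics
#'
#' Performs `n` leapfrog steps of size `epsilon`: half-step momentum,
#' full-step position scaled by the inverse mass diagonal, half-step
#' momentum. `gradFn(position)` must return the gradient of the log target
#' density (= minus the potential-energy gradient). Deterministic,
#' time-reversible (negate momentum) and volume preserving.
#'
#' @param position,momentum numeric vectors of equal length.
#' @param epsilon step size > 0.
#' @param n number of steps >= 1.
#' @param gradFn gradient oracle of the log target density.
#' @param massDiag diagonal of the mass matrix (default identity).
#' @return list with elements `position` and `momentum`.
#' @export
leapfrog <- function(position, momentum, epsilon, n, gradFn,
                     massDiag = rep(1, length(position))) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (n < 1) stop("n must be >= 1")
  g <- gradFn(position)
  if (!all(is.finite(g)))
    stop(errorCondition("non-finite gradient in leapfrog",
                        class = c("leapfrogError", "error", "condition"),
                        position = position))
  for (s in seq_len(n)) {
    momentum <- momentum + (epsilon / 2) * g
    position <- position + epsilon * momentum / massDiag
    g <- gradFn(position)
    if (!all(is.finite(g)))
      stop(errorCondition("non-finite gradient in leapfrog",
                          class = c("leapfrogError", "error", "condition"),
                          position = position))
    momentum <- momentum + (epsilon / 2) * g
  }
  list(position = position, momentum = momentum)
}

# log target and gradient for the two tau-update modes.
# gibbs: position = gamma, tau fixed within the HMC step.
# joint: position = c(gamma, log tau); the +log(tau) Jacobian of the
# log-transform enters the target.
.hmcTarget <- function(stats, spec, mode, tau = NULL) {
  if (mode == "gibbs") {
    list(
      logDens = function(pos) coalescentLogLik(stats, pos) +
        gmrfLogPrior(pos, tau, spec),
      grad = function(pos) gradGamma(stats = stats, spec = spec,
                                     gamma = pos, tau = tau))
  } else {
    M <- spec@M
    list(
      logDens = function(pos) {
        d <- length(pos)
        gamma <- pos[-d]; lt <- pos[d]; tv <- exp(lt)
        coalescentLogLik(stats, gamma) +
          (M / 2) * lt - (tv / 2) * qQuadform(gamma) +
          (spec@a - 1) * lt - spec@b * tv + lt  # + Jacobian
      },
      grad = function(pos) {
        d <- length(pos)
        gamma <- pos[-d]; tv <- exp(pos[d])
        c(-stats@c + stats@S * exp(-gamma) - tv * qProd(gamma),
          M / 2 + spec@a - tv * (spec@b + qQuadform(gamma) / 2))
      })
  }
}

#' One Hamiltonian Monte Carlo transition
#'
#' Draws momentum from `N(0, M)`, integrates the leapfrog trajectory on the
#' position block (gamma alone in `gibbs` mode; `(gamma, log tau)` in
#' `joint` mode, with the log-transform Jacobian in the potential), and
#' accepts with probability `min(1, exp(-deltaH))`. A non-finite Hamiltonian
#' or gradient rejects the proposal.
#'
#' @param state current [SkygridState-class].
#' @param stats a [SuffStats-class].
#' @param spec a [GMRFSpec-class].
#' @param settings an [HMCSettings-class]; `settings@epsilon` must be set
#'   (see [runHMC()] for the adaptive default).
#' @param epsilon optional step-size override (used during adaptation).
#' @return list with `state`, `accepted`, `acceptProb`, `deltaH`.
#' @export
hmcStep <- function(state, stats, spec, settings = hmcSettings(epsilon = 0.1),
                    epsilon = settings@epsilon) {
  mode <- settings@tauUpdate
  pos <- if (mode == "joint") c(state@gamma, log(state@tau)) else state@gamma
  d <- length(pos)
  massDiag <- if (length(settings@massDiagonal) == d)
    settings@massDiagonal else rep(1, d)
  target <- .hmcTarget(stats, spec, mode, tau = state@tau)
  p0 <- rnorm(d, sd = sqrt(massDiag))
  H0 <- -target$logDens(pos) + sum(p0^2 / massDiag) / 2
  prop <- tryCatch(
    leapfrog(pos, p0, epsilon, settings@nLeapfrog, target$grad, massDiag),
    leapfrogError = function(e) NULL)
  if (is.null(prop))
    return(list(state = state, accepted = FALSE, acceptProb = 0,
                deltaH = Inf))
  H1 <- -target$logDens(prop$position) +
    sum(prop$momentum^2 / massDiag) / 2
  dH <- H1 - H0
  aProb <- if (is.finite(dH)) min(1, exp(-dH)) else 0
  if (runif(1) < aProb) {
    newState <- if (mode == "joint")
      skygridState(prop$position[-d], exp(prop$position[d]))
    else skygridState(prop$position, state@tau)
    list(state = newState, accepted = TRUE, acceptProb = aProb, deltaH = dH)
  } else {
    list(state = state, accepted = FALSE, acceptProb = aProb, deltaH = dH)
  }
}

#' Conjugate Gibbs draw of the GMRF precision
#'
#' Exact draw from `Gamma(a + M/2, b + gamma' Q gamma / 2)`, the full
#' conditional of `tau` (see [tauFullConditional()]).
#'
#' @param gamma numeric vector of log population sizes.
#' @param spec a [GMRFSpec-class].
#' @return positive numeric draw.
#' @export
gibbsTau <- function(gamma, spec) {
  fc <- tauFullConditional(gamma, spec)
  rgamma(1, shape = fc$shape, rate = fc$rate)
}

#' Initialise dual-averaging step-size adaptation state
#'
#' @param epsilon0 initial step size.
#' @param warmupIterations number of adaptation iterations before freezing.
#' @return adaptation state list for [adaptStepSize()].
#' @export
initStepSizeAdapt <- function(epsilon0, warmupIterations) {
  list(epsilon = epsilon0, mu = log(10 * epsilon0), logEpsBar = log(epsilon0),
       Hbar = 0, t = 0L, warmup = as.integer(warmupIterations),
       gamma0 = 0.05, t0 = 10, kappa = 0.75, frozen = FALSE)
}

#' Dual-averaging update of the leapfrog step size
#'
#' Nesterov dual averaging targeting `settings@targetAccept`: persistently
#' high acceptance raises epsilon, persistently low acceptance lowers it.
#' After `adapt$warmup` updates the step size freezes at the averaged value
#' and further calls leave it unchanged.
#'
#' @param adapt adaptation state from [initStepSizeAdapt()].
#' @param acceptProb acceptance probability of the last proposal.
#' @param settings an [HMCSettings-class] (supplies the target acceptance).
#' @return updated adaptation state; `$epsilon` holds the step size for the
#'   next iteration.
#' @export
adaptStepSize <- function(adapt, acceptProb, settings = hmcSettings()) {
  if (adapt$frozen || adapt$t >= adapt$warmup) {
    adapt$frozen <- TRUE
    adapt$epsilon <- exp(adapt$logEpsBar)
    return(adapt)
  }
  adapt$t <- adapt$t + 1L
  eta <- 1 / (adapt$t + adapt$t0)
  adapt$Hbar <- (1 - eta) * adapt$Hbar +
    eta * (settings@targetAccept - acceptProb)
  logEps <- adapt$mu - sqrt(adapt$t) / adapt$gamma0 * adapt$Hbar
  w <- adapt$t^(-adapt$kappa)
  adapt$logEpsBar <- w * logEps + (1 - w) * adapt$logEpsBar
  adapt$epsilon <- exp(logEps)
  if (adapt$t >= adapt$warmup) {
    adapt$frozen <- TRUE
    adapt$epsilon <- exp(adapt$logEpsBar)
  }
  adapt
}

#' Run a Hamiltonian Monte Carlo chain
#'
#' Each iteration performs one HMC transition and, in `gibbs` mode, one
#' conjugate precision draw. The step size adapts by dual averaging during
#' the first `warmupFraction` of iterations and is frozen thereafter. The
#' default initial step size is `0.1 / sqrt(d)`.
#'
#' @inheritParams runBUMCMC
#' @param settings an [HMCSettings-class].
#' @return A [Trace-class]; the extra attribute `postWarmupAcceptance`
#'   records the acceptance rate after step-size freezing.
#' @export
runHMC <- function(init, stats, spec, settings = hmcSettings(),
                   iterations = 1000L, thin = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  d <- length(init@gamma) + (settings@tauUpdate == "joint")
  eps0 <- if (length(settings@epsilon)) settings@epsilon else 0.1 / sqrt(d)
  warmup <- floor(settings@warmupFraction * iterations)
  adapt <- initStepSizeAdapt(eps0, warmup)
  nKeep <- if (iterations >= thin) iterations %/% thin else 0L
  gm <- matrix(NA_real_, nKeep + 1L, length(init@gamma))
  tv <- numeric(nKeep + 1L)
  lp <- numeric(nKeep + 1L)
  gm[1L, ] <- init@gamma; tv[1L] <- init@tau
  lp[1L] <- logPosterior(init, stats, spec)
  state <- init
  nAcc <- 0L; nPost <- 0L; nAccPost <- 0L
  row <- 1L
  if (iterations > 0) for (it in seq_len(iterations)) {
    res <- hmcStep(state, stats, spec, settings, epsilon = adapt$epsilon)
    state <- res$state
    if (settings@tauUpdate == "gibbs")
      state <- skygridState(state@gamma, gibbsTau(state@gamma, spec))
    adapt <- adaptStepSize(adapt, res$acceptProb, settings)
    nAcc <- nAcc + res$accepted
    if (it > warmup) { nPost <- nPost + 1L; nAccPost <- nAccPost + res$accepted }
    if (it %% thin == 0L) {
      row <- row + 1L
      gm[row, ] <- state@gamma; tv[row] <- state@tau
      lp[row] <- logPosterior(state, stats, spec)
    }
  }
  tr <- new("Trace", gamma = gm, tau = tv, logPosteriors = lp,
            acceptanceRate = if (iterations > 0) nAcc / iterations else 0,
            iterationStride = as.integer(thin),
            wallTime = proc.time()[["elapsed"]] - t0, sampler = "hmc")
  attr(tr, "postWarmupAcceptance") <- if (nPost > 0) nAccPost / nPost else NA_real_
  attr(tr, "epsilonFinal") <- adapt$epsilon
  tr
}
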