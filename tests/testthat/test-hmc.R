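test_that("leapfrog reproduces hand-computed steps and free-particle motion", {
  # flat target: straight-line motion
  flat <- function(p) rep(0, length(p))
  out <- leapfrog(c(0, 1), c(2, -1), epsilon = 0.1, n = 7, flat)
  expect_equal(out$position, c(0, 1) + 7 * 0.1 * c(2, -1))
  expect_equal(out$momentum, c(2, -1))

  # standard quadratic potential U = x^2/2, grad log target = -x
  quad <- function(p) -p
  one <- leapfrog(1, 0, epsilon = 0.1, n = 1, quad)
  # p_half = -0.05, x1 = 0.995, p1 = -0.09975
  expect_equal(one$position, 0.995)
  expect_equal(one$momentum, -0.09975)

  expect_error(leapfrog(1, 0, epsilon = 0, n = 1, quad), "epsilon")
  expect_error(leapfrog(1, 0, epsilon = 0.1, n = 1,
                        function(p) NaN), class = "leapfrogError")
})

test_that("leapfrog is reversible and volume preserving", {
  set.seed(12)
  grad <- function(p) -p - 0.3 * p^3
  for (rep in 1:10) {
    d <- sample(1:6, 1)
    x0 <- rnorm(d); p0 <- rnorm(d)
    mass <- runif(d, 0.5, 2)
    fwd <- leapfrog(x0, p0, 0.05, 25, grad, mass)
    back <- leapfrog(fwd$position, -fwd$momentum, 0.05, 25, grad, mass)
    expect_equal(back$position, x0, tolerance = 1e-10)
    expect_equal(-back$momentum, p0, tolerance = 1e-10)
  }
  # volume preservation: finite-difference Jacobian determinant of the
  # phase-space map is 1
  d <- 2
  phaseMap <- function(z) {
    o <- leapfrog(z[1:d], z[(d + 1):(2 * d)], 0.1, 5, grad)
    c(o$position, o$momentum)
  }
  z0 <- c(0.3, -0.4, 0.8, 0.1)
  h <- 1e-6
  J <- sapply(seq_len(2 * d), function(j) {
    e <- numeric(2 * d); e[j] <- h
    (phaseMap(z0 + e) - phaseMap(z0 - e)) / (2 * h)
  })
  expect_equal(det(J), 1, tolerance = 1e-6)
})

test_that("energy error scales as epsilon^2 and vanishing epsilon accepts", {
  dat <- smallDataset(seed = 41)
  tau <- 3
  gamma0 <- newtonRaphsonMode(rep(0, 5), tau, dat$stats, dat$spec) + 0.3
  target <- skygridmc:::.hmcTarget(dat$stats, dat$spec, "gibbs", tau = tau)
  p0 <- c(0.5, -0.2, 0.9, 0.1, -0.7)
  H <- function(pos, p) -target$logDens(pos) + sum(p^2) / 2
  eps <- c(0.2, 0.1, 0.05, 0.025)
  dH <- vapply(eps, function(e) {
    # fixed total trajectory time so only the step size varies
    n <- round(2 / e)
    out <- leapfrog(gamma0, p0, e, n, target$grad)
    abs(H(out$position, out$momentum) - H(gamma0, p0))
  }, numeric(1))
  slope <- coef(lm(log(dH) ~ log(eps)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)

  # epsilon -> 0: acceptance probability -> 1
  set.seed(2)
  res <- hmcStep(skygridState(gamma0, tau), dat$stats, dat$spec,
                 hmcSettings(epsilon = 1e-6, nLeapfrog = 3))
  expect_equal(res$acceptProb, 1, tolerance = 1e-6)
})

test_that("gibbs draws of tau follow the conjugate gamma law", {
  spec <- gmrfSpec(1)
  gamma <- c(0, 1)
  fc <- tauFullConditional(gamma, spec)
  expect_equal(c(fc$shape, fc$rate), c(0.501, 0.501))
  set.seed(14)
  draws <- replicate(1e4, gibbsTau(gamma, spec))
  ks <- ks.test(draws, pgamma, shape = fc$shape, rate = fc$rate)
  expect_gt(ks$p.value, 0.01)
  # moments of a larger sample
  draws2 <- replicate(1e5, gibbsTau(gamma, spec))
  se <- sd(draws2) / sqrt(length(draws2))
  expect_lt(abs(mean(draws2) - fc$shape / fc$rate), 3 * se)
  # constant gamma: rate reduces to b
  fc0 <- tauFullConditional(c(2, 2), spec)
  expect_equal(fc0$rate, spec@b)
})

test_that("dual averaging responds monotonically and freezes after warmup", {
  s <- hmcSettings(targetAccept = 0.8)
  ad <- initStepSizeAdapt(0.1, warmupIterations = 50)
  # all-accept history: epsilon strictly increases
  eps <- numeric(10)
  for (i in 1:10) {
    ad <- adaptStepSize(ad, 1.0, s)
    eps[i] <- ad$epsilon
  }
  expect_true(all(diff(eps) > 0))
  # all-reject: epsilon decreases
  ad2 <- initStepSizeAdapt(0.1, warmupIterations = 50)
  ad2 <- adaptStepSize(ad2, 0, s)
  e1 <- ad2$epsilon
  ad2 <- adaptStepSize(ad2, 0, s)
  expect_lt(ad2$epsilon, e1)
  # post-warmup: frozen
  ad3 <- initStepSizeAdapt(0.1, warmupIterations = 2)
  ad3 <- adaptStepSize(ad3, 1, s)
  ad3 <- adaptStepSize(ad3, 1, s)
  frozenEps <- ad3$epsilon
  ad3 <- adaptStepSize(ad3, 0, s)
  expect_identical(ad3$epsilon, frozenEps)
  expect_true(ad3$frozen)
})

test_that("adapted step size reaches the target acceptance on a Gaussian target", {
  # standard multivariate normal via a quadratic 'likelihood': use the
  # skygrid machinery with an exactly Gaussian full conditional is not
  # available, so drive hmcStep's ingredients directly
  set.seed(33)
  d <- 5
  grad <- function(p) -p
  logDens <- function(p) -sum(p^2) / 2
  s <- hmcSettings(targetAccept = 0.8, nLeapfrog = 10)
  ad <- initStepSizeAdapt(0.5, warmupIterations = 500)
  x <- rnorm(d)
  accPost <- 0; nPost <- 0
  for (it in 1:1500) {
    p0 <- rnorm(d)
    H0 <- -logDens(x) + sum(p0^2) / 2
    out <- leapfrog(x, p0, ad$epsilon, s@nLeapfrog, grad)
    dH <- (-logDens(out$position) + sum(out$momentum^2) / 2) - H0
    aProb <- min(1, exp(-dH))
    if (runif(1) < aProb) x <- out$position
    ad <- adaptStepSize(ad, aProb, s)
    if (it > 500) { accPost <- accPost + aProb; nPost <- nPost + 1 }
  }
  expect_lt(abs(accPost / nPost - 0.8), 0.1)
})

test_that("runHMC is reproducible, records the initial state and mixes", {
  dat <- smallDataset(seed = 55)
  init <- skygridState(rep(log(6), 5), 1)
  tr0 <- runHMC(init, dat$stats, dat$spec, iterations = 0)
  expect_equal(nrow(gammaSamples(tr0)), 1L)

  tr1 <- runHMC(init, dat$stats, dat$spec, iterations = 1500, thin = 3,
                seed = 7)
  tr2 <- runHMC(init, dat$stats, dat$spec, iterations = 1500, thin = 3,
                seed = 7)
  expect_identical(gammaSamples(tr1), gammaSamples(tr2))
  expect_identical(tauSamples(tr1), tauSamples(tr2))
  pw <- attr(tr1, "postWarmupAcceptance")
  expect_gt(pw, 0.5)
  expect_lt(pw, 0.99)

  # joint mode runs and keeps tau positive
  trJ <- runHMC(init, dat$stats, dat$spec,
                hmcSettings(tauUpdate = "joint"), iterations = 1000,
                thin = 5, seed = 8)
  expect_true(all(tauSamples(trJ) > 0))
})
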