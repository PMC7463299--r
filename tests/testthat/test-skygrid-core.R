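test_that("buildGrid spaces points evenly and validates input", {
  g <- buildGrid(40, 4)
  expect_equal(gridPoints(g), c(10, 20, 30, 40))
  expect_equal(gridCutoff(g), 40)
  expect_equal(nIntervals(g), 5L)

  weekly <- buildGrid(1, 52)
  expect_equal(nIntervals(weekly), 53L)  # 52 grid points, 53 parameters
  expect_equal(gridPoints(weekly)[52], 1)

  single <- buildGrid(10, 1)
  expect_equal(gridPoints(single), 10)
  expect_equal(nIntervals(single), 2L)

  expect_error(buildGrid(-1, 4))
  expect_error(buildGrid(10, 0))
})

test_that("sufficient statistics match the hand-worked three-tip example", {
  st <- threeTipStats()
  expect_equal(coalCounts(st), c(1, 1))
  # spans: 3 lineages on [0,1] -> 3; 1 lineage weight... 2 lineages on
  # [1,1.5] -> 0.5 into interval 1; 2 lineages on [1.5,2] -> 0.5 interval 2
  expect_equal(waitSums(st), c(3.5, 0.5))

  # additivity over loci
  st2 <- sufficientStatistics(list(threeTipSequence(), threeTipSequence()),
                              buildGrid(1.5, 1))
  expect_equal(coalCounts(st2), c(2, 2))
  expect_equal(waitSums(st2), c(7, 1))

  # grid entirely beyond the TMRCA leaves the old interval empty
  stE <- sufficientStatistics(threeTipSequence(), buildGrid(5, 1))
  expect_equal(coalCounts(stE)[2], 0)
  expect_equal(waitSums(stE)[2], 0)
})

test_that("events exactly on a grid point belong to the older interval", {
  es <- threeTipSequence()  # coalescences at 1 and 2
  st <- sufficientStatistics(es, buildGrid(2, 2))  # grid points 1, 2
  # both coalescences sit exactly on grid points -> intervals 2 and 3
  expect_equal(coalCounts(st), c(0, 1, 1))
})

test_that("coalescent log likelihood matches direct substitution", {
  st <- threeTipStats()
  expect_equal(coalescentLogLik(st, c(0, 0)), -4)
  expect_equal(coalescentLogLik(st, log(c(3.5, 0.5))),
               -log(3.5) - 1 - log(0.5) - 1)
  empty <- new("SuffStats", c = c(0, 0), S = c(0, 0))
  expect_equal(coalescentLogLik(empty, c(1, -1)), 0)
  expect_error(coalescentLogLik(st, c(0, 0, 0)), "length")
})

test_that("direct interval evaluation equals the sufficient-statistic path", {
  es <- threeTipSequence()
  grid <- buildGrid(1.5, 1)
  expect_equal(intervalLogLikDirect(es, grid, c(0, 0)), -4)

  # single pair coalescing at t with one interval: -gamma - t exp(-gamma)
  g2 <- assignTipDates(parseNewick("(A:1.2,B:1.2);"), c(A = 0, B = 0))
  es2 <- extractEventSequence(g2)
  grid1 <- buildGrid(10, 1)
  gam <- c(0.7, 0.7)
  expect_equal(intervalLogLikDirect(es2, grid1, gam),
               -0.7 - 1.2 * exp(-0.7))

  # oracle equivalence over random genealogies and random grids
  set.seed(17)
  for (rep in 1:60) {
    es <- extractEventSequence(randomGenealogy(sample(2:50, 1)))
    M <- sample(1:8, 1)
    grid <- buildGrid(runif(1, 0.5, 15), M)
    gamma <- rnorm(M + 1)
    direct <- intervalLogLikDirect(es, grid, gamma)
    viaStats <- coalescentLogLik(sufficientStatistics(es, grid), gamma)
    expect_equal(direct, viaStats, tolerance = 1e-12)
  }
})

test_that("likelihood is unchanged by grid refinement with duplicated gamma", {
  set.seed(3)
  es <- extractEventSequence(randomGenealogy(15))
  grid <- buildGrid(6, 3)  # points 2,4,6
  gamma <- rnorm(4)
  base <- coalescentLogLik(sufficientStatistics(es, grid), gamma)
  # split interval 2 ([2,4)) at 3 and duplicate gamma_2
  grid2 <- buildGrid(6, 4, gridPoints = c(2, 3, 4, 6))
  gamma2 <- gamma[c(1, 2, 2, 3, 4)]
  refined <- coalescentLogLik(sufficientStatistics(es, grid2), gamma2)
  expect_equal(refined, base, tolerance = 1e-12)
})

test_that("GMRF prior and Q identity behave per the first-difference form", {
  spec <- gmrfSpec(1)
  expect_equal(gmrfLogPrior(c(0, 1), 2, spec), 0.5 * log(2) - 1)
  expect_equal(gmrfLogPrior(c(3, 3), 2, spec), 0.5 * log(2))
  expect_error(gmrfLogPrior(c(0, 1), 0, spec), "tau")

  set.seed(9)
  for (rep in 1:25) {
    M <- sample(1:12, 1)
    gamma <- rnorm(M + 1)
    Q <- gmrfQ(gmrfSpec(M))
    expect_equal(drop(gamma %*% Q %*% gamma), sum(diff(gamma)^2),
                 tolerance = 1e-12)
    expect_gte(drop(gamma %*% Q %*% gamma), 0)
  }
  # null space of Q is the constant vector
  expect_equal(drop(rep(2, 5) %*% gmrfQ(gmrfSpec(4)) %*% rep(2, 5)), 0)
})

test_that("tau prior, posterior and full conditional match closed forms", {
  spec <- gmrfSpec(1)  # a = b = 0.001 defaults
  expect_equal(tauLogPrior(1, spec), -0.001)
  expect_equal(tauLogPrior(3, gmrfSpec(1, a = 1, b = 1)), -3)
  expect_error(tauLogPrior(0, spec), "tau")

  st <- threeTipStats()
  expect_equal(logPosterior(stats = st, spec = spec, gamma = c(0, 0), tau = 1),
               -4.001)

  fc <- tauFullConditional(c(0, 1), spec)
  expect_equal(fc$shape, 0.501)
  expect_equal(fc$rate, 0.501)
  expect_equal(tauFullConditional(c(2, 2), spec)$rate, spec@b)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(21)
  fd <- function(gamma, tau, stats, spec, h = 1e-5) {
    vapply(seq_along(gamma), function(k) {
      up <- gamma; up[k] <- up[k] + h
      dn <- gamma; dn[k] <- dn[k] - h
      (logPosterior(stats = stats, spec = spec, gamma = up, tau = tau) -
         logPosterior(stats = stats, spec = spec, gamma = dn, tau = tau)) /
        (2 * h)
    }, numeric(1))
  }
  st <- threeTipStats()
  spec <- gmrfSpec(1)
  expect_equal(gradGamma(stats = st, spec = spec, gamma = c(0, 0), tau = 1),
               c(2.5, -0.5))
  # per-interval MLE is stationary when the prior is (numerically) off
  expect_equal(gradGamma(stats = st, spec = spec,
                         gamma = log(c(3.5, 0.5)), tau = 1e-300),
               c(0, 0), tolerance = 1e-12)
  for (rep in 1:50) {
    M <- sample(1:9, 1)
    stats <- new("SuffStats", c = rpois(M + 1, 3),
                 S = rgamma(M + 1, 2, 0.5) + 0.05)
    spec <- gmrfSpec(M)
    gamma <- rnorm(M + 1)
    tau <- rgamma(1, 2, 1) + 0.1
    g <- gradGamma(stats = stats, spec = spec, gamma = gamma, tau = tau)
    gf <- fd(gamma, tau, stats, spec)
    expect_equal(g, gf, tolerance = 1e-6)
  }
})

test_that("likelihood depends on event times only, not topology", {
  # two different topologies with identical sampling/coalescent times
  a <- assignTipDates(parseNewick("(((A:1,B:1):1,C:2):1,D:3);"),
                      c(A = 0, B = 0, C = 0, D = 0))
  b <- assignTipDates(parseNewick("(((A:1,C:1):1,B:2):1,D:3);"),
                      c(A = 0, B = 0, C = 0, D = 0))
  grid <- buildGrid(2.5, 2)
  gamma <- c(0.3, -0.2, 0.5)
  la <- coalescentLogLik(sufficientStatistics(extractEventSequence(a), grid), gamma)
  lb <- coalescentLogLik(sufficientStatistics(extractEventSequence(b), grid), gamma)
  expect_equal(la, lb)
})
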