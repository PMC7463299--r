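# Shared fixtures: small hand-checkable genealogies and random generators
# used across the unit and property tests.

# three isochronous tips, coalescences at backwards times 1 and 2
threeTipSequence <- function() {
  g <- assignTipDates(parseNewick("((A:1,B:1):1,C:2);"),
                      c(A = 2000, B = 2000, C = 2000))
  extractEventSequence(g)
}

# the worked sufficient statistics of the three-tip tree on a grid with
# one point at 1.5: c = (1, 1), S = (3.5, 0.5)
threeTipStats <- function() sufficientStatistics(threeTipSequence(),
                                                 buildGrid(1.5, 1))

# random heterochronous genealogy via the simulator
randomGenealogy <- function(nTips = 10, maxSpread = 2, theta = 5) {
  st <- sort(runif(nTips, 0, maxSpread))
  st[1] <- 0
  simulateGenealogy(st, grid = buildGrid(10, 1),
                    gamma = rep(log(theta), 2))
}

# small simulated multi-locus dataset with its grid/spec/stats
smallDataset <- function(seed = 11, m = 2, nTips = 12, M = 4, cutoff = 6,
                         gamma = NULL) {
  set.seed(seed)
  grid <- buildGrid(cutoff, M)
  if (is.null(gamma)) gamma <- seq(log(10), log(3), length.out = M + 1)
  gens <- simulateDataset(m, rep(0, nTips), grid = grid, gamma = gamma)
  ref <- max(vapply(gens, function(g) g@mostRecentTipDate, numeric(1)))
  seqs <- lapply(gens, extractEventSequence, globalReference = ref)
  list(grid = grid, spec = gmrfSpec(M),
       stats = sufficientStatistics(seqs, grid), seqs = seqs, gamma = gamma)
}
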