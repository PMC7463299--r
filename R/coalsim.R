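# Heterochronous coalescent simulator for piecewise-constant demographic
# functions -- the exact data-generating process of the skygrid likelihood.
# Waiting times are drawn by analytic time rescaling: the cumulative
# coalescent intensity is integrated exactly across grid breakpoints (the
# rate v(v-1)/(2 theta_k) is constant within each piece), never by thinning.

# theta at backwards time t under (grid, gamma)
.thetaAt <- function(t, gridPts, theta) theta[.intervalIndex(t, gridPts)]

#' Simulate one heterochronous genealogy
#'
#' Lineages enter at the given backwards sampling times; while at least two
#' are active, the next coalescence time is drawn from the inhomogeneous
#' exponential law with rate `v(v-1) / (2 theta_k)` (piecewise-constant
#' `theta = exp(gamma)` on the grid), truncated at the next sampling time.
#' Coalescing pairs are chosen uniformly. The most recent sample is anchored
#' at `calendarAnchor` and all tips are dated accordingly.
#'
#' @param sampleTimes numeric, backwards sampling times (>= 0); recycled
#'   against `sampleCounts`.
#' @param sampleCounts integer, tips sampled at each time (default 1 each).
#' @param grid a [GridSpec-class].
#' @param gamma log population sizes, length `M + 1`.
#' @param calendarAnchor calendar date assigned to the most recent sample.
#' @return A dated [DatedGenealogy-class] with tips labelled
#'   `t1_<date>, t2_<date>, ...`.
#' @examples
#' set.seed(1)
#' g <- simulateGenealogy(c(0, 0, 1), grid = buildGrid(5, 1),
#'                        gamma = c(0, 0))
#' @export
simulateGenealogy <- function(sampleTimes, sampleCounts = rep(1L, length(sampleTimes)),
                              grid, gamma, calendarAnchor = 2000.0) {
  if (length(gamma) != grid@M + 1L)
    stop("gamma length must equal M + 1")
  st <- rep(sampleTimes, sampleCounts)
  n <- length(st)
  if (n < 2L) stop("at least 2 samples are required")
  st <- sort(st)
  x <- grid@gridPoints
  theta <- exp(gamma)

  nodeTime <- c(st, rep(NA_real_, n - 1L))   # backwards times, tips then internals
  parent <- integer(2L * n - 1L)
  active <- integer(0)
  pending <- seq_len(n)                      # tip ids in time order
  t <- st[1]
  nextInternal <- n + 1L
  while (length(pending) || length(active) > 1L) {
    # admit all samples at the current time
    while (length(pending) && nodeTime[pending[1]] <= t + 1e-12) {
      active <- c(active, pending[1])
      pending <- pending[-1L]
    }
    v <- length(active)
    tNext <- if (length(pending)) nodeTime[pending[1]] else Inf
    if (v < 2L) {
      t <- tNext
      next
    }
    # draw the coalescence waiting time by exact piecewise integration
    E <- rexp(1)
    tc <- NA_real_
    a <- t
    repeat {
      k <- .intervalIndex(a, x)
      pieceEnd <- min(if (k <= length(x)) x[k] else Inf, tNext)
      rate <- v * (v - 1) / (2 * theta[k])
      cap <- rate * (pieceEnd - a)
      if (E <= cap) { tc <- a + E / rate; break }
      E <- E - cap
      a <- pieceEnd
      if (a >= tNext) break
    }
    if (is.na(tc)) {  # reached the next sampling time first
      t <- tNext
      next
    }
    pair <- if (v == 2L) active else sample(active, 2L)
    node <- nextInternal
    nextInternal <- nextInternal + 1L
    nodeTime[node] <- tc
    parent[pair] <- node
    active <- c(setdiff(active, pair), node)
    t <- tc
  }

  # assemble an ape::phylo; the root (last internal node) must be n + 1
  nInternal <- n - 1L
  created <- (n + 1L):(2L * n - 1L)
  newId <- integer(2L * n - 1L)
  newId[seq_len(n)] <- seq_len(n)
  newId[created] <- n + rev(seq_len(nInternal))  # root (created last) -> n+1
  edgeChild <- which(parent > 0L)
  edge <- cbind(newId[parent[edgeChild]], newId[edgeChild])
  edgeLen <- nodeTime[parent[edgeChild]] - nodeTime[edgeChild]
  dates <- calendarAnchor - (st - st[1])
  labels <- sprintf("t%d_%s", seq_len(n), format(dates, trim = TRUE))
  tr <- structure(list(edge = edge, edge.length = edgeLen,
                       tip.label = labels, Nnode = nInternal),
                  class = "phylo", order = "unknown")
  tr <- ape::reorder.phylo(tr, "cladewise")
  names(dates) <- labels
  assignTipDates(.asGenealogy(tr), dates)
}

#' Simulate a multi-locus data set
#'
#' `m` independent genealogies sharing one demographic function, the product
#' form of the multi-locus skygrid likelihood.
#'
#' @param m number of loci (>= 1).
#' @param sampleTimes,sampleCounts per-locus sampling scheme (shared across
#'   loci; pass a list of length `m` for per-locus schemes).
#' @inheritParams simulateGenealogy
#' @return list of `m` dated [DatedGenealogy-class] objects.
#' @export
simulateDataset <- function(m, sampleTimes, sampleCounts = NULL, grid, gamma,
                            calendarAnchor = 2000.0) {
  if (m < 1L) stop("m must be >= 1")
  stList <- if (is.list(sampleTimes)) sampleTimes else
    rep(list(sampleTimes), m)
  scList <- if (is.list(sampleCounts)) sampleCounts else
    rep(list(if (is.null(sampleCounts))
      rep(1L, length(stList[[1]])) else sampleCounts), m)
  lapply(seq_len(m), function(i)
    simulateGenealogy(stList[[i]], scList[[i]], grid, gamma, calendarAnchor))
}

#' Write simulated genealogies to disk
#'
#' Newick (one tree per line) plus a `taxon<TAB>date` TSV -- the input
#' formats of [readGenealogies()] and [readTipDates()]. Tip labels are made
#' unique across loci by a `locus<i>_` prefix.
#'
#' @param genealogies list of dated [DatedGenealogy-class] objects.
#' @param treesFile,datesFile output paths.
#' @return invisibly, the two paths.
#' @export
writeSimulation <- function(genealogies, treesFile, datesFile) {
  allDates <- list()
  lines <- character(length(genealogies))
  for (i in seq_along(genealogies)) {
    g <- genealogies[[i]]
    tr <- g@tree
    tr$tip.label <- sprintf("locus%d_%s", i, tr$tip.label)
    lines[i] <- ape::write.tree(tr)
    d <- g@tipDates
    names(d) <- tr$tip.label
    allDates[[i]] <- d
  }
  writeLines(lines, treesFile)
  d <- unlist(allDates)
  write.table(data.frame(taxon = names(d), date = unname(d)),
              datesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(treesFile, datesFile))
}
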