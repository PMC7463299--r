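# Runner functions tying I/O, simulation, sampling and diagnostics together.
# Configs are flat YAML (or plain R lists) whose keys mirror the function
# arguments; these functions are what the thin command-line wrapper in
# inst/scripts/skygrid-tool.R dispatches to.

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

.cfg <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) stop("config key missing: ", key)
  default
}

# Load trees + dates per the config, returning dated genealogies.
.loadData <- function(config) {
  treeFiles <- .cfg(config, "trees", required = TRUE)
  gens <- unlist(lapply(treeFiles, readGenealogies), recursive = FALSE)
  datesFile <- .cfg(config, "dates")
  lapply(gens, function(g) {
    dates <- if (!is.null(datesFile)) {
      all <- readTipDates(datesFile)
      all[names(all) %in% g@tree$tip.label]
    } else tipDatesFromLabels(g)
    assignTipDates(g, dates)
  })
}

.samplers <- c("bumcmc", "hmc", "rwmh")

# One sampler run on prepared sufficient statistics. Returns a Trace.
.runSampler <- function(sampler, init, stats, spec, config,
                        iterations, thin, seed) {
  switch(sampler,
    bumcmc = runBUMCMC(init, stats, spec,
                       bumcmcSettings(F = .cfg(config, "tuning_F", 2.0)),
                       iterations = iterations, thin = thin, seed = seed),
    hmc = runHMC(init, stats, spec,
                 hmcSettings(epsilon = .cfg(config, "epsilon"),
                             nLeapfrog = .cfg(config, "leapfrog_steps", 20L),
                             tauUpdate = .cfg(config, "tau_update", "gibbs")),
                 iterations = iterations, thin = thin, seed = seed),
    rwmh = runRWMH(init, stats, spec, iterations = iterations, thin = thin,
                   seed = seed),
    stop("unknown sampler '", sampler, "'; valid kernels: ",
         paste(.samplers, collapse = ", ")))
}

# Moment-based starting state: constant gamma at the pooled estimate.
.initState <- function(stats) {
  pooled <- sum(stats@S) / max(sum(stats@c), 1)
  skygridState(rep(log(max(pooled, 1e-6)), length(stats@c)), tau = 1)
}

#' Run a skygrid analysis on dated genealogies
#'
#' Reads the trees and dates named in the config, builds the grid and
#' sufficient statistics, runs the configured sampler, and writes a
#' Tracer-style tab-separated parameter log (columns `state`,
#' `logPopSize1..d`, `precision`), a trajectory CSV and a diagnostics JSON.
#' No output is written if any stage fails.
#'
#' Config keys: `trees` (paths), `dates` (TSV path; omit to parse dates from
#' trailing `_<decimal>` in tip labels), `cutoff`, `grid_points` (M),
#' `sampler` (one of bumcmc/hmc/rwmh), `iterations`, `thin`, `seed`,
#' `prior_a`, `prior_b`, `epsilon`, `leapfrog_steps`, `tau_update`,
#' `tuning_F`, `out_log`, `out_trajectory`, `out_json`.
#'
#' @param config a flat list or path to a YAML file.
#' @return invisibly, a list with the `trace`, `grid`, `stats`, `summary`
#'   (trajectory data.frame) and `diagnostics` list.
#' @export
runAnalysis <- function(config) {
  config <- .loadConfig(config)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  sampler <- match.arg(.cfg(config, "sampler", "bumcmc"), .samplers)
  gens <- .loadData(config)
  reference <- max(vapply(gens, function(g) g@mostRecentTipDate, numeric(1)))
  seqs <- lapply(gens, extractEventSequence, globalReference = reference)
  grid <- buildGrid(.cfg(config, "cutoff", required = TRUE),
                    .cfg(config, "grid_points", required = TRUE))
  spec <- gmrfSpec(grid@M, a = .cfg(config, "prior_a", 0.001),
                   b = .cfg(config, "prior_b", 0.001))
  stats <- sufficientStatistics(seqs, grid)
  seed <- .cfg(config, "seed", 1L)
  iterations <- .cfg(config, "iterations", 10000L)
  thin <- .cfg(config, "thin", 10L)
  trace <- .runSampler(sampler, .initState(stats), stats, spec, config,
                       iterations, thin, seed)
  summary <- trajectorySummary(trace, grid, level = 0.95, discard = 0.1)
  ept <- essPerTime(trace, discard = 0.1)
  diagnostics <- list(
    version = as.character(packageVersion("skygridmc")),
    config = config, seed = seed, sampler = sampler,
    started = started, finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    acceptance_rate = trace@acceptanceRate,
    wall_time_seconds = trace@wallTime,
    ess_log_pop_sizes = unname(ept$essGamma),
    ess_precision = ept$essTau,
    min_ess_per_second = ept$min, median_ess_per_second = ept$median)
  outLog <- .cfg(config, "out_log")
  outTraj <- .cfg(config, "out_trajectory")
  outJson <- .cfg(config, "out_json")
  if (!is.null(outLog)) {
    d <- ncol(trace@gamma)
    df <- data.frame(state = (seq_len(nrow(trace@gamma)) - 1L) * trace@iterationStride,
                     trace@gamma, precision = trace@tau)
    names(df)[2:(d + 1L)] <- paste0("logPopSize", seq_len(d))
    write.table(df, outLog, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(outTraj))
    write.csv(summary, outTraj, row.names = FALSE)
  if (!is.null(outJson))
    jsonlite::write_json(diagnostics, outJson, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(list(trace = trace, grid = grid, stats = stats,
                 summary = summary, diagnostics = diagnostics))
}

#' Simulate a multi-locus data set and write it to disk
#'
#' Config keys: `m` (loci), `sample_times`, `sample_counts` (per-locus
#' scheme; defaults to `n_tips` isochronous tips at time 0), `n_tips`,
#' `cutoff`, `grid_points`, `gamma` (vector, length M+1) or `theta`
#' (constant), `seed`, `out_trees`, `out_dates`, `out_truth`.
#' The truth file is itself a YAML config fragment (trees/dates paths,
#' grid, simulating gamma and seed) accepted by [runAnalysis()].
#'
#' @param config a flat list or path to a YAML file.
#' @return invisibly, the list of simulated genealogies.
#' @export
runSimulation <- function(config) {
  config <- .loadConfig(config)
  seed <- .cfg(config, "seed", 1L)
  set.seed(seed)
  m <- .cfg(config, "m", 1L)
  grid <- buildGrid(.cfg(config, "cutoff", required = TRUE),
                    .cfg(config, "grid_points", required = TRUE))
  gamma <- .cfg(config, "gamma")
  if (is.null(gamma)) {
    theta <- .cfg(config, "theta", required = TRUE)
    gamma <- rep(log(theta), grid@M + 1L)
  }
  st <- .cfg(config, "sample_times")
  if (is.null(st)) st <- rep(0, .cfg(config, "n_tips", 10L))
  sc <- .cfg(config, "sample_counts", rep(1L, length(st)))
  gens <- simulateDataset(m, st, sc, grid, gamma)
  outTrees <- .cfg(config, "out_trees", required = TRUE)
  outDates <- .cfg(config, "out_dates", required = TRUE)
  writeSimulation(gens, outTrees, outDates)
  outTruth <- .cfg(config, "out_truth")
  if (!is.null(outTruth))
    yaml::write_yaml(list(trees = outTrees, dates = outDates,
                          cutoff = grid@cutoff, grid_points = grid@M,
                          gamma = as.numeric(gamma), seed = seed), outTruth)
  invisible(gens)
}

#' Benchmark transition kernels on fixed genealogies
#'
#' Runs each named kernel for the configured iterations, over several
#' replicates with distinct derived seeds, on the same data, and reports
#' per-kernel min/median ESS per second of the log population sizes and the
#' ESS per second of the precision, averaged over replicates -- the
#' experimental design used to compare HMC against block-updating MCMC.
#'
#' Config keys: those of [runAnalysis()] for data/grid, plus `samplers`
#' (character vector, >= 2), `replicates` (>= 1), `iterations`, `thin`,
#' `seed`, `out_json`.
#'
#' @param config a flat list or path to a YAML file.
#' @return a data.frame (one row per kernel) with columns `sampler`,
#'   `min_ess_per_sec`, `median_ess_per_sec`, `precision_ess_per_sec`,
#'   plus attribute `replicates` holding the per-replicate values.
#' @export
runBenchmark <- function(config) {
  config <- .loadConfig(config)
  samplers <- .cfg(config, "samplers", required = TRUE)
  if (length(samplers) < 2L) stop("benchmark needs >= 2 kernels")
  bad <- setdiff(samplers, .samplers)
  if (length(bad))
    stop("unknown sampler '", bad[1], "'; valid kernels: ",
         paste(.samplers, collapse = ", "))
  reps <- .cfg(config, "replicates", 5L)
  gens <- .loadData(config)
  reference <- max(vapply(gens, function(g) g@mostRecentTipDate, numeric(1)))
  seqs <- lapply(gens, extractEventSequence, globalReference = reference)
  grid <- buildGrid(.cfg(config, "cutoff", required = TRUE),
                    .cfg(config, "grid_points", required = TRUE))
  spec <- gmrfSpec(grid@M, a = .cfg(config, "prior_a", 0.001),
                   b = .cfg(config, "prior_b", 0.001))
  stats <- sufficientStatistics(seqs, grid)
  iterations <- .cfg(config, "iterations", 20000L)
  thin <- .cfg(config, "thin", 2L)
  seed0 <- .cfg(config, "seed", 1L)
  init <- .initState(stats)
  perRep <- list()
  for (s in samplers) for (r in seq_len(reps)) {
    tr <- .runSampler(s, init, stats, spec, config, iterations, thin,
                      seed = seed0 + 1000L * (r - 1L) + match(s, .samplers))
    e <- essPerTime(tr, discard = 0.1)
    perRep[[length(perRep) + 1L]] <- data.frame(
      sampler = s, replicate = r, min_ess_per_sec = e$min,
      median_ess_per_sec = e$median, precision_ess_per_sec = e$tau)
  }
  perRep <- do.call(rbind, perRep)
  agg <- do.call(rbind, lapply(split(perRep, perRep$sampler), function(df)
    data.frame(sampler = df$sampler[1],
               min_ess_per_sec = mean(df$min_ess_per_sec),
               median_ess_per_sec = mean(df$median_ess_per_sec),
               precision_ess_per_sec = mean(df$precision_ess_per_sec))))
  rownames(agg) <- NULL
  attr(agg, "replicates") <- perRep
  outJson <- .cfg(config, "out_json")
  if (!is.null(outJson))
    jsonlite::write_json(
      list(version = as.character(packageVersion("skygridmc")),
           seed = seed0, iterations = iterations, replicates = reps,
           summary = agg, per_replicate = perRep),
      outJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  agg
}
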