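# Reading dated genealogies and converting them to backwards-time event
# sequences. Tree parsing is delegated to ape; this module adds the date
# plumbing and validity checks the coalescent likelihood relies on.

#' Parse a single Newick tree
#'
#' Wraps [ape::read.tree()] with stricter validation: balanced parentheses,
#' at least two tips, and a branch length on every edge. The returned
#' genealogy is undated; see [assignTipDates()].
#'
#' @param text a Newick string (single rooted tree with branch lengths).
#' @return An undated [DatedGenealogy-class].
#' @examples
#' parseNewick("((A:1,B:1):1,C:2);")
#' @export
parseNewick <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop("expected a single Newick string")
  nopen <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nclose <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (nopen != nclose)
    stop(sprintf("parse error: unbalanced parentheses (%d '(' vs %d ')')",
                 nopen, nclose))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop("parse error: not a valid Newick tree: ", substr(text, 1, 60))
  .asGenealogy(tr)
}

.asGenealogy <- function(tr) {
  if (is.null(tr$tip.label) || length(tr$tip.label) < 2L)
    stop("parse error: tree must have at least 2 tips")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("parse error: missing branch length on at least one edge")
  if (any(tr$edge.length < 0))
    stop("parse error: negative branch length")
  if (!ape::is.binary(tr))
    stop("genealogy must be strictly bifurcating")
  nd <- rep(NA_real_, length(tr$tip.label))
  names(nd) <- tr$tip.label
  new("DatedGenealogy", tree = tr, tipDates = nd,
      mostRecentTipDate = NA_real_, nodeCalendarTimes = numeric(0))
}

#' Read genealogies from a Newick or NEXUS file
#'
#' Newick files hold one tree per line; a file whose first non-blank line is
#' `#NEXUS` is read through [ape::read.nexus()] (trees block only).
#'
#' @param file path to the tree file.
#' @return A list of undated [DatedGenealogy-class] objects.
#' @export
readGenealogies <- function(file) {
  if (!file.exists(file)) stop("tree file not found: ", file)
  first <- ""
  lines <- readLines(file, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank)) first <- trimws(nonblank[1])
  if (toupper(substr(first, 1, 6)) == "#NEXUS") {
    trs <- ape::read.nexus(file)
    if (inherits(trs, "phylo")) trs <- list(trs)
  } else {
    trs <- lapply(nonblank, function(ln) {
      g <- parseNewick(ln)
      g@tree
    })
  }
  lapply(trs, .asGenealogy)
}

#' Read tip dates from a tab-separated file
#'
#' Expected format: header `taxon<TAB>date`, one row per tip, dates in
#' decimal years (or any unit consistent with the branch lengths).
#'
#' @param file path to the TSV file.
#' @return Named numeric vector of calendar dates.
#' @export
readTipDates <- function(file) {
  if (!file.exists(file)) stop("dates file not found: ", file)
  df <- read.delim(file, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric"))
  if (ncol(df) < 2L) stop("dates file must have columns taxon<TAB>date")
  dates <- df[[2]]
  names(dates) <- df[[1]]
  if (anyNA(dates)) stop("non-numeric date in dates file")
  dates
}

#' Parse tip dates from trailing "_<decimal>" in tip labels
#'
#' @param genealogy a [DatedGenealogy-class].
#' @return Named numeric vector of calendar dates.
#' @export
tipDatesFromLabels <- function(genealogy) {
  labs <- genealogy@tree$tip.label
  m <- regmatches(labs, regexpr("_[0-9]+(\\.[0-9]+)?$", labs))
  if (length(m) != length(labs) || any(!nzchar(m)))
    stop("tip labels lack a trailing _<decimal> date: ",
         paste(labs[!grepl("_[0-9]+(\\.[0-9]+)?$", labs)], collapse = ", "))
  dates <- as.numeric(sub("^_", "", m))
  names(dates) <- labs
  dates
}

#' Attach calendar dates to a genealogy's tips
#'
#' Verifies that the node times implied by the dates and branch lengths are
#' consistent across every root-to-tip path (each tip implies a calendar
#' time for the root; all must agree within `tol`), and caches the implied
#' calendar time of every node.
#'
#' @param genealogy a [DatedGenealogy-class] (dated or not).
#' @param dates named numeric vector of calendar dates; every tip label of
#'   the tree must appear.
#' @param tol absolute path-consistency tolerance in time units.
#' @return The dated [DatedGenealogy-class].
#' @examples
#' g <- parseNewick("(A:1.5,B:0.5);")
#' g <- assignTipDates(g, c(A = 2004, B = 2003))
#' @export
assignTipDates <- function(genealogy, dates, tol = 1e-6) {
  tr <- genealogy@tree
  labs <- tr$tip.label
  missing <- setdiff(labs, names(dates))
  if (length(missing))
    stop("missing tip date for: ", paste(missing, collapse = ", "))
  dates <- dates[labs]
  ntip <- length(labs)
  depth <- ape::node.depth.edgelength(tr)  # distance from the root
  rootCal <- dates - depth[seq_len(ntip)]
  spread <- max(rootCal) - min(rootCal)
  if (spread > tol)
    stop(sprintf(paste0("tip dates inconsistent with branch lengths: ",
                        "root-to-tip paths imply root calendar times ",
                        "differing by %.6g (tolerance %g)"), spread, tol))
  root0 <- mean(rootCal)
  nodeCal <- root0 + depth
  nodeCal[seq_len(ntip)] <- dates  # tips exactly at their stated dates
  new("DatedGenealogy", tree = tr, tipDates = dates,
      mostRecentTipDate = max(dates), nodeCalendarTimes = nodeCal)
}

#' Convert a dated genealogy to a backwards-time event sequence
#'
#' Event times are measured backwards from `globalReference` (0 = reference,
#' increasing into the past), which must not precede any tip date. Ties are
#' broken with sampling events before coalescent events.
#'
#' @param genealogy a dated [DatedGenealogy-class].
#' @param globalReference calendar time of the origin of the shared
#'   backwards timeline; defaults to this genealogy's most recent tip.
#' @return An [EventSequence-class].
#' @examples
#' g <- assignTipDates(parseNewick("(A:1.5,B:0.5);"), c(A = 2004, B = 2003))
#' extractEventSequence(g)  # sampling at 0 and 1, coalescence at 1.5
#' @export
extractEventSequence <- function(genealogy,
                                 globalReference = genealogy@mostRecentTipDate) {
  if (!length(genealogy@nodeCalendarTimes) || anyNA(genealogy@tipDates))
    stop("genealogy is undated; call assignTipDates() first")
  if (globalReference < genealogy@mostRecentTipDate - 1e-9)
    stop("globalReference precedes a tip date")
  tr <- genealogy@tree
  ntip <- length(tr$tip.label)
  nodeCal <- genealogy@nodeCalendarTimes
  sampTimes <- unname(globalReference - genealogy@tipDates)
  coalTimes <- globalReference - nodeCal[(ntip + 1L):length(nodeCal)]
  times <- c(sampTimes, coalTimes)
  kinds <- c(rep("sampling", ntip), rep("coalescent", length(coalTimes)))
  ord <- order(times, kinds != "sampling")  # sampling first on exact ties
  offset <- globalReference - genealogy@mostRecentTipDate
  times <- times[ord]
  times[1] <- offset  # exact, avoids 1e-16 wobble in the validity check
  new("EventSequence", times = times, kinds = kinds[ord],
      offset = offset, nTips = as.integer(ntip))
}
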