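# Sliding-window chi-square differential enrichment of pulldown versus
# input fragment counts, run at a sweep of window sizes and compiled.
# Fragments are used as given (fragment size 0: no extension or
# shifting); a fragment is assigned to a window when its midpoint falls
# inside.

#' Sliding-window fragment midpoint counts
#'
#' Windows are `[s, s + window - 1]` for starts `s = 1, 1 + step, ...`
#' while the window lies fully inside the chromosome; a chromosome
#' shorter than the window yields zero windows. A fragment is counted in
#' every window containing its midpoint (`start + floor(width/2)` in
#' 1-based coordinates).
#'
#' @param fragments a `GRanges` of fragments (any chromosome; only
#'   `chrom` is used).
#' @param chrom chromosome name.
#' @param chromLength chromosome length in bp.
#' @param windowSize window width in bp.
#' @param step step between window starts in bp (`0 < step <= windowSize`).
#' @return a `data.frame` with columns `start`, `end` (1-based closed)
#'   and `count`.
#' @export
windowCounts <- function(fragments, chrom, chromLength, windowSize, step) {
  stopifnot(step > 0, step <= windowSize)
  if (chromLength < windowSize)
    return(data.frame(start = integer(), end = integer(),
                      count = integer()))
  starts <- seq.int(1L, chromLength - windowSize + 1L, by = step)
  frag <- fragments[as.character(seqnames(fragments)) == chrom]
  mids <- sort(start(frag) + width(frag) %/% 2L)
  count <- findInterval(starts + windowSize - 1L, mids) -
    findInterval(starts - 1L, mids)
  data.frame(start = starts, end = starts + windowSize - 1L, count = count)
}

#' Pearson chi-square test of a 2x2 contingency table
#'
#' Without continuity correction; the p-value is from the chi-square
#' distribution with 1 degree of freedom. The table used by the caller
#' is `[[window pulldown, window input], [library total minus window
#' pulldown, same for input]]`. A zero margin yields statistic 0 and
#' p = 1 by convention, with a warning.
#'
#' @param a,b,c,d the four cell counts (row-wise).
#' @return a list with elements `statistic` and `p`.
#' @examples
#' chiSquare2x2(30, 10, 10, 30)  # statistic 20
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  if (m == 0) {
    warning("zero margin in 2x2 table; p = 1 by convention")
    return(list(statistic = 0, p = 1))
  }
  stat <- n * (a * d - b * c)^2 / m
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Vectorized chi-square over parallel count vectors; zero-margin entries
# get statistic 0 / p 1 silently (the scalar interface warns).
.chisqVec <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(m == 0, 0, n * (a * d - b * c)^2 / m)
  list(statistic = stat,
       p = ifelse(m == 0, 1, stats::pchisq(stat, 1, lower.tail = FALSE)))
}

#' Call differentially enriched candidate regions at one window size
#'
#' For every sliding window, pulldown and input midpoint counts are
#' compared against the library-size margins by Pearson chi-square.
#' Windows with `p < pThreshold` and pulldown-over-input direction
#' (window pulldown fraction exceeding window input fraction) are kept,
#' and overlapping/adjacent significant windows are merged into one
#' region that records recomputed counts and the minimal window p.
#'
#' @param pulldown,input `GRanges` of fragments for the two samples.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param windowSize window width in bp.
#' @param step step in bp (default `windowSize/4`).
#' @param pThreshold per-window p-value threshold (default 1e-4;
#'   deliberately permissive, the KS validation stage is the guard
#'   against false positives).
#' @return a `GRanges` of candidate regions with metadata columns
#'   `pulldownCount`, `inputCount`, `chisq`, `pvalue` and `windowSize`.
#' @export
callCandidates <- function(pulldown, input, seqlengths, windowSize,
                           step = max(1L, windowSize %/% 4L),
                           pThreshold = 1e-4) {
  if (!length(pulldown) || !length(input))
    stop("both samples must contain fragments")
  totP <- length(pulldown)
  totI <- length(input)
  res <- lapply(names(seqlengths), function(chrom) {
    wp <- windowCounts(pulldown, chrom, seqlengths[[chrom]], windowSize,
                       step)
    if (!nrow(wp)) return(NULL)
    wi <- windowCounts(input, chrom, seqlengths[[chrom]], windowSize, step)
    a <- wp$count; b <- wi$count
    cs <- .chisqVec(a, b, totP - a, totI - b)
    sig <- cs$p < pThreshold & (a / totP) > (b / totI)
    if (!any(sig)) return(NULL)
    win <- GRanges(chrom, IRanges(wp$start[sig], wp$end[sig]),
                   pvalue = cs$p[sig], chisq = cs$statistic[sig])
    merged <- GenomicRanges::reduce(win)
    hit <- findOverlaps(merged, win)
    minP <- tapply(mcols(win)$pvalue[subjectHits(hit)], queryHits(hit), min)
    maxChi <- tapply(mcols(win)$chisq[subjectHits(hit)], queryHits(hit),
                     max)
    mcols(merged)$pvalue <- as.numeric(minP)
    mcols(merged)$chisq <- as.numeric(maxChi)
    merged
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- GRanges()
    mcols(out) <- DataFrame(pulldownCount = integer(),
                            inputCount = integer(), chisq = numeric(),
                            pvalue = numeric(), windowSize = integer())
    return(out)
  }
  out <- sort(do.call(c, res))
  mcols(out)$pulldownCount <- .midpointCount(pulldown, out)
  mcols(out)$inputCount <- .midpointCount(input, out)
  mcols(out)$windowSize <- windowSize
  out[, c("pulldownCount", "inputCount", "chisq", "pvalue", "windowSize")]
}

# Fragments whose midpoint falls inside each region.
.midpointCount <- function(fragments, regions) {
  mids <- GRanges(as.character(seqnames(fragments)),
                  IRanges(start(fragments) + width(fragments) %/% 2L,
                          width = 1L))
  countOverlaps(regions, mids)
}

#' Compile candidate regions from a window-size sweep
#'
#' Takes the union of the per-size candidate lists; overlapping regions
#' are merged and the provenance column lists every contributing window
#' size. The minimal p across contributors is retained, and counts are
#' recomputed over the merged intervals when fragments are supplied.
#'
#' @param candidateLists list of `GRanges`, one per window size, as
#'   returned by [callCandidates()].
#' @param pulldown,input optional fragment `GRanges` used to recompute
#'   midpoint counts over the merged regions.
#' @return a sorted `GRanges` with metadata columns `pulldownCount`,
#'   `inputCount`, `pvalue` and `windowSizes` (an `IntegerList`).
#' @export
compileWindowSweep <- function(candidateLists, pulldown = NULL,
                               input = NULL) {
  candidateLists <- candidateLists[lengths(candidateLists) > 0L]
  if (!length(candidateLists)) {
    out <- GRanges()
    mcols(out) <- DataFrame(pulldownCount = integer(),
                            inputCount = integer(), pvalue = numeric(),
                            windowSizes = IRanges::IntegerList())
    return(out)
  }
  all <- do.call(c, lapply(candidateLists, function(g)
    g[, c("pvalue", "windowSize")]))
  merged <- GenomicRanges::reduce(sort(all))
  hit <- findOverlaps(merged, all)
  grp <- factor(queryHits(hit), levels = seq_along(merged))
  mcols(merged)$pvalue <- as.numeric(
    tapply(mcols(all)$pvalue[subjectHits(hit)], grp, min))
  mcols(merged)$windowSizes <- IRanges::IntegerList(
    tapply(mcols(all)$windowSize[subjectHits(hit)], grp,
           function(w) sort(unique(w)), simplify = FALSE))
  if (!is.null(pulldown)) {
    mcols(merged)$pulldownCount <- .midpointCount(pulldown, merged)
  }
  if (!is.null(input)) {
    mcols(merged)$inputCount <- .midpointCount(input, merged)
  }
  merged
}

#' Call and compile candidate regions across the standard window sweep
#'
#' Convenience wrapper running [callCandidates()] at each window size and
#' [compileWindowSweep()] on the results. The default sweep is 400 to
#' 1200 bp.
#'
#' @inheritParams callCandidates
#' @param windowSizes integer vector of window widths (default
#'   `c(400, 600, 800, 1000, 1200)`).
#' @param stepFraction step as a fraction of the window size (default
#'   1/4).
#' @return the compiled candidate `GRanges` (see [compileWindowSweep()]).
#' @export
callCandidateRegions <- function(pulldown, input, seqlengths,
                                 windowSizes = c(400L, 600L, 800L, 1000L,
                                                 1200L),
                                 stepFraction = 0.25,
                                 pThreshold = 1e-4) {
  lists <- lapply(windowSizes, function(w) {
    callCandidates(pulldown, input, seqlengths, w,
                   step = max(1L, as.integer(w * stepFraction)),
                   pThreshold = pThreshold)
  })
  compileWindowSweep(lists, pulldown = pulldown, input = input)
}
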