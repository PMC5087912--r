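# Statistical validation of candidate motif sites: unity-normalized
# differential coverage at each candidate versus sampled null motif
# positions, compared by two-sample Kolmogorov-Smirnov tests with
# Benjamini-Hochberg correction and a 99.9th-percentile decision rule.

#' Unity (sum-to-one) normalization of a coverage vector
#'
#' Divides per-base coverage by its total so regions of different depth
#' are comparable as mass profiles. An all-zero vector signals a
#' zero-coverage region via a condition of class `"zeroCoverage"`;
#' callers drop such regions with a warning.
#'
#' @param x numeric vector of per-base coverage (non-negative).
#' @return `x / sum(x)`, summing to 1.
#' @export
unityNormalize <- function(x) {
  if (!length(x)) stop("empty coverage vector")
  if (any(x < 0)) stop("coverage must be non-negative")
  s <- sum(x)
  if (s == 0)
    stop(structure(class = c("zeroCoverage", "error", "condition"),
                   list(message = "zero-coverage region", call = NULL)))
  x / s
}

#' Differential coverage distribution over one window
#'
#' Elementwise difference of the unity-normalized pulldown and input
#' coverage; always sums to zero.
#'
#' @param pulldownCov,inputCov numeric per-base coverage vectors of equal
#'   length.
#' @return numeric vector `unityNormalize(pulldownCov) -
#'   unityNormalize(inputCov)`.
#' @export
differentialDistribution <- function(pulldownCov, inputCov) {
  if (length(pulldownCov) != length(inputCov))
    stop("coverage vectors must have equal length")
  unityNormalize(pulldownCov) - unityNormalize(inputCov)
}

#' Sample null foreground and background motif positions
#'
#' The null pool is the hypothetical (motif-matching) position list with
#' every position overlapping a candidate site removed entirely. Two
#' disjoint samples of `n` positions each are drawn without replacement,
#' reproducibly under the seed.
#'
#' @param hypotheticalSites `GRanges` of all motif positions (e.g. from
#'   [catalogSites()]).
#' @param candidateSites `GRanges` of candidate sites to exclude.
#' @param n sample size for each of the two sets.
#' @param seed integer seed.
#' @return a list with `GRanges` elements `foreground` and `background`.
#' @export
sampleNullRegions <- function(hypotheticalSites, candidateSites, n, seed) {
  pool <- hypotheticalSites
  if (length(candidateSites))
    pool <- pool[countOverlaps(pool, candidateSites) == 0L]
  if (length(pool) < 2L * n)
    stop("null pool too small: ", length(pool), " non-candidate sites, ",
         2L * n, " needed")
  idx <- withSeed(seed, sample(length(pool), 2L * n))
  list(foreground = pool[idx[seq_len(n)]],
       background = pool[idx[n + seq_len(n)]])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two
#' empirical CDFs; the p-value is from the asymptotic two-sample KS
#' distribution.
#'
#' @param x,y numeric vectors.
#' @return a list with elements `D` and `p`.
#' @examples
#' ksTwoSample(c(1, 3, 5, 7), c(2, 4, 6, 8))  # D = 0.25
#' @export
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Decide significance of one candidate differential distribution
#'
#' Performs one KS test of the candidate differential against each null
#' differential distribution, BH-adjusts the p-values within this
#' candidate's family, and takes the nearest-rank percentile (default
#' 99.9th) of the adjusted values as the decision p. Classes:
#' `"significant"` when `p < alpha`, `"marginal"` when
#' `alpha <= p < marginalUpper`, else `"nonsignificant"`.
#'
#' @param candidateDiff numeric differential distribution of the
#'   candidate window.
#' @param nullDiffs list of numeric null differential distributions.
#' @param config a [SiteValidationConfig-class].
#' @return a list with elements `p` (decision p-value) and `class`.
#' @export
decideSite <- function(candidateDiff, nullDiffs,
                       config = siteValidationConfig()) {
  if (!length(nullDiffs)) stop("at least one null distribution required")
  pvals <- vapply(nullDiffs,
                  function(nd) ksTwoSample(candidateDiff, nd)$p, 0)
  adj <- sort(bhAdjust(pvals))
  # nearest-rank: ceil(P/100 * n), rounded first so that exact products
  # (e.g. 99.9% of 1000 = 999) are not pushed up by floating point
  rank <- max(1L, as.integer(
    ceiling(round(config@percentile / 100 * length(adj), 9L))))
  p <- adj[[rank]]
  class <- if (p < config@alpha) "significant"
    else if (p < config@marginalUpper) "marginal"
    else "nonsignificant"
  list(p = p, class = class)
}

#' Log2 fold enrichment over a decision window
#'
#' The log2 ratio of the maximum per-base pulldown coverage to the
#' maximum input coverage within the window. When either maximum is
#' zero, both maxima are incremented by a pseudocount of 1 before the
#' ratio.
#'
#' @param pulldownCov,inputCov numeric per-base coverage vectors of equal
#'   length.
#' @return log2 fold enrichment (finite).
#' @export
foldEnrichment <- function(pulldownCov, inputCov) {
  if (length(pulldownCov) != length(inputCov))
    stop("coverage vectors must have equal length")
  mp <- max(pulldownCov)
  mi <- max(inputCov)
  if (mp == 0 || mi == 0) {
    mp <- mp + 1
    mi <- mi + 1
  }
  log2(mp / mi)
}

# Extract the per-base coverage vector of a window from an RleList,
# clamped to chromosome bounds.
.covWindow <- function(cov, chrom, start, end) {
  r <- cov[[chrom]]
  as.numeric(S4Vectors::window(r, max(1L, start), min(length(r), end)))
}

# Decision window centered on a site: center +/- halfWidth.
.decisionWindow <- function(sites, halfWidth) {
  center <- start(sites) + width(sites) %/% 2L
  GRanges(as.character(seqnames(sites)),
          IRanges(center - halfWidth, center + halfWidth))
}

#' Validate candidate regions into binding sites
#'
#' The full validation stage: motif matches inside each candidate region
#' (on variant-reconstructed sequence when variants are supplied,
#' back-mapped to reference coordinates) become candidate sites,
#' deduplicated by interval. An equal number of null foreground and
#' background positions is sampled from the non-candidate motif
#' positions; null differential distributions pair shuffled null
#' foreground pulldown windows with background input windows. Each
#' candidate's differential distribution is KS-tested against every null
#' differential, BH-adjusted, and classified by the nearest-rank
#' percentile rule; fold enrichment is computed over the same decision
#' window.
#'
#' @param candidates `GRanges` of candidate regions (from
#'   [callCandidateRegions()]).
#' @param motif IUPAC motif string.
#' @param genome named `DNAStringSet`.
#' @param pulldownCov,inputCov `RleList` coverage tracks (from
#'   [fragmentCoverage()] or [readBedGraph()]).
#' @param config a [SiteValidationConfig-class].
#' @param variants optional variant `data.frame` (see
#'   [readMinimalVcf()]) used to reconstruct candidate-region sequence
#'   before motif matching.
#' @param hypotheticalSites optional precomputed [catalogSites()] result
#'   (computed from the genome otherwise).
#' @return a `GRanges` of candidate sites with metadata columns
#'   `orientation`, `indelSpanning`, `foldLog2`, `decisionP` and `class`.
#'   Sites in zero-coverage windows are dropped with a warning.
#' @export
validateSites <- function(candidates, motif, genome, pulldownCov, inputCov,
                          config = siteValidationConfig(),
                          variants = NULL, hypotheticalSites = NULL) {
  empty <- GRanges()
  mcols(empty) <- DataFrame(orientation = character(),
                            indelSpanning = logical(),
                            foldLog2 = numeric(), decisionP = numeric(),
                            class = character())
  if (!length(candidates)) return(empty)
  k <- nchar(motif)
  # motif matching inside candidate regions, on reconstructed sequence
  siteList <- lapply(seq_along(candidates), function(i) {
    region <- candidates[i]
    rr <- applyVariants(genome, region, variants)
    m <- matchMotif(reconstructedSeq(rr), motif)
    if (!nrow(m)) return(NULL)
    sites <- do.call(c, lapply(seq_len(nrow(m)), function(j)
      backmapMatch(m$start[j], k, rr)))
    mcols(sites)$orientation <- m$orientation
    sites
  })
  siteList <- siteList[!vapply(siteList, is.null, logical(1))]
  if (!length(siteList)) return(empty)
  sites <- do.call(c, siteList)
  key <- paste(seqnames(sites), start(sites), end(sites))
  sites <- sort(sites[!duplicated(key)])
  # null sampling from the motif catalog
  if (is.null(hypotheticalSites))
    hypotheticalSites <- catalogSites(genome, motif)
  n <- length(sites)
  nulls <- sampleNullRegions(hypotheticalSites, sites, n, config@seed)
  # null differentials: shuffled pairing of foreground pulldown windows
  # with background input windows
  fgWin <- .decisionWindow(nulls$foreground, config@halfWidth)
  bgWin <- .decisionWindow(nulls$background, config@halfWidth)
  perm <- withSeed(config@seed + 1L, sample(n))
  nullDiffs <- vector("list", n)
  for (i in seq_len(n)) {
    fw <- fgWin[perm[i]]
    bw <- bgWin[i]
    nullDiffs[[i]] <- tryCatch({
      pc <- .covWindow(pulldownCov, as.character(seqnames(fw)), start(fw),
                       end(fw))
      ic <- .covWindow(inputCov, as.character(seqnames(bw)), start(bw),
                       end(bw))
      len <- min(length(pc), length(ic))
      unityNormalize(pc[seq_len(len)]) - unityNormalize(ic[seq_len(len)])
    }, zeroCoverage = function(e) NULL)
  }
  nullDiffs <- nullDiffs[!vapply(nullDiffs, is.null, logical(1))]
  if (!length(nullDiffs))
    stop("all null windows have zero coverage; tracks too sparse")
  # per-candidate decision and fold enrichment
  win <- .decisionWindow(sites, config@halfWidth)
  keep <- rep(TRUE, n)
  decP <- numeric(n); cls <- character(n); fold <- numeric(n)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(win[i]))
    pc <- .covWindow(pulldownCov, chrom, start(win[i]), end(win[i]))
    ic <- .covWindow(inputCov, chrom, start(win[i]), end(win[i]))
    d <- tryCatch(unityNormalize(pc) - unityNormalize(ic),
                  zeroCoverage = function(e) NULL)
    if (is.null(d)) {
      keep[i] <- FALSE
      next
    }
    dec <- decideSite(d, nullDiffs, config)
    decP[i] <- dec$p; cls[i] <- dec$class
    fold[i] <- foldEnrichment(pc, ic)
  }
  if (!all(keep))
    warning(sum(!keep), " candidate site(s) dropped (zero-coverage window)")
  out <- sites[keep]
  mcols(out)$indelSpanning <- mcols(out)$indelSpanning %||%
    rep(FALSE, length(out))
  mcols(out)$foldLog2 <- fold[keep]
  mcols(out)$decisionP <- decP[keep]
  mcols(out)$class <- cls[keep]
  out
}

#' Write validated sites as TSV
#'
#' Columns: chrom, start (0-based), end, orientation, fold_log2,
#' decision_p, class.
#'
#' @param sites `GRanges` from [validateSites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesTsv <- function(sites, path) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   start = start(sites) - 1L,
                   end = end(sites),
                   orientation = mcols(sites)$orientation,
                   fold_log2 = mcols(sites)$foldLog2,
                   decision_p = mcols(sites)$decisionP,
                   class = mcols(sites)$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
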