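# Gene/promoter annotation of sites, closest-feature distances,
# consensus heterochromatin, DHS position profiling and chromatin odds
# ratios. Overlap threshold everywhere is >= 1 bp.

#' Promoter regions of transcripts
#'
#' The promoter is the 1000 bp immediately upstream of the transcription
#' start site on the annotated strand, clamped at chromosome bounds.
#'
#' @param tx a `GRanges` of transcripts (strand `+` or `-`), as from
#'   [readRefFlat()].
#' @param upstream promoter width in bp (default 1000).
#' @param seqlengths optional named chromosome lengths used to clamp
#'   minus-strand promoters at chromosome ends.
#' @return a `GRanges` of promoters carrying the transcripts' metadata
#'   columns (`gene` etc.); zero-width promoters (TSS at a chromosome
#'   edge) are retained with width 0 dropped to the empty range.
#' @export
promoterRegions <- function(tx, upstream = 1000L, seqlengths = NULL) {
  plus <- as.character(strand(tx)) == "+"
  pstart <- ifelse(plus, start(tx) - upstream, end(tx) + 1L)
  pend <- ifelse(plus, start(tx) - 1L, end(tx) + upstream)
  pstart <- pmax(pstart, 1L)
  if (!is.null(seqlengths)) {
    lens <- seqlengths[as.character(seqnames(tx))]
    pend <- pmin(pend, lens)
  }
  keep <- pstart <= pend
  out <- GRanges(as.character(seqnames(tx))[keep],
                 IRanges(pstart[keep], pend[keep]),
                 strand = strand(tx)[keep])
  mcols(out) <- mcols(tx)[keep, , drop = FALSE]
  out
}

#' Annotate sites with overlapping transcripts and promoters
#'
#' Each site is labeled with every transcript it overlaps by at least 1
#' bp and every promoter it overlaps; sites overlapping neither are
#' intergenic. A site may carry several gene labels, and may be both
#' intragenic (gene A) and promoter (gene B).
#'
#' @param sites a `GRanges` of sites.
#' @param tx a `GRanges` of transcripts with metadata column `gene`.
#' @param upstream promoter width passed to [promoterRegions()].
#' @param seqlengths optional chromosome lengths for promoter clamping.
#' @return `sites` with added metadata columns `genes` and
#'   `promoterGenes` (semicolon-joined, `""` when none) and `annotation`
#'   (`"transcript"`, `"promoter"`, `"transcript;promoter"` or
#'   `"intergenic"`). `metadata(x)$annotationSummary` counts sites in
#'   transcripts, in promoters, and intergenic.
#' @export
annotateSites <- function(sites, tx, upstream = 1000L, seqlengths = NULL) {
  joinLabels <- function(subject, labels) {
    out <- character(length(sites))
    if (length(subject)) {
      hit <- findOverlaps(sites, subject)
      lab <- tapply(labels[subjectHits(hit)], queryHits(hit),
                    function(g) paste(sort(unique(g)), collapse = ";"))
      out[as.integer(names(lab))] <- as.character(lab)
    }
    out
  }
  genes <- joinLabels(tx, mcols(tx)$gene)
  prom <- promoterRegions(tx, upstream, seqlengths)
  promGenes <- joinLabels(prom, mcols(prom)$gene)
  ann <- ifelse(nzchar(genes) & nzchar(promGenes), "transcript;promoter",
         ifelse(nzchar(genes), "transcript",
         ifelse(nzchar(promGenes), "promoter", "intergenic")))
  mcols(sites)$genes <- genes
  mcols(sites)$promoterGenes <- promGenes
  mcols(sites)$annotation <- ann
  metadata(sites)$annotationSummary <- c(
    inTranscript = sum(nzchar(genes)),
    inPromoter = sum(nzchar(promGenes)),
    intergenic = sum(ann == "intergenic"))
  sites
}

#' Distance from each site to its closest feature
#'
#' Zero when overlapping; otherwise the gap in bases between the nearest
#' edges. Ties between an upstream and a downstream feature at the same
#' gap are broken toward the smaller coordinate. Sites on chromosomes
#' with no features are flagged missing.
#'
#' @param sites a `GRanges`.
#' @param track a `GRanges` of features.
#' @return a `data.frame` with columns `distance` (NA when missing),
#'   `featureIndex` (index into `track`) and `missing`.
#' @export
closestFeatureDistance <- function(sites, track) {
  n <- length(sites)
  dist <- rep(NA_real_, n)
  fidx <- rep(NA_integer_, n)
  track <- sort(track)
  # disjoint seqlevels are expected (sites on feature-free chromosomes
  # are reported as missing), so the Seqinfo merge chatter is silenced
  ov <- suppressWarnings(findOverlaps(sites, track))
  if (length(ov)) {
    first <- !duplicated(queryHits(ov))
    dist[queryHits(ov)[first]] <- 0
    fidx[queryHits(ov)[first]] <- subjectHits(ov)[first]
  }
  todo <- which(is.na(dist))
  if (length(todo)) {
    s <- sites[todo]
    left <- suppressWarnings(follow(s, track))   # feature ending before
    right <- suppressWarnings(precede(s, track)) # feature starting after
    dLeft <- ifelse(is.na(left), Inf,
                    start(s) - end(track)[ifelse(is.na(left), 1L, left)] -
                      1L)
    dRight <- ifelse(is.na(right), Inf,
                     start(track)[ifelse(is.na(right), 1L, right)] -
                       end(s) - 1L)
    pickLeft <- dLeft <= dRight  # tie goes to the smaller coordinate
    d <- pmin(dLeft, dRight)
    ok <- is.finite(d)
    dist[todo[ok]] <- d[ok]
    fidx[todo[ok]] <- ifelse(pickLeft[ok], left[ok], right[ok])
  }
  data.frame(distance = dist, featureIndex = fidx, missing = is.na(dist))
}

#' Consensus feature track across replicate tracks
#'
#' Maximal intervals where the per-base number of supporting tracks is at
#' least `k` (each track contributing at most once per base).
#'
#' @param tracks list of `GRanges` (e.g. per-cell-line heterochromatin
#'   segmentations; the flagship use is 8 tracks with `k = 5`).
#' @param k minimum per-base support (default 5).
#' @param seqlengths optional named chromosome lengths; inferred from
#'   the tracks' maximal ends otherwise.
#' @return a `GRanges` of consensus intervals.
#' @export
consensusTrack <- function(tracks, k = 5L, seqlengths = NULL) {
  if (length(tracks) < k)
    stop("fewer tracks (", length(tracks), ") than threshold k = ", k)
  if (is.null(seqlengths)) {
    all <- do.call(c, lapply(tracks, function(g)
      GRanges(as.character(seqnames(g)), ranges(g))))
    seqlengths <- vapply(split(end(all), as.character(seqnames(all))), max,
                         0L)
  }
  covs <- lapply(tracks, function(g) {
    g <- GenomicRanges::reduce(GRanges(as.character(seqnames(g)),
                                       ranges(g)))
    GenomeInfoDb::seqlevels(g) <- names(seqlengths)
    GenomeInfoDb::seqlengths(g) <- seqlengths
    GenomicRanges::coverage(g)
  })
  support <- Reduce(`+`, covs)
  hits <- slice(support, lower = k, rangesOnly = TRUE)
  GRanges(hits)
}

#' DHS position-coverage profile and per-site open-chromatin flags
#'
#' Splits each chromosome into fixed bins (default 10 kb; the final
#' incomplete bin is kept and normalized by its true width) and reports
#' the percent of bases covered by the feature track per bin, plus an
#' inside/outside flag for every site (>= 1 bp overlap).
#'
#' @param sites a `GRanges` of sites.
#' @param track a `GRanges` feature track (e.g. DHS clusters).
#' @param seqlengths named chromosome lengths.
#' @param bin bin width in bp (default 10000).
#' @return a list with `bins` (a `GRanges` with metadata column
#'   `percent`) and `siteInside` (logical vector parallel to `sites`).
#' @export
dhsPositionProfile <- function(sites, track, seqlengths, bin = 10000L) {
  track <- GenomicRanges::reduce(GRanges(as.character(seqnames(track)),
                                         ranges(track)))
  GenomeInfoDb::seqlevels(track) <- names(seqlengths)
  GenomeInfoDb::seqlengths(track) <- seqlengths
  cov <- GenomicRanges::coverage(track)
  bins <- do.call(c, lapply(names(seqlengths), function(chrom) {
    starts <- seq.int(1L, seqlengths[[chrom]], by = bin)
    GRanges(chrom, IRanges(starts, pmin(starts + bin - 1L,
                                        seqlengths[[chrom]])))
  }))
  pct <- vapply(seq_along(bins), function(i) {
    chrom <- as.character(seqnames(bins[i]))
    100 * sum(.covWindow(cov, chrom, start(bins[i]), end(bins[i]))) /
      width(bins[i])
  }, 0)
  mcols(bins)$percent <- pct
  list(bins = bins,
       siteInside = countOverlaps(sites, track) > 0L)
}

#' Chromatin odds of sites relative to a feature track
#'
#' The count of sites on the numerator side of the track divided by the
#' count on the denominator side: `"within_over_outside"` divides sites
#' overlapping the track (>= 1 bp) by sites not overlapping it;
#' `"outside_over_within"` is the reciprocal orientation.
#'
#' @param sites a `GRanges`.
#' @param track a `GRanges` feature track.
#' @param mode `"within_over_outside"` or `"outside_over_within"`.
#' @return the odds ratio (numeric).
#' @export
chromatinOdds <- function(sites,
                          track,
                          mode = c("within_over_outside",
                                   "outside_over_within")) {
  mode <- match.arg(mode)
  inside <- sum(countOverlaps(sites, track) > 0L)
  outside <- length(sites) - inside
  num <- if (mode == "within_over_outside") inside else outside
  den <- if (mode == "within_over_outside") outside else inside
  if (den == 0) stop("zero denominator: no sites on the ",
                     if (mode == "within_over_outside") "outside" else
                       "inside", " side")
  num / den
}
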