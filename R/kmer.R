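# 9-mer composition comparison: extract motif sites overlapping a
# feature track with 1000-bp flanks and compare k-mer content against a
# reference transcript.

#' Extract feature-overlapping sites with flanks
#'
#' Sites overlapping the track by at least 1 bp are retained and
#' expanded by `flank` bases on each side (2009 bp for an interior 9-bp
#' site), clamped at chromosome bounds with a flag.
#'
#' @param sites a `GRanges` of motif sites.
#' @param track a `GRanges` feature track (e.g. lncRNA annotations).
#' @param genome a named `DNAStringSet`.
#' @param flank flank width in bp (default 1000).
#' @return a `DNAStringSet` of region sequences named
#'   `chrom:start-end`; `metadata` is not carried, but
#'   `attr(x, "regions")` holds the `GRanges` with metadata column
#'   `clamped`.
#' @export
extractFlankedRegions <- function(sites, track, genome, flank = 1000L) {
  keep <- countOverlaps(sites, track) > 0L
  sites <- sites[keep]
  if (!length(sites)) {
    out <- DNAStringSet()
    attr(out, "regions") <- GRanges()
    return(out)
  }
  lens <- genomeSeqlengths(genome)[as.character(seqnames(sites))]
  newStart <- start(sites) - flank
  newEnd <- end(sites) + flank
  clamped <- newStart < 1L | newEnd > lens
  regions <- GRanges(as.character(seqnames(sites)),
                     IRanges(pmax(newStart, 1L), pmin(newEnd, lens)))
  mcols(regions)$clamped <- clamped
  seqs <- genomeSubseq(genome, regions)
  out <- DNAStringSet(seqs)
  names(out) <- sprintf("%s:%d-%d", as.character(seqnames(regions)),
                        start(regions) - 1L, end(regions))
  attr(out, "regions") <- regions
  out
}

#' Count k-mers over a set of sequences
#'
#' Sliding-window counts on the given strand only (no canonical
#' collapsing); windows containing N are skipped.
#'
#' @param sequences a `DNAStringSet` or character vector.
#' @param k k-mer length (default 9).
#' @return a [KmerProfile-class].
#' @export
countKmers <- function(sequences, k = 9L) {
  if (k < 1L) stop("k must be >= 1")
  seqs <- if (is(sequences, "DNAStringSet")) sequences else
    DNAStringSet(toupper(as.character(sequences)))
  if (!length(seqs) || all(Biostrings::width(seqs) < k)) {
    return(new("KmerProfile", k = as.integer(k),
               counts = stats::setNames(integer(), character()),
               total = 0))
  }
  counts <- oligonucleotideFrequency(seqs, width = k,
                                     simplify.as = "collapsed")
  counts <- counts[counts > 0]
  new("KmerProfile", k = as.integer(k),
      counts = stats::setNames(as.integer(counts), names(counts)),
      total = sum(as.numeric(counts)))
}

#' Shared k-mer similarity between two profiles
#'
#' Statistics over the distinct k-mer sets of two profiles: the number
#' of shared distinct k-mers, the Jaccard index, and the fraction of the
#' first profile's distinct k-mers present in the second.
#'
#' @param profileA,profileB [KmerProfile-class] objects with equal k.
#' @return a list with elements `shared`, `jaccard` and `fractionAinB`.
#' @export
sharedKmerSimilarity <- function(profileA, profileB) {
  if (kmerSize(profileA) != kmerSize(profileB))
    stop("profiles have different k (", kmerSize(profileA), " vs ",
         kmerSize(profileB), ")")
  a <- names(kmerCounts(profileA))
  b <- names(kmerCounts(profileB))
  shared <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(shared = shared,
       jaccard = if (uni > 0) shared / uni else NA_real_,
       fractionAinB = if (length(a) > 0) shared / length(a) else NA_real_)
}
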