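# Degenerate motif matching and motif-audit statistics. The flagship
# motif is the 9-bp polyamide recognition sequence TGWWGGCGW (W = A or T);
# matching is exact-degenerate on both strands, and N never matches.

#' Match a degenerate motif on both strands of a sequence
#'
#' Reports every offset where the motif, or its reverse complement,
#' matches exactly under IUPAC degeneracy. Overlapping matches are all
#' reported, and an offset matching in both orientations yields two
#' records. Windows containing N never match.
#'
#' @param sequence a DNA string (character or `DNAString`) over A/C/G/T/N.
#' @param motif IUPAC motif string (e.g. `"TGWWGGCGW"`).
#' @return a `data.frame` with columns `start` (1-based), `end` and
#'   `orientation` (`"forward"` or `"reverse"`), sorted by start then
#'   orientation.
#' @examples
#' matchMotif("TGATGGCGT", "TGWWGGCGW")
#' @export
matchMotif <- function(sequence, motif) {
  subject <- if (is(sequence, "DNAString")) sequence else
    DNAString(toupper(as.character(sequence)))
  pat <- DNAString(toupper(motif))
  k <- length(pat)
  if (length(subject) < k)
    return(data.frame(start = integer(), end = integer(),
                      orientation = character()))
  hit1 <- .matchOneStrand(subject, pat)
  hit2 <- .matchOneStrand(subject, reverseComplement(pat))
  out <- rbind(
    if (length(hit1)) data.frame(start = hit1, end = hit1 + k - 1L,
                                 orientation = "forward"),
    if (length(hit2)) data.frame(start = hit2, end = hit2 + k - 1L,
                                 orientation = "reverse"))
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      orientation = character()))
  out <- out[order(out$start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Biostrings ambiguity matching lets N in the subject satisfy degenerate
# pattern letters; the pipeline's contract is that masked (N) bases never
# match, so N-containing hits are filtered out.
.matchOneStrand <- function(subject, pat) {
  m <- matchPattern(pat, subject, fixed = FALSE)
  if (!length(m)) return(integer())
  hasN <- vapply(seq_along(m),
                 function(i) grepl("N", as.character(m[[i]]), fixed = TRUE),
                 logical(1))
  BiocGenerics::start(m)[!hasN]
}

#' Catalog every hypothetical motif position in a genome
#'
#' Concatenates [matchMotif()] over all chromosomes. Positions matched in
#' both orientations are distinct strand events; the deduplicated
#' position count (unique intervals) is also reported, and is the count
#' used by downstream site tallies.
#'
#' @param genome a named `DNAStringSet`.
#' @param motif IUPAC motif string.
#' @return a `GRanges` of unique motif positions sorted by (chrom, start),
#'   with metadata column `orientation` (`"forward"`, `"reverse"` or
#'   `"both"`). `metadata(x)$strandEvents` holds the per-strand event
#'   count before deduplication.
#' @export
catalogSites <- function(genome, motif) {
  hits <- lapply(names(genome), function(chrom) {
    df <- matchMotif(genome[[chrom]], motif)
    if (!nrow(df)) return(NULL)
    GRanges(chrom, IRanges(df$start, df$end), orientation = df$orientation)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    out <- GRanges()
    mcols(out)$orientation <- character()
    metadata(out)$strandEvents <- 0L
    return(out)
  }
  all <- sort(do.call(c, hits))
  key <- paste(seqnames(all), start(all))
  first <- !duplicated(key)
  ori <- tapply(mcols(all)$orientation, factor(key, levels = key[first]),
                function(o) if (length(unique(o)) > 1L) "both" else o[[1L]])
  out <- all[first]
  mcols(out)$orientation <- as.character(ori)
  metadata(out)$strandEvents <- length(all)
  out
}

#' Scramble a motif, keeping its 5' anchor fixed
#'
#' Emulates the alkylation-anchored motif audit: the first letter (the 5'
#' thymine whose adjacent adenine is alkylated) is kept, and the
#' remaining letters are uniformly permuted. Draws are independent, so
#' duplicate permutations can occur.
#'
#' @param motif IUPAC motif string of length >= 2.
#' @param n number of scrambled motifs (default 100).
#' @param seed integer seed; fixed seed gives identical output.
#' @return character vector of `n` scrambled motifs.
#' @export
scrambleMotifs <- function(motif, n = 100L, seed = 1L) {
  if (n <= 0L) stop("n must be >= 1")
  letters <- strsplit(toupper(motif), "")[[1L]]
  if (length(letters) < 2L) stop("motif must have length >= 2")
  withSeed(seed, {
    vapply(seq_len(n), function(i) {
      paste(c(letters[1L], sample(letters[-1L])), collapse = "")
    }, "")
  })
}

#' Genome and CDS site-count ratios for a set of motifs
#'
#' For each motif, counts its unique genome positions and the subset
#' overlapping coding sequence by at least 1 bp, then divides each count
#' by the reference motif's corresponding count. The percentile rank of
#' the reference within the supplied motif population is reported for
#' both metrics.
#'
#' @param genome a named `DNAStringSet`.
#' @param motifs character vector of motifs to audit.
#' @param referenceMotif the reference motif (denominator).
#' @param cds a `GRanges` of coding intervals.
#' @return a `data.frame` with one row per motif (columns `motif`,
#'   `genomeCount`, `cdsCount`, `genomeRatio`, `cdsRatio`);
#'   `attr(x, "referencePercentile")` gives the reference's percentile
#'   rank (fraction of audited motifs with count <= reference, in
#'   percent) for both metrics.
#' @export
motifSiteRatios <- function(genome, motifs, referenceMotif, cds) {
  countOne <- function(m) {
    sites <- catalogSites(genome, m)
    c(genome = length(sites),
      cds = if (length(sites)) sum(countOverlaps(sites, cds) > 0) else 0L)
  }
  ref <- countOne(referenceMotif)
  if (ref[["genome"]] == 0L)
    stop("reference motif absent from genome")
  counts <- t(vapply(motifs, countOne, c(genome = 0L, cds = 0L)))
  cdsDen <- ref[["cds"]]
  out <- data.frame(
    motif = motifs,
    genomeCount = counts[, "genome"],
    cdsCount = counts[, "cds"],
    genomeRatio = counts[, "genome"] / ref[["genome"]],
    cdsRatio = if (cdsDen > 0) counts[, "cds"] / cdsDen else
      rep(NA_real_, length(motifs)),
    row.names = NULL)
  attr(out, "referencePercentile") <- c(
    genome = 100 * mean(counts[, "genome"] <= ref[["genome"]]),
    cds = if (cdsDen > 0) 100 * mean(counts[, "cds"] <= cdsDen) else NA_real_)
  out
}
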