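#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAString DNAStringSet BStringSet readBStringSet
#'   writeXStringSet reverseComplement vmatchPattern matchPattern
#'   oligonucleotideFrequency subseq
NULL

#' Configuration for statistical validation of candidate binding sites
#'
#' Holds the tunable parameters of the Kolmogorov-Smirnov validation stage:
#' the significance level, the marginal band, the percentile used for the
#' per-site decision, the half-width of the decision window around a site,
#' and the seed governing null-site sampling and pairing.
#'
#' @slot alpha significance level for the decision p-value (default 0.05).
#' @slot marginalUpper upper bound of the marginally-significant band;
#'   sites with `alpha <= p < marginalUpper` are classed `"marginal"`.
#' @slot percentile percentile (in (0, 100]) of the BH-adjusted KS
#'   p-values used as the per-site decision p (default 99.9; nearest-rank).
#' @slot halfWidth half-width in bp of the coverage window centered on a
#'   site over which differential distributions are computed (default 500,
#'   i.e. a -500..+500 bp window).
#' @slot seed integer seed for null-region sampling and pair shuffling.
#'
#' @examples
#' siteValidationConfig(alpha = 0.05, seed = 7)
#' @export
setClass("SiteValidationConfig",
  representation(
    alpha = "numeric",
    marginalUpper = "numeric",
    percentile = "numeric",
    halfWidth = "integer",
    seed = "integer"
  )
)

setValidity("SiteValidationConfig", function(object) {
  msg <- character()
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!(object@marginalUpper > object@alpha && object@marginalUpper < 1))
    msg <- c(msg, "marginalUpper must satisfy alpha < marginalUpper < 1")
  if (!(object@percentile > 0 && object@percentile <= 100))
    msg <- c(msg, "percentile must be in (0, 100]")
  if (object@halfWidth < 1L)
    msg <- c(msg, "halfWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param alpha,marginalUpper,percentile,halfWidth,seed see slot docs.
#' @rdname SiteValidationConfig-class
#' @export
siteValidationConfig <- function(alpha = 0.05, marginalUpper = 0.055,
                                 percentile = 99.9, halfWidth = 500L,
                                 seed = 1L) {
  new("SiteValidationConfig", alpha = alpha, marginalUpper = marginalUpper,
      percentile = percentile, halfWidth = as.integer(halfWidth),
      seed = as.integer(seed))
}

setMethod("show", "SiteValidationConfig", function(object) {
  cat("SiteValidationConfig\n")
  cat(sprintf("  alpha: %g  (marginal band [%g, %g))\n",
              object@alpha, object@alpha, object@marginalUpper))
  cat(sprintf("  decision percentile: %g (nearest-rank)\n", object@percentile))
  cat(sprintf("  window half-width: %d bp\n", object@halfWidth))
  cat(sprintf("  seed: %d\n", object@seed))
})

#' A reference region whose sequence was rebuilt through sample variants
#'
#' The result of applying SNVs and indels to a reference interval: the
#' reconstructed sequence together with a monotone map from every
#' reconstructed offset back to a reference position. Deleted reference
#' bases map nowhere (they are absent from the reconstruction); inserted
#' bases map to the reference base preceding the insertion, so motif
#' matches on the reconstruction can be back-translated to reference
#' coordinates.
#'
#' @slot region the reference interval (`GRanges` of length 1).
#' @slot seq the reconstructed sequence (character, uppercase ACGTN).
#' @slot map integer vector, one entry per reconstructed base, giving the
#'   1-based reference position that base maps to; non-decreasing.
#'
#' @export
setClass("ReconstructedRegion",
  representation(
    region = "GRanges",
    seq = "character",
    map = "integer"
  )
)

setValidity("ReconstructedRegion", function(object) {
  msg <- character()
  if (length(object@region) != 1L)
    msg <- c(msg, "region must be a single interval")
  if (length(object@seq) != 1L)
    msg <- c(msg, "seq must be a single string")
  if (nchar(object@seq) != length(object@map))
    msg <- c(msg, "map length must equal reconstructed sequence length")
  if (length(object@map) && any(diff(object@map) < 0L))
    msg <- c(msg, "coordinate map must be non-decreasing")
  if (length(object@map) &&
      (min(object@map) < GenomicRanges::start(object@region) ||
       max(object@map) > GenomicRanges::end(object@region)))
    msg <- c(msg, "coordinate map must stay within the reference region")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReconstructedRegion", function(object) {
  cat("ReconstructedRegion\n")
  cat(sprintf("  reference: %s:%d-%d\n",
              as.character(GenomicRanges::seqnames(object@region)),
              GenomicRanges::start(object@region),
              GenomicRanges::end(object@region)))
  cat(sprintf("  reconstructed length: %d (reference width %d)\n",
              nchar(object@seq), GenomicRanges::width(object@region)))
})

#' A simulated pulldown experiment with known ground truth
#'
#' Container for the synthetic-data module: a genome with implanted motif
#' instances, the implanted true (enriched) sites, the implanted decoy
#' (motif-matching but unenriched) positions, and the simulation
#' parameters.
#'
#' @slot genome `DNAStringSet`, one entry per chromosome.
#' @slot trueSites `GRanges` of implanted enriched motif instances, with
#'   metadata column `orientation`.
#' @slot decoySites `GRanges` of implanted non-enriched motif instances.
#' @slot params list of generator parameters (see [simulationParams()]).
#'
#' @export
setClass("PipSimulation",
  representation(
    genome = "DNAStringSet",
    trueSites = "GRanges",
    decoySites = "GRanges",
    params = "list"
  )
)

setValidity("PipSimulation", function(object) {
  msg <- character()
  chroms <- names(object@genome)
  if (is.null(chroms) || any(chroms == ""))
    msg <- c(msg, "genome chromosomes must be named")
  sites <- c(object@trueSites, object@decoySites)
  if (length(sites) &&
      !all(as.character(GenomicRanges::seqnames(sites)) %in% chroms))
    msg <- c(msg, "implanted sites must lie on genome chromosomes")
  if (length(object@trueSites) && length(object@decoySites) &&
      any(GenomicRanges::countOverlaps(object@trueSites,
                                       object@decoySites) > 0))
    msg <- c(msg, "true and decoy sites must be disjoint")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PipSimulation", function(object) {
  cat("PipSimulation\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp total\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ",")))
  cat(sprintf("  true sites: %d   decoy sites: %d\n",
              length(object@trueSites), length(object@decoySites)))
  cat(sprintf("  motif: %s   seed: %s\n",
              object@params$motif %||% "?",
              format(object@params$seed %||% NA)))
})

#' K-mer composition profile of a sequence set
#'
#' Sparse k-mer counts over one or more DNA sequences; windows containing
#' N are never counted and strands are taken as given (no canonical
#' collapsing).
#'
#' @slot k k-mer length.
#' @slot counts named integer vector of counts for k-mers observed at
#'   least once.
#' @slot total total number of counted k-mer windows.
#'
#' @export
setClass("KmerProfile",
  representation(
    k = "integer",
    counts = "integer",
    total = "numeric"
  )
)

setValidity("KmerProfile", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@counts)) {
    if (is.null(names(object@counts)))
      msg <- c(msg, "counts must be named by k-mer")
    if (any(object@counts < 1L))
      msg <- c(msg, "stored counts must be >= 1")
    if (any(nchar(names(object@counts)) != object@k))
      msg <- c(msg, "k-mer names must have length k")
  }
  if (!isTRUE(all.equal(object@total, sum(as.numeric(object@counts)))))
    msg <- c(msg, "total must equal the sum of counts")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerProfile", function(object) {
  cat(sprintf("KmerProfile: k = %d, %d distinct k-mers, %s windows counted\n",
              object@k, length(object@counts),
              format(object@total, big.mark = ",")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
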