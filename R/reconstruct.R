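# Sample-specific sequence reconstruction: apply SNVs and indels to a
# reference region so motif matching runs on the cell line's actual
# sequence, with back-mapping of match coordinates to reference
# coordinates.

#' Read a minimal VCF of variants
#'
#' Parses only CHROM, POS, REF and ALT; FILTER/INFO and genotypes are
#' ignored. POS is converted from VCF's 1-based convention at this
#' boundary (the internal convention is also 1-based, so positions pass
#' through unchanged). Records with multi-allelic ALT (comma-separated)
#' are rejected with a warning.
#'
#' @param path path to a VCF file; `##` meta lines and the `#CHROM`
#'   header are optional.
#' @return a `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @export
readMinimalVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L))
    stop("VCF record with fewer than 5 columns")
  alt <- vapply(fields, `[[`, "", 5L)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) rejected")
    fields <- fields[!multi]; alt <- alt[!multi]
  }
  data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = as.integer(vapply(fields, `[[`, "", 2L)),
    ref = toupper(vapply(fields, `[[`, "", 4L)),
    alt = toupper(alt))
}

#' Apply variants to a reference region
#'
#' Substitutes each variant's ALT allele for its REF allele within the
#' region and builds a monotone coordinate map from reconstructed offsets
#' back to reference positions. Indels use the VCF shared-anchor
#' encoding: inserted bases map to the reference base preceding the
#' insertion, and deleted reference bases are absent from the map.
#'
#' @param genome a named `DNAStringSet`.
#' @param region a `GRanges` of length 1.
#' @param variants a `data.frame` as from [readMinimalVcf()]; variants
#'   outside the region are ignored. Variants must not overlap one
#'   another, and every REF allele must match the reference.
#' @return a [ReconstructedRegion-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACCGG"))
#' v <- data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "G")
#' applyVariants(g, GenomicRanges::GRanges("chr1:1-6"), v)
#' @export
applyVariants <- function(genome, region, variants = NULL) {
  stopifnot(length(region) == 1L)
  chrom <- as.character(seqnames(region))
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  refSeq <- genomeSubseq(genome, region)
  s0 <- start(region)
  if (is.null(variants) || !nrow(variants)) {
    return(new("ReconstructedRegion", region = region, seq = refSeq,
               map = seq.int(s0, length.out = nchar(refSeq))))
  }
  v <- variants[variants$chrom == chrom &
                variants$pos >= s0 &
                variants$pos + nchar(variants$ref) - 1L <= end(region), ,
                drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  if (nrow(v) > 1L &&
      any(v$pos[-1L] <= v$pos[-nrow(v)] + nchar(v$ref[-nrow(v)]) - 1L))
    stop("overlapping variants in region")
  refChars <- strsplit(refSeq, "")[[1L]]
  pieces <- character(); maps <- list()
  cursor <- s0  # next unconsumed reference position
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
    obs <- paste(refChars[(p - s0 + 1L):(p - s0 + nchar(ref))],
                 collapse = "")
    if (obs != ref)
      stop("REF allele mismatch at ", chrom, ":", p,
           " (expected ", ref, ", reference has ", obs, ")")
    if (cursor < p) {
      pieces <- c(pieces, paste(refChars[(cursor - s0 + 1L):(p - s0)],
                                collapse = ""))
      maps <- c(maps, list(seq.int(cursor, p - 1L)))
    }
    # ALT bases map to the shared anchor positions where they exist; the
    # inserted surplus maps to the last reference base of the allele.
    nref <- nchar(ref); nalt <- nchar(alt)
    altMap <- c(seq.int(p, length.out = min(nref, nalt)),
                rep(p + nref - 1L, max(0L, nalt - nref)))
    pieces <- c(pieces, alt)
    maps <- c(maps, list(altMap))
    cursor <- p + nref
  }
  if (cursor <= end(region)) {
    pieces <- c(pieces, paste(refChars[(cursor - s0 + 1L):
                                       (end(region) - s0 + 1L)],
                              collapse = ""))
    maps <- c(maps, list(seq.int(cursor, end(region))))
  }
  new("ReconstructedRegion", region = region,
      seq = paste(pieces, collapse = ""),
      map = as.integer(unlist(maps)))
}

#' Back-map a motif match to reference coordinates
#'
#' Translates a match found on the reconstructed sequence to the
#' reference interval it spans. Matches whose reference width differs
#' from the motif length (because they span an indel) are flagged.
#'
#' @param offset 1-based match start on the reconstructed sequence.
#' @param k motif length.
#' @param rr a [ReconstructedRegion-class].
#' @return a `GRanges` of length 1 with metadata column `indelSpanning`.
#' @export
backmapMatch <- function(offset, k, rr) {
  if (offset < 1L || offset + k - 1L > length(rr@map))
    stop("match offset out of bounds of reconstructed sequence")
  refStart <- rr@map[offset]
  refEnd <- rr@map[offset + k - 1L]
  out <- GRanges(as.character(seqnames(rr@region)),
                 IRanges(refStart, refEnd))
  mcols(out)$indelSpanning <- (refEnd - refStart + 1L) != k
  out
}

#' Reconstructed sequence of a region
#' @param rr a [ReconstructedRegion-class].
#' @return the reconstructed sequence as a character string.
#' @export
reconstructedSeq <- function(rr) rr@seq
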