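# Readers and writers for the plain-text genomics formats the pipeline
# touches. External dialects (BED 0-based half-open, VCF 1-based) are
# converted to the internal GRanges convention (1-based closed) here and
# nowhere else.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and restricted to the alphabet A, C, G, T, N;
#' any other letter is an error naming the offending character.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`, one entry per chromosome. Names are
#'   truncated at the first whitespace of the header line.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty FASTA file: ", path)
  if (!startsWith(lines[[1L]], ">"))
    stop("malformed FASTA header at line 1: expected '>' record start")
  raw <- readBStringSet(path)
  seqs <- toupper(as.character(raw))
  bad <- regmatches(seqs, regexpr("[^ACGTN]", seqs))
  if (length(bad) && any(nzchar(bad)))
    stop("illegal character ", bad[nzchar(bad)][[1L]],
         " in FASTA sequence (alphabet is A/C/G/T/N)")
  names(seqs) <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(names(seqs)))) stop("malformed FASTA header: empty name")
  DNAStringSet(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome a named `DNAStringSet`.
#' @return named integer vector of chromosome lengths.
#' @export
genomeSeqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read intervals from a BED file
#'
#' BED's 0-based half-open coordinates are converted to the internal
#' 1-based closed `GRanges` convention at this boundary. Records with
#' `start >= end` are rejected with a warning; non-integer coordinates are
#' a parse error. A missing strand column yields `*`.
#'
#' @param path path to a BED3+ file (tab-separated).
#' @return a `GRanges`; metadata columns `name` and `score` are kept when
#'   present in the file.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t19", bed)
#' readBed(bed)  # chr1:11-19, strand *
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("BED record with fewer than 3 columns at line ",
         which(ncols < 3L)[[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0) ||
      any(start0 != floor(start0)) || any(end0 != floor(end0)))
    stop("non-integer BED coordinates in ", path)
  ok <- start0 < end0
  if (!all(ok)) {
    warning(sum(!ok), " BED record(s) with start >= end rejected")
    fields <- fields[ok]; chrom <- chrom[ok]
    start0 <- start0[ok]; end0 <- end0[ok]
    ncols <- ncols[ok]
  }
  if (!length(fields)) return(GRanges())
  strand <- rep("*", length(fields))
  has6 <- ncols >= 6L
  if (any(has6)) {
    s <- vapply(fields[has6], `[[`, "", 6L)
    s[!s %in% c("+", "-")] <- "*"
    strand[has6] <- s
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (any(ncols >= 4L)) {
    nm <- rep(".", length(fields))
    nm[ncols >= 4L] <- vapply(fields[ncols >= 4L], `[[`, "", 4L)
    mcols(gr)$name <- nm
  }
  if (any(ncols >= 5L)) {
    sc <- rep(0, length(fields))
    sc[ncols >= 5L] <- suppressWarnings(
      as.numeric(vapply(fields[ncols >= 5L], `[[`, "", 5L)))
    mcols(gr)$score <- sc
  }
  attr(gr, "bedColumns") <- max(ncols)
  gr
}

#' Write intervals to a BED file
#'
#' Coordinates are converted back to BED's 0-based half-open convention.
#' Three columns are written unless the object carries names, scores or
#' stranded intervals, in which case six are written (strand `*` becomes
#' `.`). `readBed()` followed by `writeBed()` reproduces coordinates
#' bit-exactly.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  chrom <- as.character(seqnames(gr))
  start0 <- format(start(gr) - 1L, scientific = FALSE, trim = TRUE)
  end0 <- format(end(gr), scientific = FALSE, trim = TRUE)
  hasMeta <- !is.null(mcols(gr)$name) || !is.null(mcols(gr)$score) ||
    any(as.character(strand(gr)) != "*")
  if (!hasMeta) {
    out <- paste(chrom, start0, end0, sep = "\t")
  } else {
    nm <- mcols(gr)$name %||% rep(".", length(gr))
    sc <- mcols(gr)$score %||% rep(0, length(gr))
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    out <- paste(chrom, start0, end0, nm,
                 format(sc, scientific = FALSE, trim = TRUE), st, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read transcripts from a UCSC refFlat table
#'
#' Expects the standard 11 refFlat columns. Exon start/end lists are
#' parsed from their comma-separated (possibly comma-terminated) fields;
#' records whose exon lists disagree with `exonCount`, or whose
#' coordinates are inconsistent, are rejected with a warning.
#'
#' @param path path to a refFlat file.
#' @return a `GRanges` of transcripts (txStart/txEnd converted from
#'   UCSC 0-based), with metadata columns `gene`, `txName`, `cds`
#'   (an `IRanges`, zero-width for non-coding transcripts) and `exons`
#'   (an `IRangesList`).
#' @export
readRefFlat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("geneName", "name", "chrom",
                                         "strand", "txStart", "txEnd",
                                         "cdsStart", "cdsEnd", "exonCount",
                                         "exonStarts", "exonEnds"),
                           comment.char = "#")
  parseList <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.integer)
  exS <- parseList(tab$exonStarts)
  exE <- parseList(tab$exonEnds)
  ok <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- exS[[i]]; e <- exE[[i]]
    if (length(s) != tab$exonCount[i] || length(e) != tab$exonCount[i]) {
      ok[i] <- FALSE; next
    }
    if (tab$txStart[i] >= tab$txEnd[i] ||
        tab$cdsStart[i] < tab$txStart[i] || tab$cdsEnd[i] > tab$txEnd[i]) {
      ok[i] <- FALSE; next
    }
    if (length(s)) {
      if (any(s >= e) || is.unsorted(s, strictly = TRUE) ||
          any(s[-1L] < e[-length(e)]) ||
          s[1L] < tab$txStart[i] || e[length(e)] > tab$txEnd[i])
        ok[i] <- FALSE
    }
  }
  if (!all(ok))
    warning(sum(!ok), " refFlat record(s) rejected (inconsistent exon or ",
            "coordinate fields)")
  tab <- tab[ok, , drop = FALSE]
  exS <- exS[ok]; exE <- exE[ok]
  gr <- GRanges(tab$chrom, IRanges(tab$txStart + 1L, tab$txEnd),
                strand = tab$strand)
  mcols(gr)$gene <- tab$geneName
  mcols(gr)$txName <- tab$name
  mcols(gr)$cds <- IRanges(tab$cdsStart + 1L, tab$cdsEnd)
  mcols(gr)$exons <- IRangesList(mapply(function(s, e) IRanges(s + 1L, e),
                                        exS, exE, SIMPLIFY = FALSE))
  gr
}

#' Per-base coverage from aligned fragments
#'
#' Depth at a base is the number of fragments covering it. Fragments on
#' chromosomes absent from `seqlengths` are skipped with a warning;
#' fragments extending past a chromosome end are clipped with a warning.
#'
#' @param fragments a `GRanges` of aligned fragments.
#' @param seqlengths named integer vector of chromosome lengths (e.g. from
#'   [genomeSeqlengths()]).
#' @return an `RleList` of per-base depth, one vector per chromosome in
#'   `seqlengths`.
#' @export
fragmentCoverage <- function(fragments, seqlengths) {
  known <- as.character(seqnames(fragments)) %in% names(seqlengths)
  if (!all(known)) {
    warning(sum(!known), " fragment(s) on unknown chromosome(s) skipped")
    fragments <- fragments[known]
  }
  if (length(fragments)) {
    lens <- seqlengths[as.character(seqnames(fragments))]
    clip <- start(fragments) < 1L | end(fragments) > lens
    if (any(clip)) {
      warning(sum(clip), " fragment(s) clipped to chromosome bounds")
      start(fragments) <- pmax(start(fragments), 1L)
      end(fragments) <- pmin(end(fragments), lens)
    }
  }
  fragments <- GRanges(as.character(seqnames(fragments)), ranges(fragments))
  GenomeInfoDb::seqlevels(fragments) <- names(seqlengths)
  GenomeInfoDb::seqlengths(fragments) <- seqlengths
  GenomicRanges::coverage(fragments)
}

#' Read a bedGraph coverage track
#'
#' Overlapping records are collapsed by summation (coverage is additive).
#'
#' @param path path to a bedGraph file (chrom, start, end, value).
#' @param seqlengths named integer vector of chromosome lengths.
#' @return an `RleList` of per-base values.
#' @export
readBedGraph <- function(path, seqlengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4L) stop("bedGraph requires 4 columns")
  known <- tab[[1L]] %in% names(seqlengths)
  if (!all(known)) {
    warning(sum(!known), " bedGraph record(s) on unknown chromosome(s) ",
            "skipped")
    tab <- tab[known, , drop = FALSE]
  }
  gr <- GRanges(tab[[1L]], IRanges(tab[[2L]] + 1L, tab[[3L]]))
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  GenomicRanges::coverage(gr, weight = tab[[4L]])
}

#' Write a coverage track as bedGraph
#'
#' Runs of constant value are emitted as single records; zero runs are
#' skipped.
#'
#' @param cov an `RleList` of per-base values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(cov)) {
    r <- cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(paste(chrom, starts[keep] - 1L, ends[keep],
                     format(vals[keep], scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Extract the sequence of an interval from a genome
#'
#' @param genome a named `DNAStringSet`.
#' @param gr a `GRanges` (strand ignored; the plus-strand sequence is
#'   returned).
#' @return character vector of sequences, one per interval.
#' @export
genomeSubseq <- function(genome, gr) {
  chrom <- as.character(seqnames(gr))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("unknown chromosome(s): ", paste(missing, collapse = ", "))
  vapply(seq_along(gr), function(i) {
    as.character(subseq(genome[[chrom[i]]], start(gr)[i], end(gr)[i]))
  }, "")
}
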