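# Synthetic-data generator: genomes with implanted motif instances,
# pulldown/input fragment sets with controlled enrichment, and
# expression tables with a knockdown effect at bound genes. Ground truth
# is carried for every pipeline stage.

#' Default simulation parameters
#'
#' The defaults define the reference study conditions used throughout
#' the package's tests: a 2-Mb single-chromosome genome at human-like GC
#' (0.41) with 20 implanted enriched ("true") motif sites and 200
#' motif-matching but unenriched decoys, background fragment rate 0.05
#' per base, 8-fold enrichment at true sites, and sonication-scale
#' fragment lengths Normal(200, 50) truncated at 50 bp. Implants are
#' separated by at least 3000 bp so merged calling windows and decision
#' windows of distinct implants cannot collide.
#'
#' @param genomeLength total genome length in bp.
#' @param nChrom number of chromosomes (length split evenly).
#' @param gc background GC fraction.
#' @param motif IUPAC motif to implant.
#' @param nTrueSites number of enriched implants.
#' @param nDecoySites number of unenriched motif implants.
#' @param minSeparation minimum bp between implant starts.
#' @param strict when TRUE, background windows accidentally matching the
#'   motif are re-randomized until implants are the only matches.
#' @param backgroundRate fragment start rate per base (per track).
#' @param enrichment fold enrichment of pulldown depth at true sites
#'   (> 1, or exactly 1 for null simulations).
#' @param fragMean,fragSd fragment length Normal parameters (truncated
#'   at 50 bp).
#' @param nGenes,nBoundGenes,delta,sigma,nRep expression model: gene
#'   count, number of bound genes, bound-gene log2FC shift (negative for
#'   knockdown), per-gene noise SD, replicates per condition for the
#'   per-gene p simulation.
#' @param seed integer seed.
#' @return a named list of parameters.
#' @export
simulationParams <- function(genomeLength = 2e6, nChrom = 1L, gc = 0.41,
                             motif = "TGWWGGCGW",
                             nTrueSites = 20L, nDecoySites = 200L,
                             minSeparation = 3000L, strict = TRUE,
                             backgroundRate = 0.05, enrichment = 8,
                             fragMean = 200, fragSd = 50,
                             nGenes = 2000L, nBoundGenes = 200L,
                             delta = -0.5, sigma = 0.3, nRep = 2L,
                             seed = 1L) {
  stopifnot(enrichment >= 1, gc >= 0, gc <= 1, backgroundRate > 0)
  list(genomeLength = genomeLength, nChrom = as.integer(nChrom), gc = gc,
       motif = toupper(motif), nTrueSites = as.integer(nTrueSites),
       nDecoySites = as.integer(nDecoySites),
       minSeparation = as.integer(minSeparation), strict = strict,
       backgroundRate = backgroundRate, enrichment = enrichment,
       fragMean = fragMean, fragSd = fragSd, nGenes = as.integer(nGenes),
       nBoundGenes = as.integer(nBoundGenes), delta = delta,
       sigma = sigma, nRep = as.integer(nRep), seed = as.integer(seed))
}

# Resolve IUPAC W positions of a motif to a concrete instance.
.concreteMotif <- function(motif) {
  letters <- strsplit(motif, "")[[1L]]
  w <- letters == "W"
  letters[w] <- sample(c("A", "T"), sum(w), replace = TRUE)
  paste(letters, collapse = "")
}

#' Simulate a genome with implanted motif instances
#'
#' Background bases are i.i.d. at the specified GC; motif instances
#' (concrete W resolutions sampled uniformly, orientation random) are
#' implanted at uniformly sampled positions subject to the minimum
#' separation. In strict mode, accidental background matches are
#' re-randomized away, so [catalogSites()] finds exactly the implants.
#'
#' @param params a list from [simulationParams()].
#' @return a [PipSimulation-class] (fragment and expression slots are
#'   produced by [simulateFragments()] and [simulateExpression()]).
#' @export
simulateGenome <- function(params = simulationParams()) {
  k <- nchar(params$motif)
  nSites <- params$nTrueSites + params$nDecoySites
  if (params$genomeLength < 10 * nSites * k)
    stop("genome too short for the requested implants")
  withSeed(params$seed, {
    chromLen <- rep(floor(params$genomeLength / params$nChrom),
                    params$nChrom)
    names(chromLen) <- paste0("chr", seq_len(params$nChrom))
    baseProb <- c(A = (1 - params$gc) / 2, C = params$gc / 2,
                  G = params$gc / 2, T = (1 - params$gc) / 2)
    chromSeqs <- lapply(chromLen, function(L)
      sample(names(baseProb), L, replace = TRUE, prob = baseProb))
    # placement: uniform, non-overlapping, min separation, per chromosome
    placements <- .placeImplants(chromLen, nSites, k,
                                 params$minSeparation)
    ori <- sample(c("forward", "reverse"), nSites, replace = TRUE)
    for (i in seq_len(nSites)) {
      inst <- .concreteMotif(params$motif)
      if (ori[i] == "reverse")
        inst <- as.character(reverseComplement(DNAString(inst)))
      chromSeqs[[placements$chrom[i]]][
        placements$start[i]:(placements$start[i] + k - 1L)] <-
        strsplit(inst, "")[[1L]]
    }
    implants <- GRanges(placements$chrom,
                        IRanges(placements$start,
                                placements$start + k - 1L),
                        orientation = ori)
    genome <- DNAStringSet(vapply(chromSeqs, paste, "", collapse = ""))
    names(genome) <- names(chromLen)
    if (params$strict)
      genome <- .scrubAccidentalMatches(genome, params$motif, implants,
                                        baseProb)
    isTrue <- seq_len(nSites) <= params$nTrueSites
    new("PipSimulation", genome = genome,
        trueSites = sort(implants[isTrue]),
        decoySites = sort(implants[!isTrue]),
        params = params)
  })
}

# Uniform non-overlapping placement with minimum start-to-start
# separation, chromosome picked proportionally to length.
.placeImplants <- function(chromLen, n, k, minSep) {
  margin <- max(minSep, 1100L)  # keep decision windows inside bounds
  chrom <- character(n)
  start <- integer(n)
  placedByChrom <- lapply(chromLen, function(x) integer())
  for (i in seq_len(n)) {
    for (attempt in seq_len(10000L)) {
      ch <- sample(names(chromLen), 1L, prob = chromLen)
      s <- sample.int(chromLen[[ch]] - 2L * margin, 1L) + margin
      if (all(abs(placedByChrom[[ch]] - s) >= minSep)) {
        chrom[i] <- ch
        start[i] <- s
        placedByChrom[[ch]] <- c(placedByChrom[[ch]], s)
        break
      }
      if (attempt == 10000L)
        stop("cannot place implants without overlap; genome too crowded")
    }
  }
  list(chrom = chrom, start = start)
}

# Re-randomize bases of motif matches that are not implants until the
# catalog contains exactly the implanted intervals.
.scrubAccidentalMatches <- function(genome, motif, implants, baseProb) {
  implantKey <- paste(seqnames(implants), start(implants))
  for (iter in seq_len(50L)) {
    sites <- catalogSites(genome, motif)
    stray <- sites[!paste(seqnames(sites), start(sites)) %in% implantKey]
    if (!length(stray)) return(genome)
    seqs <- as.list(as.character(genome))
    for (i in seq_along(stray)) {
      chrom <- as.character(seqnames(stray[i]))
      pos <- start(stray[i]):end(stray[i])
      # mutate only bases outside implanted intervals
      imp <- implants[as.character(seqnames(implants)) == chrom]
      inImplant <- vapply(pos, function(p)
        any(p >= start(imp) & p <= end(imp)), logical(1))
      mutable <- pos[!inImplant]
      if (!length(mutable)) next
      p <- sample(mutable, 1L)
      substr(seqs[[chrom]], p, p) <- sample(names(baseProb), 1L,
                                            prob = baseProb)
    }
    genome <- DNAStringSet(unlist(seqs))
  }
  stop("could not scrub accidental motif matches in 50 iterations")
}

# Truncated-normal fragment lengths (sonication model).
.fragLengths <- function(n, mean, sd) {
  len <- round(stats::rnorm(n, mean, sd))
  pmax(len, 50L)
}

#' Simulate pulldown and input fragment sets
#'
#' The input track is Poisson-uniform fragment starts at the background
#' rate with truncated-Normal lengths. The pulldown track is an
#' independent draw of the same background plus, at each true site,
#' extra fragments at rate `(enrichment - 1) x backgroundRate x
#' fragMean` whose centers jitter around the site center with SD
#' `fragMean / 4`. Decoys receive no extra mass.
#'
#' @param sim a [PipSimulation-class] from [simulateGenome()].
#' @param seed optional seed (default: the simulation seed + 1).
#' @return a list with `GRanges` elements `pulldown` and `input`.
#' @export
simulateFragments <- function(sim, seed = NULL) {
  params <- simParams(sim)
  if (is.null(seed)) seed <- params$seed + 1L
  lens <- genomeSeqlengths(genomeSeq(sim))
  background <- function() {
    do.call(c, lapply(names(lens), function(chrom) {
      L <- lens[[chrom]]
      nf <- stats::rpois(1L, params$backgroundRate * L)
      st <- sample.int(L, nf, replace = TRUE)
      fl <- .fragLengths(nf, params$fragMean, params$fragSd)
      GRanges(chrom, IRanges(st, width = fl))
    }))
  }
  clampTo <- function(gr) {
    l <- lens[as.character(seqnames(gr))]
    end(gr) <- pmin(end(gr), l)
    gr
  }
  withSeed(seed, {
    input <- clampTo(background())
    pulldown <- clampTo(background())
    if (params$enrichment > 1 && length(trueSites(sim))) {
      extraRate <- (params$enrichment - 1) * params$backgroundRate *
        params$fragMean
      extras <- lapply(seq_along(trueSites(sim)), function(i) {
        site <- trueSites(sim)[i]
        ne <- stats::rpois(1L, extraRate)
        if (ne == 0L) return(NULL)
        fl <- .fragLengths(ne, params$fragMean, params$fragSd)
        center <- start(site) + width(site) %/% 2L +
          round(stats::rnorm(ne, 0, params$fragMean / 4))
        st <- pmax(1L, as.integer(center - fl %/% 2L))
        GRanges(as.character(seqnames(site)), IRanges(st, width = fl))
      })
      extras <- extras[!vapply(extras, is.null, logical(1))]
      if (length(extras))
        pulldown <- c(pulldown, clampTo(do.call(c, extras)))
    }
    list(pulldown = sort(pulldown), input = sort(input))
  })
}

#' Simulate an expression table with a knockdown effect at bound genes
#'
#' Unbound genes draw log2FC from Normal(0, sigma); bound genes from
#' Normal(delta, sigma). Each gene's p-value comes from a Welch t-test
#' on simulated replicate values (`nRep` per condition) whose treatment
#' mean is the gene's drawn log2FC.
#'
#' @param genes character vector of gene symbols.
#' @param boundGenes subset of `genes` carrying binding sites.
#' @param delta bound-gene log2FC shift (negative = knockdown).
#' @param sigma noise SD.
#' @param seed integer seed.
#' @param nRep replicates per condition for the per-gene p simulation.
#' @return a `data.frame` with columns `gene`, `log2FC`, `p`.
#' @export
simulateExpression <- function(genes, boundGenes, delta = -0.5,
                               sigma = 0.3, seed = 1L, nRep = 2L) {
  stopifnot(all(boundGenes %in% genes))
  withSeed(seed, {
    bound <- genes %in% boundGenes
    log2fc <- stats::rnorm(length(genes), mean = ifelse(bound, delta, 0),
                           sd = sigma)
    p <- vapply(log2fc, function(fc) {
      ctrl <- stats::rnorm(nRep, 0, sigma)
      trt <- stats::rnorm(nRep, fc, sigma)
      stats::t.test(trt, ctrl, var.equal = FALSE)$p.value
    }, 0)
    data.frame(gene = genes, log2FC = log2fc, p = p)
  })
}

#' Simulate a transcript annotation over implanted sites
#'
#' Builds a simple single-exon transcript table in which the first
#' `length(boundGenes)` transcripts each span one implanted site (so the
#' site is intragenic) and the remainder tile free genome; used to join
#' binding to expression in end-to-end runs.
#'
#' @param sim a [PipSimulation-class].
#' @param nGenes total transcripts to create.
#' @param txWidth transcript width in bp.
#' @return a `GRanges` transcript annotation (metadata columns `gene`,
#'   `txName`, `cds`, `exons`) in which transcripts `g1..gK` cover the
#'   true sites (K = number of true sites).
#' @export
simulateTranscripts <- function(sim, nGenes = 200L, txWidth = 2000L) {
  lens <- genomeSeqlengths(genomeSeq(sim))
  sites <- trueSites(sim)
  k <- length(sites)
  stopifnot(nGenes >= k)
  onSite <- GRanges(as.character(seqnames(sites)),
                    IRanges(pmax(1L, start(sites) - txWidth %/% 2L),
                            width = txWidth))
  l <- lens[as.character(seqnames(onSite))]
  end(onSite) <- pmin(end(onSite), l)
  nFree <- nGenes - k
  perChrom <- max(2L, ceiling(2L * nFree / length(lens)) + 10L)
  freeList <- lapply(names(lens), function(chrom) {
    starts <- seq.int(1L, max(1L, lens[[chrom]] - txWidth),
                      length.out = perChrom)
    GRanges(chrom, IRanges(as.integer(starts), width = txWidth))
  })
  free <- do.call(c, freeList)
  free <- free[countOverlaps(free, sites) == 0L]
  if (length(free) < nFree)
    stop("genome too small to place ", nFree, " site-free transcripts")
  free <- free[seq_len(nFree)]
  tx <- c(onSite, free)
  strand(tx) <- rep(c("+", "-"), length.out = length(tx))
  mcols(tx)$gene <- paste0("g", seq_along(tx))
  mcols(tx)$txName <- paste0("tx", seq_along(tx))
  mcols(tx)$cds <- IRanges(start(tx), end(tx))
  mcols(tx)$exons <- IRangesList(lapply(seq_along(tx), function(i)
    IRanges(start(tx)[i], end(tx)[i])))
  tx
}
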