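# End-to-end orchestration: simulate (optional) -> candidate calling ->
# site validation -> annotation -> expression integration -> pathway
# screen, with a deterministic manifest of outputs.

#' Run the full pipeline from a configuration
#'
#' Stages execute in order and write their outputs under `outdir`; the
#' manifest records each file, its md5 checksum and row count. Reruns
#' with an identical configuration and seed are bit-identical. A global
#' seed is given per-stage derived sub-seeds so stages are individually
#' reproducible.
#'
#' Configuration fields (a named list, or a YAML file read with
#' [readPipelineConfig()]):
#' \describe{
#'   \item{outdir}{output directory (created).}
#'   \item{seed}{global integer seed.}
#'   \item{motif}{IUPAC motif (default `"TGWWGGCGW"`).}
#'   \item{simulate}{optional list of [simulationParams()] overrides;
#'     when present the inputs are generated.}
#'   \item{genome, pulldown, input}{paths (FASTA, fragment BED x2) used
#'     when `simulate` is absent.}
#'   \item{expression}{optional expression TSV path (generated when
#'     simulating).}
#'   \item{pathways}{optional GMT path for the pathway screen.}
#'   \item{transcripts}{optional refFlat path for annotation.}
#'   \item{windowSizes, pThreshold, alpha}{stage parameters with the
#'     usual defaults.}
#' }
#'
#' @param config named list (see above) or path to a YAML file.
#' @return the manifest `data.frame` (file, md5, rows), invisibly also
#'   written to `manifest.tsv`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(is.list(config), !is.null(config$outdir),
            !is.null(config$seed))
  motif <- config$motif %||% "TGWWGGCGW"
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list()
  note <- function(path, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), md5 = unname(tools::md5sum(path)),
      rows = rows)
  }

  # --- inputs: simulated or read from disk -------------------------------
  if (!is.null(config$simulate)) {
    simOver <- if (isTRUE(config$simulate)) list() else config$simulate
    simPar <- do.call(simulationParams,
                      c(simOver,
                        list(seed = stageSeed(seed, "simulate"),
                             motif = motif)))
    sim <- simulateGenome(simPar)
    frags <- simulateFragments(sim)
    genome <- genomeSeq(sim)
    pulldown <- frags$pulldown
    input <- frags$input
    tx <- simulateTranscripts(sim, nGenes = simPar$nGenes %/% 10L)
    boundTruth <- mcols(tx)$gene[countOverlaps(tx, trueSites(sim)) > 0L]
    expression <- simulateExpression(
      paste0("g", seq_len(length(tx))), boundTruth,
      delta = simPar$delta, sigma = simPar$sigma,
      seed = stageSeed(seed, "expression"))
    writeGenomeFasta(genome, file.path(outdir, "ref.fa"))
    note(file.path(outdir, "ref.fa"), length(genome))
    writeBed(trueSites(sim), file.path(outdir, "truth.bed"))
    note(file.path(outdir, "truth.bed"), length(trueSites(sim)))
    writeBed(decoySites(sim), file.path(outdir, "decoys.bed"))
    note(file.path(outdir, "decoys.bed"), length(decoySites(sim)))
    writeBed(pulldown, file.path(outdir, "pulldown.bed"))
    note(file.path(outdir, "pulldown.bed"), length(pulldown))
    writeBed(input, file.path(outdir, "input.bed"))
    note(file.path(outdir, "input.bed"), length(input))
    writeExpressionTable(expression, file.path(outdir, "expression.tsv"))
    note(file.path(outdir, "expression.tsv"), nrow(expression))
  } else {
    for (f in c("genome", "pulldown", "input"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("missing required input: ", f)
    genome <- readGenomeFasta(config$genome)
    pulldown <- readBed(config$pulldown)
    input <- readBed(config$input)
    tx <- if (!is.null(config$transcripts)) readRefFlat(config$transcripts)
    expression <- if (!is.null(config$expression))
      readExpressionTable(config$expression)
  }
  lens <- genomeSeqlengths(genome)

  # --- candidate calling -------------------------------------------------
  candidates <- callCandidateRegions(
    pulldown, input, lens,
    windowSizes = as.integer(config$windowSizes %||%
                               c(400L, 600L, 800L, 1000L, 1200L)),
    pThreshold = config$pThreshold %||% 1e-4)
  writeBed(GRanges(as.character(seqnames(candidates)), ranges(candidates)),
           file.path(outdir, "regions.bed"))
  note(file.path(outdir, "regions.bed"), length(candidates))

  # --- site validation ---------------------------------------------------
  vcfg <- siteValidationConfig(alpha = config$alpha %||% 0.05,
                               seed = stageSeed(seed, "validate"))
  pdCov <- fragmentCoverage(pulldown, lens)
  inCov <- fragmentCoverage(input, lens)
  sites <- validateSites(candidates, motif, genome, pdCov, inCov, vcfg)
  writeSitesTsv(sites, file.path(outdir, "sites.tsv"))
  note(file.path(outdir, "sites.tsv"), length(sites))

  # --- annotation --------------------------------------------------------
  boundGenes <- character()
  if (!is.null(tx)) {
    annotated <- annotateSites(sites, tx, seqlengths = lens)
    df <- data.frame(chrom = as.character(seqnames(annotated)),
                     start = start(annotated) - 1L,
                     end = end(annotated),
                     class = mcols(annotated)$class,
                     genes = mcols(annotated)$genes,
                     promoterGenes = mcols(annotated)$promoterGenes,
                     annotation = mcols(annotated)$annotation)
    utils::write.table(df, file.path(outdir, "annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(outdir, "annotated.tsv"), nrow(df))
    sig <- mcols(annotated)$class == "significant"
    boundGenes <- unique(unlist(strsplit(
      mcols(annotated)$genes[sig & nzchar(mcols(annotated)$genes)], ";")))
  }

  # --- expression integration -------------------------------------------
  summaryRows <- data.frame()
  if (!is.null(expression) && length(boundGenes) >= 2L) {
    summ <- bindingExpressionSummary(boundGenes, expression)
    summaryRows <- cbind(summ, welchP = attr(summ, "welchP"))
  }
  utils::write.table(summaryRows, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note(file.path(outdir, "summary.tsv"), nrow(summaryRows))

  # --- pathway screen ----------------------------------------------------
  if (!is.null(config$pathways) && !is.null(expression)) {
    pw <- pathwayThreeCriteria(readGmt(config$pathways), expression,
                               boundGenes,
                               alpha = config$alpha %||% 0.05)
    utils::write.table(pw, file.path(outdir, "pathways.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(file.path(outdir, "pathways.tsv"), nrow(pw))
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file of [runPipeline()] fields.
#' @return a named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
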