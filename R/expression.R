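# Expression integration and pathway statistics: group comparisons of
# log2 fold changes between bound and unbound genes, bootstrap p
# estimates, the three-criteria pathway screen, and overrepresentation
# fold / Bonferroni reporting.

#' Read an expression table
#'
#' Tab-separated columns `gene`, `log2FC`, `p` (header required).
#' Genes appearing on multiple rows (multiple probes) are collapsed to
#' the row with the smallest p-value.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with one row per gene.
#' @export
readExpressionTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "log2FC", "p")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$gene, tab$p), , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an expression table
#' @param tab a `data.frame` with columns `gene`, `log2FC`, `p`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT style
#'
#' Each line: set id, description, then member genes, tab-separated.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of gene symbols;
#'   descriptions in `attr(x, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Welch's unequal-variance two-sample t-test
#'
#' @param groupA,groupB numeric vectors, each of length >= 2 with finite
#'   variance.
#' @return a list with elements `t`, `df` (Welch-Satterthwaite) and `p`
#'   (two-sided).
#' @export
welchT <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    # degenerate but well-defined: identical constants compare equal
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Two-sided F test of equal variances
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return the two-sided p-value; `attr(x, "ratio")` carries the
#'   variance ratio A/B.
#' @export
varianceFTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 values")
  if (stats::var(groupA) == 0 || stats::var(groupB) == 0)
    stop("zero variance in a group")
  ft <- stats::var.test(groupA, groupB)
  structure(unname(ft$p.value), ratio = unname(ft$estimate))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Bootstrap estimate of a two-group p-value
#'
#' For each trial, `n` values are resampled with replacement from each
#' group and a Welch t-test p-value is computed; the estimate is the
#' median p across trials.
#'
#' @param groupA,groupB numeric vectors.
#' @param trials number of bootstrap trials (default 1000).
#' @param n resample size per group per trial (default 100).
#' @param seed integer seed.
#' @return the median bootstrap p-value.
#' @export
bootstrapGroupP <- function(groupA, groupB, trials = 1000L, n = 100L,
                            seed = 1L) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 values")
  withSeed(seed, {
    ps <- vapply(seq_len(trials), function(i) {
      a <- sample(groupA, n, replace = TRUE)
      b <- sample(groupB, n, replace = TRUE)
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }, 0)
    stats::median(ps)
  })
}

#' Expression summary of bound versus unbound gene groups
#'
#' Joins binding status to the expression table and compares the group
#' means of -log2FC (so positive means down-regulation under treatment)
#' by Welch's t-test. Genes without expression records are excluded and
#' counted.
#'
#' @param boundGenes character vector of genes carrying binding sites.
#' @param expression a `data.frame` with columns `gene`, `log2FC`
#'   (treatment vs control), `p`.
#' @param otherGenes optional character vector defining the comparison
#'   group (default: all expressed genes not in `boundGenes`), e.g.
#'   motif-matched-but-unbound genes.
#' @return a `data.frame` with one row per group (`bound`, `other`)
#'   giving `n`, `meanNegLog2FC`, `sem`; `attr(x, "welchP")` the Welch
#'   p-value and `attr(x, "missing")` the count of bound genes without
#'   expression records.
#' @export
bindingExpressionSummary <- function(boundGenes, expression,
                                     otherGenes = NULL) {
  expr <- stats::setNames(expression$log2FC, expression$gene)
  bound <- intersect(boundGenes, names(expr))
  missing <- length(setdiff(boundGenes, names(expr)))
  if (is.null(otherGenes))
    otherGenes <- setdiff(names(expr), boundGenes)
  other <- intersect(setdiff(otherGenes, bound), names(expr))
  if (length(bound) < 2L || length(other) < 2L)
    stop("each group needs >= 2 expressed genes (bound: ", length(bound),
         ", other: ", length(other), ")")
  a <- -expr[bound]
  b <- -expr[other]
  wt <- welchT(a, b)
  out <- data.frame(
    group = c("bound", "other"),
    n = c(length(a), length(b)),
    meanNegLog2FC = c(mean(a), mean(b)),
    sem = c(stats::sd(a) / sqrt(length(a)),
            stats::sd(b) / sqrt(length(b))))
  attr(out, "welchP") <- wt$p
  attr(out, "missing") <- missing
  out
}

#' Three-criteria pathway screen
#'
#' For each pathway, three Welch t-tests on log2FC: (1) genes in the
#' pathway versus all other genes; (2) bound genes in the pathway versus
#' all non-bound genes; (3) bound genes in the pathway versus bound
#' genes outside it. Pathways with fewer than 2 bound genes (or without
#' expression-covered genes) are excluded before testing; a pathway is a
#' candidate when all three p-values are below `alpha`.
#'
#' @param pathways named list of gene-symbol vectors (see [readGmt()]).
#' @param expression expression `data.frame` (`gene`, `log2FC`, `p`).
#' @param boundGenes character vector of bound genes.
#' @param alpha significance level (default 0.05).
#' @return a `data.frame` with one row per pathway: `pathway`, `nGenes`
#'   (expression-covered), `nBound`, `p1`, `p2`, `p3`, `excluded`,
#'   `reason`, `candidate`.
#' @export
pathwayThreeCriteria <- function(pathways, expression, boundGenes,
                                 alpha = 0.05) {
  expr <- stats::setNames(expression$log2FC, expression$gene)
  boundGenes <- intersect(boundGenes, names(expr))
  out <- data.frame(pathway = names(pathways),
                    nGenes = 0L, nBound = 0L,
                    p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                    excluded = FALSE, reason = "",
                    candidate = FALSE)
  for (i in seq_along(pathways)) {
    members <- intersect(pathways[[i]], names(expr))
    boundIn <- intersect(members, boundGenes)
    out$nGenes[i] <- length(members)
    out$nBound[i] <- length(boundIn)
    if (!length(members)) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "no expression-covered genes"
      next
    }
    if (length(boundIn) < 2L) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "fewer than 2 bound genes"
      next
    }
    othersAll <- setdiff(names(expr), members)
    nonBound <- setdiff(names(expr), boundGenes)
    boundOut <- setdiff(boundGenes, members)
    p1 <- if (length(members) >= 2L && length(othersAll) >= 2L)
      welchT(expr[members], expr[othersAll])$p else NA_real_
    p2 <- if (length(nonBound) >= 2L)
      welchT(expr[boundIn], expr[nonBound])$p else NA_real_
    p3 <- if (length(boundOut) >= 2L)
      welchT(expr[boundIn], expr[boundOut])$p else NA_real_
    out$p1[i] <- p1; out$p2[i] <- p2; out$p3[i] <- p3
    out$candidate[i] <- isTRUE(p1 < alpha) && isTRUE(p2 < alpha) &&
      isTRUE(p3 < alpha)
  }
  out
}

#' Overrepresentation fold
#'
#' Ratio of found to expected gene counts for a category.
#'
#' @param found observed gene count.
#' @param expected expected gene count (> 0).
#' @return `found / expected`.
#' @examples
#' round(overrepFold(13, 3.55), 2)  # 3.66
#' @export
overrepFold <- function(found, expected) {
  if (expected <= 0) stop("expected count must be > 0")
  found / expected
}

#' Category overrepresentation test with Bonferroni correction
#'
#' One-sided test of the observed category count in a gene list against
#' the expectation from the genome-wide category frequency, under a
#' binomial model (default) or hypergeometric model, Bonferroni-corrected
#' over the tested categories.
#'
#' @param categoryInList named integer vector: observed member count of
#'   each category within the gene list.
#' @param categoryInGenome named integer vector (same names): category
#'   sizes in the genome annotation. Categories absent from the genome
#'   annotation (size 0) are skipped with a warning.
#' @param listSize number of genes in the list.
#' @param genomeSize number of annotated genes in the genome.
#' @param model `"binomial"` or `"hypergeometric"`.
#' @return a `data.frame` with columns `category`, `found`, `expected`,
#'   `fold`, `p` (raw, one-sided) and `pBonferroni`.
#' @export
overrepTest <- function(categoryInList, categoryInGenome, listSize,
                        genomeSize,
                        model = c("binomial", "hypergeometric")) {
  model <- match.arg(model)
  cats <- names(categoryInList)
  stopifnot(!is.null(cats), all(cats %in% names(categoryInGenome)))
  genome <- categoryInGenome[cats]
  skip <- genome == 0L
  if (any(skip)) {
    warning(sum(skip), " category(ies) absent from genome annotation ",
            "skipped")
    cats <- cats[!skip]
  }
  found <- categoryInList[cats]
  genome <- categoryInGenome[cats]
  expected <- listSize * genome / genomeSize
  p <- vapply(seq_along(cats), function(i) {
    if (model == "binomial") {
      stats::binom.test(found[[i]], listSize, genome[[i]] / genomeSize,
                        alternative = "greater")$p.value
    } else {
      stats::phyper(found[[i]] - 1L, genome[[i]],
                    genomeSize - genome[[i]], listSize,
                    lower.tail = FALSE)
    }
  }, 0)
  data.frame(category = cats,
             found = as.integer(found),
             expected = as.numeric(expected),
             fold = as.numeric(found / expected),
             p = p,
             pBonferroni = stats::p.adjust(p, method = "bonferroni"),
             row.names = NULL)
}
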