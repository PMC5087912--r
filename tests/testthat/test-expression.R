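# Expression-group statistics, bootstrap, pathway screen and
# overrepresentation reporting.

test_that("Welch t matches the textbook formula oracle", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(welchT(c(1, 2, 3), c(11, 12, 13))$p, 0.01)

  got <- welchT(c(1, 2, 3, 4), c(2, 3, 4, 5))
  oracle <- bruteWelch(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(got$t, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$p, oracle$p, tolerance = 1e-10)

  set.seed(23)
  for (rep in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), 0.5, 2)
    got <- welchT(a, b); oracle <- bruteWelch(a, b)
    expect_equal(got$p, oracle$p, tolerance = 1e-10)
  }
  expect_error(welchT(1, c(1, 2)), ">= 2 values")
})

test_that("variance F test is calibrated and powered", {
  set.seed(24)
  # identical groups -> ratio exactly 1
  x <- rnorm(20)
  expect_equal(attr(varianceFTest(x, x), "ratio"), 1)
  # calibration: median p over null replicates near 0.5
  ps <- replicate(200, varianceFTest(rnorm(25), rnorm(25)))
  expect_true(median(ps) > 0.3 && median(ps) < 0.7)
  # power: variance ratio 16 at n = 50
  expect_lt(varianceFTest(rnorm(50, sd = 4), rnorm(50, sd = 1)), 0.01)
  expect_error(varianceFTest(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Spearman rho matches the rank formula", {
  expect_equal(spearmanRho(1:10, (1:10)^3), 1.0)
  expect_equal(spearmanRho(1:10, -(1:10)), -1.0)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(spearmanRho(1:5, rep(2, 5)), "constant")
})

test_that("bootstrap p estimate is deterministic, calibrated, powered", {
  set.seed(25)
  a <- rnorm(60)
  expect_identical(bootstrapGroupP(a, a + 0.1, trials = 200, seed = 6),
                   bootstrapGroupP(a, a + 0.1, trials = 200, seed = 6))
  # identical distributions: median p should be mid-range
  nullP <- bootstrapGroupP(rnorm(200), rnorm(200), trials = 300, seed = 7)
  expect_true(nullP > 0.2 && nullP < 0.8)
  # 3-SD separation: decisive
  sepP <- bootstrapGroupP(rnorm(100), rnorm(100, 3), trials = 300,
                          seed = 8)
  expect_lt(sepP, 0.01)
})

test_that("bound genes with a knockdown shift separate from unbound", {
  genes <- paste0("g", 1:2000)
  bound <- paste0("g", 1:200)
  expr <- simulateExpression(genes, bound, delta = -0.5, sigma = 0.3,
                             seed = 33)
  summ <- bindingExpressionSummary(bound, expr)
  expect_gt(summ$meanNegLog2FC[summ$group == "bound"],
            summ$meanNegLog2FC[summ$group == "other"])
  expect_lt(attr(summ, "welchP"), 0.05)
  expect_error(bindingExpressionSummary("g1", expr), ">= 2 expressed")
})

test_that("null expression shows no material group difference", {
  genes <- paste0("g", 1:500)
  bound <- paste0("g", 1:50)
  hits <- 0L
  for (s in 1:50) {
    expr <- simulateExpression(genes, bound, delta = 0, sigma = 0.3,
                               seed = 100 + s)
    summ <- bindingExpressionSummary(bound, expr)
    if (attr(summ, "welchP") < 0.05) hits <- hits + 1L
  }
  # 99% binomial upper bound for 50 draws at rate 0.05
  expect_lte(hits, qbinom(0.995, 50, 0.05) + 1)
})

test_that("the three-criteria screen flags effects and excludes small sets", {
  set.seed(26)
  genes <- paste0("g", 1:2000)
  bound <- paste0("g", 1:200)
  expr <- simulateExpression(genes, bound, delta = -0.5, sigma = 0.3,
                             seed = 41)
  # effect pathway: 15 bound + 15 unbound genes, bound members get an
  # extra knockdown shift
  effectGenes <- c(paste0("g", 1:15), paste0("g", 501:515))
  expr$log2FC[expr$gene %in% paste0("g", 1:15)] <-
    expr$log2FC[expr$gene %in% paste0("g", 1:15)] - 0.8
  pathways <- list(
    effect = effectGenes,
    tiny = c("g1", "g900"),                     # 1 bound gene
    null1 = paste0("g", 1000:1040),             # no bound genes
    null2 = c(paste0("g", 150:160), paste0("g", 1100:1130)))
  res <- pathwayThreeCriteria(pathways, expr, bound)
  expect_true(res$candidate[res$pathway == "effect"])
  expect_true(res$excluded[res$pathway == "tiny"])
  expect_equal(res$reason[res$pathway == "tiny"],
               "fewer than 2 bound genes")
  expect_true(res$excluded[res$pathway == "null1"])
  # bookkeeping: excluded + tested = total
  expect_equal(sum(res$excluded) + sum(!res$excluded), length(pathways))
})

test_that("no-effect pathways are rarely flagged over seeded nulls", {
  genes <- paste0("g", 1:400)
  bound <- paste0("g", 1:60)
  flags <- 0L
  for (s in 1:100) {
    expr <- simulateExpression(genes, bound, delta = 0, sigma = 0.3,
                               seed = 300 + s)
    res <- pathwayThreeCriteria(
      list(p = c(paste0("g", 10:20), paste0("g", 200:220))), expr, bound)
    if (res$candidate[1L]) flags <- flags + 1L
  }
  expect_lte(flags / 100, 0.05)
})

test_that("overrepresentation folds reproduce the printed arithmetic", {
  expect_equal(round(overrepFold(13, 3.55), 2), 3.66)
  expect_equal(round(overrepFold(46, 18.62), 2), 2.47)
  expect_equal(overrepFold(7, 7), 1.00)
  expect_error(overrepFold(5, 0), "must be > 0")
})

test_that("overrepresentation test matches the binomial tail", {
  res <- overrepTest(c(path = 30L), c(path = 1000L), 100L, 10000L)
  expect_equal(res$p,
               pbinom(29, 100, 0.1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(res$p, 1e-5)
  expect_equal(res$expected, 10)
  # single category: Bonferroni identity
  expect_equal(res$pBonferroni, res$p)
  # observed equal to expectation is never significant
  res2 <- overrepTest(c(path = 10L), c(path = 1000L), 100L, 10000L)
  expect_gt(res2$p, 0.3)
  # absent category skipped with warning
  expect_warning(
    res3 <- overrepTest(c(a = 5L, b = 3L), c(a = 100L, b = 0L), 50L,
                        5000L),
    "skipped")
  expect_equal(nrow(res3), 1L)
})

test_that("expression table reading collapses duplicate probes", {
  f <- tmpFile(c("gene\tlog2FC\tp", "A\t-0.5\t0.2", "A\t-0.9\t0.01",
                 "B\t0.1\t0.5"))
  tab <- readExpressionTable(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$log2FC[tab$gene == "A"], -0.9)
})

test_that("GMT reading returns named member lists", {
  f <- tmpFile(c("p1\tdesc one\tA\tB\tC", "p2\tdesc two\tB\tD"))
  sets <- readGmt(f)
  expect_equal(names(sets), c("p1", "p2"))
  expect_equal(sets$p1, c("A", "B", "C"))
  expect_error(readGmt(tmpFile("p1\tonlydesc")), "fewer than 3")
})
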