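# Promoters, site annotation, closest features, consensus tracks,
# DHS profiling and chromatin odds.

gr <- function(starts, ends = NULL, chrom = "chr1", strand = "*",
               width = NULL) {
  if (!length(starts)) return(GenomicRanges::GRanges())
  r <- if (is.null(ends)) IRanges::IRanges(starts, width = width) else
    IRanges::IRanges(starts, ends)
  GenomicRanges::GRanges(chrom, r, strand = strand)
}

makeTx <- function(starts, ends, strand, genes, chrom = "chr1") {
  tx <- gr(starts, ends, chrom, strand)
  S4Vectors::mcols(tx)$gene <- genes
  tx
}

test_that("promoters sit strand-aware upstream of the TSS, clamped", {
  # + strand, 0-based txStart 5000 -> promoter [4000,5000) = 1-based
  # 4001..5000
  tx <- makeTx(5001L, 9000L, "+", "A")
  p <- promoterRegions(tx)
  expect_equal(GenomicRanges::start(p), 4001L)
  expect_equal(GenomicRanges::end(p), 5000L)

  # - strand, 0-based txEnd 8000 -> [8000,9000) = 8001..9000
  tx2 <- makeTx(4001L, 8000L, "-", "B")
  p2 <- promoterRegions(tx2)
  expect_equal(GenomicRanges::start(p2), 8001L)
  expect_equal(GenomicRanges::end(p2), 9000L)

  # clamped at the chromosome start: txStart 300 (0-based) -> width 300
  tx3 <- makeTx(301L, 900L, "+", "C")
  p3 <- promoterRegions(tx3)
  expect_equal(GenomicRanges::width(p3), 300L)
  expect_equal(GenomicRanges::start(p3), 1L)
})

test_that("sites are labeled with overlapping genes and promoters", {
  tx <- makeTx(c(2001L, 9001L), c(5000L, 12000L), c("+", "+"),
               c("GENEA", "GENEB"))
  sites <- gr(c(3000L, 1500L, 7000L), c(3008L, 1508L, 7008L))
  ann <- annotateSites(sites, tx)
  expect_equal(S4Vectors::mcols(ann)$genes, c("GENEA", "", ""))
  expect_equal(S4Vectors::mcols(ann)$promoterGenes,
               c("", "GENEA", ""))
  expect_equal(S4Vectors::mcols(ann)$annotation,
               c("transcript", "promoter", "intergenic"))
  s <- S4Vectors::metadata(ann)$annotationSummary
  expect_equal(unname(s[c("inTranscript", "inPromoter", "intergenic")]),
               c(1L, 1L, 1L))
})

test_that("annotation on an annotation-free chromosome is all intergenic", {
  sites <- gr(seq(100L, 1000L, 100L), seq(108L, 1008L, 100L))
  ann <- annotateSites(sites, makeTx(integer(), integer(), character(),
                                     character()))
  expect_true(all(S4Vectors::mcols(ann)$annotation == "intergenic"))
})

test_that("closest-feature distances handle overlap, gaps and ties", {
  track <- gr(c(201L, 1001L), c(300L, 1100L))  # 0-based [200,300), [1000,1100)
  # overlapping -> 0
  expect_equal(closestFeatureDistance(gr(250L, 260L), track)$distance, 0)
  # site [100,109) 0-based = 101..109; feature [200,300) = 201..300;
  # gap = 91
  expect_equal(closestFeatureDistance(gr(101L, 109L), track)$distance, 91)
  # equidistant -> left feature reported
  mid <- closestFeatureDistance(gr(351L, 950L), track)
  expect_equal(mid$distance, 50)
  expect_equal(mid$featureIndex, 1L)
  # empty chromosome track -> missing
  far <- closestFeatureDistance(gr(100L, 109L, chrom = "chr9"), track)
  expect_true(far$missing)
})

test_that("closest distances agree with a brute-force all-pairs scan", {
  set.seed(44)
  track <- sort(gr(sample.int(100000L, 300L), width = 1L))
  GenomicRanges::end(track) <- GenomicRanges::start(track) +
    sample(10:500, 300L, replace = TRUE)
  track <- GenomicRanges::reduce(track)
  sites <- gr(sample.int(100000L, 200L), width = 1L)
  GenomicRanges::end(sites) <- GenomicRanges::start(sites) + 8L
  got <- closestFeatureDistance(sites, track)
  for (i in seq_along(sites)) {
    gap <- pmax(GenomicRanges::start(track) - GenomicRanges::end(sites)[i]
                - 1L,
                GenomicRanges::start(sites)[i] - GenomicRanges::end(track)
                - 1L)
    gap <- pmax(gap, 0L)
    expect_equal(got$distance[i], min(gap))
  }
})

test_that("consensus track equals the per-base support threshold", {
  tracks <- list(
    gr(1L, 100L), gr(1L, 100L), gr(1L, 100L), gr(1L, 100L),
    gr(1L, 50L), gr(60L, 100L), gr(200L, 300L), gr(200L, 300L))
  cons <- consensusTrack(tracks, k = 5L, seqlengths = c(chr1 = 400L))
  # bases 1..50 have 5 supporters, 51..59 have 4, 60..100 have 5
  expect_equal(GenomicRanges::start(cons), c(1L, 60L))
  expect_equal(GenomicRanges::end(cons), c(50L, 100L))
  expect_error(consensusTrack(tracks[1:4], k = 5L), "fewer tracks")
})

test_that("consensus with k=1 is the union and k=n the intersection", {
  set.seed(15)
  tracks <- lapply(1:8, function(i) {
    s <- sort(sample.int(9000L, 20L))
    GenomicRanges::reduce(gr(s, s + sample(50:400, 20L, replace = TRUE)))
  })
  lens <- c(chr1 = 10000L)
  u <- consensusTrack(tracks, k = 1L, seqlengths = lens)
  expect_equal(as.data.frame(u)[1:3],
               as.data.frame(GenomicRanges::reduce(do.call(c, tracks)))[1:3])
  i8 <- consensusTrack(tracks, k = 8L, seqlengths = lens)
  inter <- Reduce(GenomicRanges::intersect, tracks)
  expect_equal(GenomicRanges::start(i8), GenomicRanges::start(inter))
})

test_that("consensus matches the per-base counting oracle on 100 kb", {
  set.seed(16)
  L <- 100000L
  tracks <- lapply(1:8, function(i) {
    s <- sort(sample.int(L - 500L, 60L))
    GenomicRanges::reduce(gr(s, s + sample(50:400, 60L, replace = TRUE)))
  })
  cons <- consensusTrack(tracks, k = 5L, seqlengths = c(chr1 = L))
  # oracle: count per-base membership with a plain integer vector
  support <- integer(L)
  for (t in tracks)
    for (j in seq_along(t))
      support[GenomicRanges::start(t)[j]:GenomicRanges::end(t)[j]] <-
        support[GenomicRanges::start(t)[j]:GenomicRanges::end(t)[j]] + 1L
  inCons <- logical(L)
  for (j in seq_along(cons))
    inCons[GenomicRanges::start(cons)[j]:GenomicRanges::end(cons)[j]] <-
      TRUE
  expect_identical(inCons, support >= 5L)
})

test_that("DHS profile bins are exact percentages that average correctly", {
  lens <- c(chr1 = 25000L)
  track <- gr(c(1L, 12001L), c(10000L, 13000L))
  sites <- gr(c(500L, 20000L), c(508L, 20008L))
  prof <- dhsPositionProfile(sites, track, lens, bin = 10000L)
  expect_equal(S4Vectors::mcols(prof$bins)$percent, c(100, 10, 0))
  expect_equal(prof$siteInside, c(TRUE, FALSE))
  # weighted average equals global coverage fraction
  w <- GenomicRanges::width(prof$bins)
  global <- sum(GenomicRanges::width(GenomicRanges::reduce(track))) /
    sum(w)
  expect_equal(sum(S4Vectors::mcols(prof$bins)$percent * w) / sum(w),
               100 * global)
  # straddling site is inside by the >= 1 bp rule
  straddle <- gr(9998L, 10006L)
  expect_true(dhsPositionProfile(straddle, track, lens)$siteInside)
})

test_that("chromatin odds follow the requested orientation", {
  track <- gr(1L, 1000L)
  sites <- gr(c(10L, 20L, 2000L, 3000L, 4000L, 5000L, 6000L, 7000L,
                8000L, 9000L),
              width = 1L)
  GenomicRanges::end(sites) <- GenomicRanges::start(sites) + 8L
  expect_equal(chromatinOdds(sites, track, "within_over_outside"), 2 / 8)
  expect_equal(chromatinOdds(sites, track, "outside_over_within"), 8 / 2)
  allIn <- gr(c(5L, 50L), c(13L, 58L))
  expect_equal(chromatinOdds(allIn, track, "outside_over_within"), 0)
  expect_error(chromatinOdds(allIn, track, "within_over_outside"),
               "zero denominator")
})

test_that("uniform sites over a half-covering track give odds near 1", {
  set.seed(17)
  L <- 200000L
  track <- gr(1L, L / 2L)
  sites <- gr(sample.int(L - 10L, 800L), width = 1L)
  GenomicRanges::end(sites) <- GenomicRanges::start(sites) + 8L
  odds <- chromatinOdds(sites, track, "within_over_outside")
  expect_true(odds > 0.75 && odds < 1.3)
})
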