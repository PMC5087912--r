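# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

tmpFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# --- degenerate motif oracle -------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"))

expandMotif <- function(motif) {
  sets <- IUPAC_SETS[strsplit(motif, "")[[1L]]]
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

revcompStr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", W = "W")
  vapply(x, function(s) paste(rev(comp[strsplit(s, "")[[1L]]]),
                              collapse = ""), "")
}

# All match offsets (1-based) of motif on sequence, per orientation, by
# exact search over every concrete expansion.
bruteMotifMatch <- function(sequence, motif) {
  findAll <- function(pats) {
    hits <- integer()
    for (p in pats) {
      from <- 1L
      repeat {
        i <- regexpr(p, substring(sequence, from), fixed = TRUE)
        if (i == -1L) break
        hits <- c(hits, from + i - 1L)
        from <- from + i  # allow overlapping matches
      }
    }
    sort(unique(hits))
  }
  list(forward = findAll(expandMotif(motif)),
       reverse = findAll(expandMotif(unname(revcompStr(motif)))))
}

# --- two-sample KS D oracle --------------------------------------------

bruteKsD <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# --- Welch t oracle (textbook formulas) --------------------------------

bruteWelch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# --- random DNA ---------------------------------------------------------

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Shared small simulation used by several test files (cached per session).
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- simulationParams(genomeLength = 3e5, nTrueSites = 5L,
                            nDecoySites = 30L, minSeparation = 2500L,
                            seed = 42L)
      cache <<- simulateGenome(p)
    }
    cache
  }
})
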