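# pipscan

Genome-wide binding-site discovery for alkylating pyrrole–imidazole
polyamides (PIPs) from biotin-pulldown enrichment sequencing.

PIPs read DNA in the minor groove through pyrrole/imidazole ring
pairings (Im/Py recognizes G·C, Py/Py recognizes A·T or T·A); conjugated
to an alkylating warhead they covalently fix themselves next to their
binding site. The flagship motif handled here is the 9-bp degenerate
sequence 5'-TGWWGGCGW-3' (W = A or T), designed against the mutant
*KRAS* codon-12 region. A 9-bp degenerate motif matches tens of
thousands of genomic positions, so the scientific question this package
answers is: *which of those hypothetical positions does the compound
actually occupy in cells?* It is written for computational biologists
analyzing pulldown/input sequencing pairs of such compounds (or
simulating them), in Bioconductor idiom (`GRanges`, `DNAStringSet`,
`RleList`).

## The method

Given pulldown and input fragment sets (BED) or coverage (bedGraph) and
a reference genome (FASTA):

1. **Candidate calling** — sliding windows at a sweep of sizes
   (400–1200 bp, step = window/4). For each window the fragment-midpoint
   counts form the 2×2 table
   `[[a, b], [A − a, B − b]]` (window vs library totals) tested by
   Pearson chi-square without continuity correction,
   `X² = n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`. Windows with
   `p < 1e-4` and pulldown-over-input direction are merged; the window
   sweep is compiled by interval union.
2. **Motif filtering** — candidate-region sequence (reconstructed
   through sample SNVs/indels when a VCF is supplied, with matches
   back-mapped to reference coordinates) is scanned for the motif in
   both orientations; N never matches.
3. **KS validation** — per-base coverage in a ±500 bp window around
   each candidate site is unity-normalized (sum-to-one) per track and
   subtracted to form a differential distribution. Null differentials
   are built from an equal number of non-candidate motif positions
   (pulldown foreground paired with shuffled input background). Each
   candidate is compared to every null by a two-sample
   Kolmogorov–Smirnov test; p-values are Benjamini–Hochberg adjusted
   per candidate, and the decision p is the nearest-rank 99.9th
   percentile of the adjusted values: `p < 0.05` significant,
   `0.05 ≤ p < 0.055` marginal. Fold enrichment is
   `log2(max pulldown / max input)` over the same window.

Downstream: transcript/promoter annotation (promoter = 1000 bp upstream
of the TSS, strand-aware), consensus heterochromatin (≥ 5-of-8 track
support), DHS position profiles and chromatin odds, closest-feature
distances, expression integration (Welch's *t*, *F*, Spearman,
bootstrap), a three-criteria pathway screen, scrambled-motif audits
with a fixed 5' thymine, and 9-mer composition comparison of site
regions with 1000-bp flanks. A seeded synthetic-data module generates
genomes with implanted motif sites, enriched fragment sets and
expression tables with known ground truth.

## Worked example

```r
library(pipscan)
library(GenomicRanges)

p <- simulationParams(genomeLength = 3e5, nTrueSites = 5,
                      nDecoySites = 30, minSeparation = 2500, seed = 42)
sim <- simulateGenome(p)
#> PipSimulation
#>   genome: 1 chromosome(s), 300,000 bp total
#>   true sites: 5   decoy sites: 30
#>   motif: TGWWGGCGW   seed: 42

fr <- simulateFragments(sim)
lens <- genomeSeqlengths(genomeSeq(sim))
cand <- callCandidateRegions(fr$pulldown, fr$input, lens)
length(cand)
#> [1] 5

sites <- validateSites(cand, "TGWWGGCGW", genomeSeq(sim),
                       fragmentCoverage(fr$pulldown, lens),
                       fragmentCoverage(fr$input, lens),
                       siteValidationConfig(seed = 5))
as.data.frame(sites)[, c("start", "end", "orientation", "foldLog2", "class")]
#>    start    end orientation foldLog2       class
#> 1   5269   5277     reverse 2.402098 significant
#> 2  95812  95820     forward 2.039528 significant
#> 3 121890 121898     forward 1.925999 significant
#> 4 251525 251533     forward 2.700440 significant
#> 5 294142 294150     forward 2.301170 significant
```

All five implanted sites are recovered as significant 9-bp loci, none of
the 30 decoy motif positions is called, and the log2 fold enrichments
(≈ 1.9–2.7, i.e. 4–6× peak-coverage ratios) reflect the simulated 8×
fragment-rate enrichment after unimodal peak spreading. `runPipeline()`
chains the stages (simulate → call → validate → annotate → integrate →
pathways) from one seeded YAML/list config and writes a manifest with
md5 checksums; `inst/scripts/pipscan` exposes the same stages as shell
subcommands (`simulate`, `scan`, `callregions`, `validate`, `scramble`,
`run`).

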