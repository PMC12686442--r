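# cmaflux

Chaperone-mediated autophagy (CMA) is the selective lysosomal degradation of
proteins that carry a KFERQ-like pentapeptide targeting motif, recognised by
the cytosolic chaperone HSC70 and translocated into the lysosome through the
LAMP-2A receptor (a splice isoform of *LAMP2*, the rate-limiting effector of
the pathway). Studying CMA in omics data — e.g. in retinal pigment epithelium
(RPE) from healthy versus age-related macular degeneration (AMD) donors —
requires a recurring computational toolkit that this package provides as
tested, reusable functions:

- **KFERQ-like motif scanning** (`scanProteins()`, `classifyWindow()`,
  `summarizeMotifs()`, `compareToReference()`): every 5-residue window is
  classified as **canonical** (terminal anchor Q; among the remaining four
  residues 1–2 hydrophobic {F,I,L,V}, 1–2 positive {K,R} and exactly one
  negative {E,D}, with all four accounted for), **phosphorylation-generated**
  (one S/T/Y recounted as the negative residue) and/or
  **acetylation-generated** (terminal K recounted as the anchor). The rule
  table (`MotifRuleSet()`) is fully configurable.
- **Transcriptional CMA score** (`computeCmaScore()`, `scoreGroups()`): for a
  network of effectors and positive/negative modulators with direction
  *d*<sub>g</sub> ∈ {−1, +1} and weight *w*<sub>g</sub> (LAMP2 = 2, others 1),
  the per-sample score is

  score<sub>s</sub> = Σ<sub>g</sub> *d*<sub>g</sub> *w*<sub>g</sub>
  *z*<sub>gs</sub> / Σ<sub>g</sub> *w*<sub>g</sub>

  where *z*<sub>gs</sub> is the per-gene z-score of log2 expression across
  samples (population SD).
- **Lysosomal-flux differential proteomics** (`rowwiseTest()`,
  `callSubstrates()`, `overlapSets()`): proteins accumulating when lysosomal
  proteolysis is blocked with NH₄Cl + leupeptin ("N/L") are candidate
  degradation substrates. Row-wise paired (per-donor one-sample t) or Welch
  tests yield log2 fold changes and p-values; the substrate filter is
  **FC > 1.25, p < 0.01, ≥ 1 KFERQ-like motif**, and substrate sets are
  compared with the Jaccard index |A∩B|/|A∪B|.
- **Set-enrichment statistics** (`enrichmentScore()`, `permutationTest()`,
  `ora()`, `setSimilarityFilter()`): the weighted Kolmogorov–Smirnov
  running-sum enrichment score with gene-set permutation nulls (NES,
  add-one-smoothed p), hypergeometric over-representation with
  Benjamini–Hochberg correction, and Jaccard-filtered similarity edges
  between result sets (default cut 0.25).
- **Synthetic data with known truth** (`simulateProteome()`,
  `simulateExpression()`, `simulateNlExperiment()`): seeded generators of
  motif-bearing proteomes, network-shifted expression matrices and paired
  control/N-L experiments with planted substrates, used to validate every
  stage end-to-end.
- **Pipeline** (`runPipeline()` and the CLI at
  `system.file("cli", "cmaflux.R", package = "cmaflux")`): scan →
  differential test → motif-gated substrate call → ORA, with a reproducible
  JSON manifest.

## Worked example

Classify a window, then run a seeded N/L experiment through the substrate
caller and compare the calls with the planted truth:

```r
library(cmaflux)

classifyWindow("QKILS")
#>          motifClass anchorTerminus ptmPosition
#> 1 phospho_generated           left           4

sim <- simulateNlExperiment(nProteins = 300, fracSubstrates = 0.1,
                            accumulationFC = 2, noiseSd = 0.1,
                            nDonors = 5, seed = 7)
diff <- rowwiseTest(sim$quant)                     # paired per-donor t-tests
called <- callSubstrates(diff, sim$motifs, label = "N/L demo")
called
#> SubstrateCallSet 'N/L demo' : 30 of 300 tested proteins called
#>   filter: FC > 1.25 ( up ), p < 0.01 , KFERQ-motif required

ov <- overlapSets(substrateIds(called), sim$truth$substrates)
round(ov$jaccard, 4)
#> [1] 1
```

The window `QKILS` is phosphorylation-generated: with the serine (0-based
position 4) recounted as the negative residue, the left-anchored window has
2 hydrophobic, 1 positive and 1 negative residue. In the simulated
experiment all 30 planted substrates — 10% of 300 proteins, accumulating
2-fold under N/L — are recovered with no false calls, so the called set and
the truth overlap with Jaccard index 1.

## Documentation

The methods vignette (`vignettes/cma-substrate-discovery.Rmd`) describes the
statistical models, the default parameters and their rationale, what the
synthetic generators do and do not emulate, and known limitations.
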