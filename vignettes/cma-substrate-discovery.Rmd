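---
title: "Methods: CMA substrate discovery, motif scanning and activity scoring"
author: "cmaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CMA substrate discovery, motif scanning and activity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaflux)
```

# Scope

Chaperone-mediated autophagy (CMA) degrades proteins bearing a KFERQ-like
targeting motif: HSC70 recognises the pentapeptide, and the substrate is
translocated into the lysosome through LAMP-2A, the rate-limiting receptor
encoded by a splice variant of *LAMP2*. This vignette documents the
statistical models behind the package's four analysis stages — motif
scanning, transcriptional activity scoring, lysosomal-flux differential
proteomics, and set-enrichment statistics — together with the synthetic-data
generators used to validate them, the defaults that matter, and the
numerical conventions adopted where the design was genuinely open.

# KFERQ-like motif model

## Rule set

A 5-residue window is **canonical** when one terminus holds the anchor Q and
the remaining four residues comprise 1–2 hydrophobic (F, I, L, V), 1–2
positively charged (K, R) and exactly one negatively charged residue (E, D),
with all four residues accounted for by the three classes. Two
post-translational extensions create non-canonical motifs:

* **phosphorylation-generated** — one S/T/Y, recounted as the negative
  residue once phosphorylated, completes an otherwise non-canonical window
  (the terminal Q is still required). Because the four non-anchor residues
  must be fully classed, at most one S/T/Y can be present, so "exactly one
  substitution" is implied rather than enforced separately;
* **acetylation-generated** — a terminal K, recounted as the anchor once
  acetylated, with the remaining four residues satisfying canonical
  composition as-is.

Exactly one PTM substitution is admitted per window per classification;
combined phospho+acetyl windows are not reported (the three-class scheme is
standard in the field's figures). A window already canonical at an anchor is
not additionally reported as PTM-generated for that anchor — automatic for
phosphorylation (canonical needs one negative residue, the phospho rule
none) and vacuous for acetylation (the terminus holds K, not Q).

The rule table is a first-class object (`MotifRuleSet()`): classifier
dialects differ in details such as whether asparagine may surrogate for the
anchor or whether two negative residues are tolerated, so every residue
class and count range is configurable. We implement the strict rule above as
the default and make no attempt to guess other dialects.

```{r}
classifyWindow("KFERQ")
classifyWindow("KFERK")  # terminal K as acetyl-anchor; both termini qualify
```

Note that `KFERK` admits the acetylation-generated class at *both* termini:
each terminal lysine, taken as the anchor, leaves four residues (1
hydrophobic, 2 positive, 1 negative) in canonical composition. The scanner
reports every classification a window admits.

## Conventions and degenerate inputs

* Input is case-insensitive; coordinates are 0-based half-open in memory and
  1-based closed in written reports (`writeMotifHits()`).
* Windows containing ambiguity letters (X, B, Z, U, O, J, `*`) are voided
  individually — conservative and local — with a logged notice; the rest of
  the protein is still scanned. A wrong-length window is an error.
* Sequences shorter than five residues yield no hits; overlapping hits are
  all reported.

## Summaries and reference comparison

`summarizeMotifs()` counts motif-bearing proteins per class. Inclusive
counting (a protein counts toward every class it contains) is the default,
since published abundance bar charts do not state their convention;
exclusive counting (priority canonical > phosphorylation-generated >
acetylation-generated) is available. `compareToReference()` contrasts two
summaries class-by-class with a two-sided exact conditional (Fisher) test on
the 2×2 contains/total table and Benjamini–Hochberg adjustment across
classes. The test is a deliberate choice: abundance comparisons against a
reference proteome are usually plotted without a named test, and an exact
test is safe at any count, including zero cells (odds ratios then carry a
Haldane 0.5 continuity correction, flagged in the output).

A useful null constant: the exact fraction of the $20^5$ standard-residue
windows that are canonical, `canonicalWindowFraction()`, computed once by
enumeration and cached (0.072% under the default rules). Random-sequence
backgrounds converge to it within binomial error, which the test suite
checks.

# Transcriptional CMA score

The score summarises the CMA network — effectors plus positive and negative
modulators — into one number per sample:

$$\mathrm{score}_s = \frac{\sum_g d_g\, w_g\, z_{gs}}{\sum_g w_g},$$

with direction $d_g = +1$ for effectors/positive modulators and $-1$ for
negative modulators, weight $w_g = 1$ except LAMP2 ($w = 2$, the limiting
effector), and $z_{gs}$ the per-gene z-score of log2 expression across
samples. Raw counts are transformed $x \mapsto \log_2(x+1)$ first.

Design choices:

* **Per-gene z-scoring before averaging.** The formulation circulating in the literature specifies only a
  log2-normalised, weighted, directed average; z-scoring makes genes of
  different expression magnitude commensurable — without it the weighted
  average would be dominated by highly expressed genes and the LAMP2 weight
  would be meaningless. The **population** (n-denominator) SD is used so
  that tiny fixtures are deterministic (two samples give z = ±1 exactly).
* **Membership is configuration, not code.** The shipped default network
  (`defaultCmaNetwork()`, 18 genes) follows the field's curated picture of
  the CMA network — chaperone-machinery effectors (LAMP2, HSPA8, HSP90AA1,
  DNAJB1, BAG1, ST13, HSPA4, CTSA), positive modulators (NFE2L2, PHLPP1,
  RAC1, GPER1) and negative modulators (RARA, AKT1, MTOR, RICTOR, GFAP,
  EEF1A1). Published heatmaps do not list their exact membership, so the
  table is an editable TSV and the score operation is membership-agnostic.
* **Degenerate genes.** Network genes absent from the matrix are dropped
  silently with a recorded reason; zero-variance genes (common in sparse
  single-cell fixtures) are dropped with a warning. The weight normaliser is
  recomputed over the genes actually used; if none survive, the score
  errors rather than fabricating zeros.
* **Single-cell input** is scored per cell on the log-normalised matrix;
  cluster-level summaries are ordinary downstream aggregation of the
  per-cell scores.

Consequences used as test invariants: scores are invariant to per-gene
location/scale changes, average to zero across samples when all genes are
used, negate under direction flip, and a weight-2 gene moves the score
exactly twice as much per unit z as a weight-1 gene.

Group comparison (`scoreGroups()`) reports means ± s.e.m. and a two-sided
*unpaired Student's* (equal-variance) t-test, the convention for two-group
donor comparisons in this literature.

# N/L flux proteomics and the substrate caller

Blocking lysosomal proteolysis (20 mM NH₄Cl + 100 µM leupeptin, "N/L")
makes lysosomal-degradation substrates accumulate. The caller operationalises
this in three steps:

1. **Row-wise tests** (`rowwiseTest()`). Paired design (the default whenever
   donor ids are present, since donor lines are the experimental unit):
   per-donor log2 differences NL − control, one-sample t-test. Unpaired:
   Welch's t. log2FC is the mean difference. Raw-scale inputs are
   log2-transformed and median-centred per sample (standard label-free
   practice; optional). **No imputation** — imputation would inject
   untestable assumptions; instead proteins need ≥ 2 quantified values per
   group (or ≥ 2 complete donor pairs) and are otherwise flagged
   (`insufficient_n`, `one_condition_only`). Zero-variance rows with unequal
   means report the limiting p = 0 with a `degenerate_variance` flag rather
   than NaN.
2. **The filter** (`callSubstrates()`): linear FC > 1.25 in the accumulation
   direction, raw p < 0.01, and ≥ 1 KFERQ-like motif. The p-value is
   deliberately unadjusted — the conventional filter uses a raw cut — but BH
   q-values are reported alongside for transparency. Enrichment is
   one-directional by default (inhibitor logic reveals substrates as
   *accumulating*); `direction = "both"` is available. The filter is
   monotone: relaxing either threshold, or removing the motif gate, can only
   enlarge the called set.
3. **Overlap** (`overlapSets()`): exact set arithmetic and the Jaccard index.
   As a worked identity, substrate sets of sizes 171 and 328 sharing 118
   members give J = 118/381 = 0.3097.

# Set-enrichment statistics

* `enrichmentScore()` implements the weighted running-sum
  (Kolmogorov–Smirnov-like) statistic: sorted by score (descending, ties
  stable by input position), hits add $|s|^p / N_R$, misses subtract
  $1/(N-N_h)$; ES is the signed maximum deviation. When the largest positive
  and negative deviations tie in magnitude (to within rounding) ES is
  defined as 0 — this keeps the statistic exactly antisymmetric under
  ranking reversal, which floating-point tie-breaking by position would
  violate. The default ranking metric for proteome-wide analyses is signed
  log2FC (the t-statistic is an equally defensible choice and can be
  supplied instead).
* `permutationTest()` draws null member sets of the same size from the
  ranked universe (gene-set permutation, null sets drawn at the
  gene-set's size), normalises by the mean |null ES| of matching
  sign (sign-stratified NES), and reports an add-one-smoothed empirical
  p-value, so $p \ge 1/(n_{perm}+1)$ (default $n_{perm} = 1000$). Fixed
  seeds give bit-identical results and leave the caller's RNG untouched.
* `ora()` is the hypergeometric upper tail $P(X \ge k)$ of the query/set
  overlap within the tested background, BH-adjusted across sets. Sets are
  intersected with the background before testing, and the query must be a
  subset of the background. (The g:SCS-style bespoke correction of some web
  tools is out of scope; BH is the transparent standard.)
* `setSimilarityFilter()` emits Jaccard ≥ 0.25 edges between member sets,
  the conventional enrichment-map edge filter; network visualisation itself
  is left to dedicated tools.

# Synthetic data: what it emulates, and what it does not

The generators produce the three input classes of the pipeline as pure
functions of (configuration, seed):

* `simulateProteome()` — background sequences are **rejection-sampled** from
  the uniform 20-letter alphabet until motif-free (rather than restricting
  the alphabet, which would distort composition); planted sequences receive
  one pentapeptide of the assigned class at a random interior position and
  are re-drawn until the scanner recovers exactly the assigned class, so
  planted fractions are recovered *exactly*. A cap on rejection iterations
  errors with advice to shorten sequences.
* `simulateExpression()` — Gaussian log2 expression with a group shift of
  $-d_g\,\delta$ on every network gene in the second group, i.e. effectors
  down and negative modulators up, the signature of reduced CMA. Defaults:
  200 genes, 10 samples/group, $\delta = 1$ log2 unit, noise SD 0.5 —
  a clearly detectable but noisy bulk contrast.
* `simulateNlExperiment()` — the conventional label-free error model:
  log-normal intensity noise (Gaussian on log2), additive log2 effects,
  donors as random offsets (SD 0.3) so the paired test has real structure to
  exploit. Substrates gain $\log_2(\mathrm{FC})$ under N/L only.
  Non-substrates are motif-positive at rate 0.45, the approximate
  canonical-motif prevalence of the human proteome, so false calls must pass
  the motif gate at a realistic rate. The benchmark design used in the
  acceptance checks — FC 2, noise SD 0.1, 5 donors, 500 proteins, 50
  replicates, with a matched FC 1 null — reflects the strong
  signal-to-noise of targeted lysosomal-inhibition experiments.

These fixtures validate *statistical machinery*, not biology: they contain
no peptide-to-protein inference, no intensity-dependent missingness, no
correlated protein modules, and real mRNA counts are not Gaussian. Passing
tests therefore demonstrate that each stage recovers what was planted under
its own model assumptions — they do not certify performance on real
proteomes, where effect sizes are heterogeneous and missingness is
informative.

# Problem sizes and numerical choices

The test suite runs the scanner-versus-oracle comparison on 1,000 random
sequences (length ≤ 60), the full $20^5$ window enumeration once, 50-replicate
benchmark and null N/L designs, and 100-replicate score-symmetry sweeps —
sizes chosen so the whole suite completes in a few minutes while keeping
Monte-Carlo error well below the asserted margins. Exact fixtures are
asserted at 1e-12; t-tests are cross-checked against `stats::t.test` row by
row at the same tolerance.

# Known limitations

* Distinguishing CMA from endosomal microautophagy or macroautophagy is not
  attempted computationally: both degrade KFERQ-bearing proteins, and the
  comparative-inhibitor algebra (e.g. subtracting an autophagosome-inhibitor
  condition) is left to the user.
* The motif rules are sequence-only: structural accessibility of the motif
  and HSC70 binding are out of scope.
* The default CMA network membership is a curated, editable choice; results
  should be reported together with the network table used.
* The exact canonical-window frequency and all oracle constants refer to the
  default rule dialect; custom rule sets recompute them (cached per dialect).

# Session info

```{r}
sessionInfo()
```
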