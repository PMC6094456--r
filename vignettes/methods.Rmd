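---
title: "Methods: metabolite-correlated co-expression networks in teanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolite-correlated co-expression networks in teanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teanet)
```

`teanet` relates metabolite contents measured across a panel of tea-plant
tissues to gene co-expression modules estimated from one pooled RNA-seq
library per tissue. This vignette is the package's own account of the
statistical procedure: the model behind each stage, the parameters that
matter, the numerical conventions, and what the validation on synthetic
data does and does not establish.

## Study design and its consequences

The design the package targets has one sequencing library per tissue
(around ten tissues), each library a pool of equal RNA amounts from
biological replicates. Two consequences shape the methods:

* **No replicate-level dispersion.** With one library per condition, count
  models with a free dispersion parameter cannot be estimated. The
  Audic–Claverie exact test, which compares two single counts given their
  library totals, is the appropriate tool; its p-values describe sampling
  noise only, not biological variability, and with deep libraries almost
  any truly regulated gene is declared differential. The DEG stage is
  therefore a *screen* that defines the network gene set, not an
  inferential endpoint.
* **Few samples (n ≈ 10).** All correlations (gene–gene, eigengene–trait)
  rest on ten observations. This motivates the very high soft threshold
  (β = 30) that suppresses the substantial background correlation noise at
  this n, and it is why trait significance uses the exact Student-t null
  rather than asymptotics alone.

## Quantification

FPKM is computed as `count × 1e9 / (length_bp × library_size)`, with
library sizes defaulting to column sums; callers counting paired-end data
must supply fragment totals. Two filters with distinct roles:

* `filter_low_expression(tau = 0.3, max_low = 8)` removes a gene when its
  FPKM falls below 0.3 in at least eight of ten tissues. The phrasing "low
  in at least eight" (rather than "expressed in fewer than k") is chosen
  deliberately so that tissue-specific genes — strongly expressed in two
  or three tissues only — survive. Both knobs are exposed.
* `flag_expressed(tau = 0.3)` merely counts, per tissue, genes with
  FPKM ≥ 0.3 (inclusive boundary) for reporting.

Network input is `log10(FPKM + 1)`. The pseudocount of 1 maps zero FPKM to
exactly zero and keeps the transform monotone; it is configurable. Raw
FPKM correlation is possible by skipping `log_transform()`, but log scale
is the default because expression spans orders of magnitude across tissues
and Pearson correlation on the raw scale would be dominated by the highest
values.

## Differential expression

For libraries with totals N₁, N₂ and one gene's counts x, y, the
Audic–Claverie kernel

p(y | x) = (N₂/N₁)^y · (x+y)! / ( x! · y! · (1+N₂/N₁)^(x+y+1) )

is exactly a negative binomial in y with size x+1 and success probability
N₁/(N₁+N₂); the implementation evaluates tails through the log-space
negative-binomial CDF, and the unit tests check it against an independent
term-by-term log-gamma summation of the kernel. The two-sided p doubles
the smaller inclusive tail and caps at 1.

Two numerical conventions worth making explicit:

* **Exchange asymmetry.** Because the kernel conditions on the *first*
  library's count, swapping `(x, N₁)` with `(y, N₂)` shifts the tail by
  one point mass of the discrete kernel. The two orientations agree
  closely for moderate counts (the suite bounds the ratio) and exactly at
  the centre of symmetry, but not identically in deep tails. We keep the
  literal conditional form rather than an ad-hoc symmetrisation, and
  document the convention.
* **Per-comparison FDR.** Benjamini–Hochberg runs within each pairwise
  comparison (its own p-value family), matching the per-comparison DEG
  convention; genes differential in at least one of the 45 pairs form the
  union used for the network. Pooling families across comparisons would
  change individual q-values but is not offered as a default because the
  calling convention is per comparison.

The log₂ ratio uses library-normalised counts with pseudocount 1 on both
sides, so zero counts stay finite and the ratio is antisymmetric under
library exchange. Default thresholds: |log₂ ratio| ≥ 1, q < 0.05 (strict).

## Network construction

* **Adjacency.** Unsigned, `a_ij = |r_ij|^β`, by default. The choice of
  unsigned is deliberate: content relationships of interest include both
  positive and negative correlations, and an unsigned network lets
  anti-correlated genes share modules whose eigengene then correlates
  negatively with a trait. A signed option (`((1+r)/2)^β`) is available.
* **Soft threshold.** Default β = 30. `pick_soft_threshold()` scans
  candidates and returns the smallest with signed scale-free fit R² ≥ 0.8,
  falling back to the default when none qualifies — which is the typical
  outcome at n = 10, where the correlation noise floor keeps the degree
  distribution from looking scale-free at low powers. The fit discretises
  connectivity into 10 equal-width bins, regresses log₁₀ frequency on
  log₁₀ mean connectivity over non-empty bins, and signs R² by the
  negative of the slope's sign so that an *increasing* frequency–degree
  relation scores negatively.
* **TOM.** `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)` with
  `l_ij = Σ_{u≠i,j} a_iu a_uj`, computed via one matrix product; the test
  suite checks it against a literal double-loop oracle at 1e-10.
* **Module detection.** Average-linkage clustering of `1 − TOM`, then a
  *static* cut at `cut_fraction` (default 0.99) of the maximum merge
  height; clusters smaller than `min_module_size = 30` become
  "unassigned"; surviving clusters are relabelled M1, M2, … by decreasing
  size. The reference adaptive ("dynamic") tree cut is intentionally not
  replicated: the static cut plus size filter plus eigengene merging is
  simpler, fully specified, and is validated by planted-module recovery
  rather than label-for-label agreement with any particular
  implementation. Ties in merge heights can leave float-level height
  inversions in the agglomeration record; `cut_modules()` clamps
  inversions below 1e-8 (relative) and refuses anything larger.
* **Eigengenes and merging.** A module eigengene is the first right
  singular vector of the row-standardized module submatrix,
  restandardized to mean 0 / SD 1 and sign-aligned so its correlation
  with the module's mean standardized profile is non-negative (the SVD
  sign is otherwise arbitrary). Modules merge iteratively while the
  smallest eigengene dissimilarity `1 − cor` is below
  `merge_cut = 0.25`, with eigengenes recomputed after every merge;
  merging happens *before* trait correlation, so reported modules are the
  merged ones.
* **Connectivity and hubs.** `k_within(g)` sums a gene's adjacency to the
  other members of its module. Hubs are the top 2% per module with count
  `max(1, ceiling(0.02 × size))` — so even the minimum-size module reports
  one hub — with ties broken lexicographically by gene id for
  determinism. Whole-network connectivity is deliberately not the default
  ranking: hub status is a within-module notion here.

## Module–trait analysis

Pearson correlation between each eigengene and each trait (mg/g contents,
untransformed — their natural reporting scale; a log option can be applied
upstream by the caller), with:

* **p-values** from the Student-t form `t = r√(n−2)/√(1−r²)` on n−2
  degrees of freedom (equivalently the incomplete-beta identity
  `p = I_{1−r²}((n−2)/2, 1/2)`, which the suite verifies at 1e-12).
  `|r| = 1` returns p = 0 with a warning.
* **Confidence intervals** from Fisher's Z: `tanh(atanh(r) ± z*/√(n−3))`,
  always inside (−1, 1).
* **Classification.** Content-related: raw p < 0.05 (strict) for ≥ 1
  trait. Highly significant: additionally |r| ≥ 0.8. BH q per trait column
  is computed and reported, but the classification intentionally uses raw
  p — the convention being mirrored — so users can tighten it themselves
  with the reported q.

## Pathway enrichment

Hypergeometric upper tail `P(X ≥ k)` (evaluated as the `phyper` upper tail
of k−1 — the inclusive convention is stated to avoid the classic
off-by-one) for each (module, pathway) pair with at least one overlapping
gene, BH-adjusted across all tests pooled (per-module families by
option), significant at q < 0.05. The background universe defaults to
annotated genes that entered the network; the full annotation universe is
an option. The unassigned pool is never tested.

## The synthetic-data generator

`sim_config()` defaults encode the emulated design: 10 samples (tissues),
1200 genes of which 6 × 150 lie in planted modules, within-module
gene–eigengene correlation 0.95, log-scale residual SD 0.5, per-gene
baseline log-FPKM ~ N(log 20, 1), transcript lengths uniform on
300–3000 bp, library sizes 2×10⁷ fragments, eight traits named after the
tea metabolites (C, GC, EC, EGC, ECG, EGCG, theanine, caffeine) coupled
round-robin to the planted modules with coupling 0.95 and trait noise SD
0.1 (the last two couplings negative, to exercise sign handling), and 20
pathways with pathway i enriched in module i at odds 10 over a base
membership probability of 0.05. Module gene loadings take either sign
with probability ½. Counts are Poisson around
`FPKM × length × library_size / 1e9`. Each generator call seeds its own
RNG stream (expression, traits and annotation use deterministic seed
offsets), so identical configurations give bit-identical outputs.

What this emulates: planted correlation structure driven by latent sample
profiles, traits that are noisy linear functions of those profiles,
annotation enrichment, Poisson counting noise, realistic FPKM dynamic
range. What it does not: replicate-level biological variability (the
pooled design has none to emulate), over-dispersion beyond Poisson,
correlated background genes, isoform/length ambiguity, and mapping
artefacts. Passing the recovery suite therefore shows the pipeline is
correct and well-calibrated *under its own stated model*, not that any
particular biological dataset will yield equally clean modules.

Validation problem sizes were chosen to exercise every stage while staying
desk-scale: 1200 genes × 10 samples for end-to-end recovery (adjusted Rand
index and per-module Jaccard against the planted truth, checked in the
test suite), 50 seeds for the trait-coupling classification rate, 10,000
null genes for the count-test calibration, and ~2,400 null cells for the
module–trait false-positive rate. These are the same sizes
`scripts/acceptance.R` reruns.

## Known limitations

* The static cut assumes modules separate at a common dendrogram height;
  nested or strongly unbalanced module structure is handled less
  gracefully than by adaptive cutting, and background genes are identified
  only insofar as they merge above the cut.
* With n = 10, module–trait p-values are exact under normality but the
  5% screen is liberal across a large grid; the reported per-trait q
  column is the tool for stricter control.
* The DEG stage inherits the pooled design's blindness to biological
  replication; its union should be read as "genes with tissue-dependent
  expression", not as a validated DEG list.
* Desk scale targets ≤ ~10k network genes (dense TOM is O(p²) memory,
  O(p³) time); block-wise decomposition is out of scope.
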