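---
title: "hotsig: models, nulls and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hotsig: models, nulls and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotsig)
```

`hotsig` analyses cohorts of somatically mutated tumors for focal
gain-of-function mutation patterns — the kind exemplified by the
NRF2/KEAP1 axis, where mutations concentrate on single residues,
constitutively activate a transcriptional program, and leave a
detectable expression signature. This vignette documents the
statistical machinery: what each stage assumes, which parameters
matter, how the synthetic-data generator is built, and where the
procedure was genuinely underdetermined and a design decision had to be
taken.

## Consensus mutation cataloguing

Multi-caller somatic call sets disagree; a standard compromise between
sensitivity and specificity is to keep mutation records reported by at
least two of the four callers (MuSE, MuTect2, SomaticSniper, VarScan2).
`merge_caller_calls()` keys records by
(case, gene, chromosome, position, ref, alt) — case identity being the
first 12 characters of the TCGA-style barcode, the participant
convention — unions the reporting callers per key, and drops keys below
`min_callers` (default 2). Raising the threshold can only remove
records (a property the test suite checks), and duplicate keys within
one caller's table are deduplicated with a warning rather than counted
twice.

Substitutions are classified as transitions ({A,G} or {C,T} exchanges)
or transversions (everything else); the classification is invariant
under complementation of both bases, so it does not depend on the
reported strand. Burden counts mutation *events* per case, not unique
positions. "Non-synonymous" throughout means every variant class except
`silent` and `other`; the MAF `Variant_Classification` vocabulary is
mapped onto {missense, nonsense, frameshift, inframe_indel, splice,
silent, other}.

Two small inferential tools live here:

* `overlap_test()` asks whether two case sets (say, NRF2-mutant and
  KEAP1-mutant cases) share more cases than random subsets of the
  cohort would. The exact mode is the hypergeometric upper tail
  P(X ≥ k); the Monte-Carlo mode draws `m` random subset pairs and
  reports (b + 1)/(m + 1). Both report the expected overlap K·n/N.
  Sampling is unconditional on tumor type; stratified resampling is not
  implemented.
* `burden_comparison()` compares burden between activated and
  non-activated cases per tumor type with a two-sided Mann–Whitney U
  test — exact for group sizes up to 8 without ties, normal
  approximation with continuity correction otherwise — followed by
  Benjamini–Hochberg adjustment across types. The choice of
  Mann–Whitney is a design decision: the comparison is framed in terms
  of medians and no parametric form of the burden distribution can be
  assumed.
* `pearson_fisher_test()` reports Pearson's r with a two-sided p-value
  from the Fisher transform, z = atanh(r) scaled by sqrt(n − 3) against
  a standard normal; it therefore requires at least 4 paired
  observations and returns an explicit NA (with a warning) under zero
  variance.

## Monte-Carlo hotspot enrichment

The hotspot question is positional: does codon *j* of a protein of
length L carry more of the gene's n nonsynonymous events than a uniform
placement would give it? The permutation null redistributes the n
observed events independently and uniformly over the L codons; for each
tested position, b counts the permutations whose count at that position
reaches the observed one, and the estimated p-value is the add-one
estimator

> p̂ = (b + 1)/(m + 1),

which is never smaller than 1/(m + 1) and is a valid p-value for any m.
The default permutation depth is m = 10⁵, which resolves p-values down
to 10⁻⁵ in well under a minute; m = 5×10⁶ (resolving 2×10⁻⁷) remains
available through the `m` argument when publication-grade floors are
needed. Three decisions are worth making explicit:

* **What is permuted.** Events are pooled across cases and
  redistributed uniformly over codons; per-case mutation multiplicity
  is not preserved. This is the simplest null consistent with asking
  whether a *position's frequency* is surprising, but it is a choice —
  a per-case permutation scheme would be equally defensible.
* **The BH family.** Only positions with at least one observed event
  are tested and enter the Benjamini–Hochberg correction, per gene.
  Zero-count positions can never be called enriched and would only
  dilute the correction. A consequence on sparse synthetic data: when a
  605-codon gene carries only a couple dozen events, even a single
  event at a position is individually unlikely under the uniform null
  (p ≈ n/L), so singleton positions can sit near the 0.05 boundary;
  with realistically dense cohorts this effect vanishes.
* **Batching.** Permutations are drawn in memory-bounded chunks, but
  the draw sequence depends only on (seed, m, counts) — chunk size
  never changes a result.

`tumor_type_enrichment()` asks the analogous question across tumor
types: the k cases mutated at one position are drawn without
replacement from the pool of all gene-mutant cases, and each type's
draw count is compared with its observed count, with the same estimator
and BH adjustment. `hotspot_transversion_bias()` tests transversion
excess at hotspot positions with a one-sided Fisher's exact test on the
2×2 table (hotspot/other × transversion/transition); empty margins
return p = 1 with a warning rather than an error, since sparse genes
legitimately produce them.

## Activation-signature derivation

The signature stage assumes a training set of activated tumors and
normal tissues spanning two tumor types (the packaged
`training_design()` picks 12 + 12, balanced 6 + 6 per type, mirroring
the usual training split). Four steps:

1. **Variance-stabilizing transform.** Median-of-ratios size factors —
   geometric-mean reference over the genes nonzero in every sample,
   factors rescaled to geometric mean 1 — followed by
   log2(count/size factor + 1). When no gene is nonzero everywhere the
   transform falls back to total-count scaling with a warning. The
   geometric-mean rescaling is a convention: size factors are only
   defined up to a common constant, and any rescaling shifts the
   transformed matrix by a constant number of log2 units without
   affecting differences, rankings, distances or any downstream result.
2. **Differential-expression filter.** Per-gene Welch t-tests on the
   transformed values, BH-adjusted; genes pass with q < 0.05 and
   |log2 mean difference| ≥ 2.5. This stage is deliberately pluggable
   (`derive_signature(..., de_table = )`): any externally computed
   table — e.g. a negative-binomial model fit — can be substituted, and
   the built-in Welch filter makes no claim to reproduce one. Genes
   constant in both groups get p = 1 when the means agree and p = 0
   otherwise.
3. **Tumor-type-bias ranking.** For each candidate gene, d_r is the
   difference in mean transformed expression between the two tumor
   types, computed **over the training tumors only** (normals carry no
   tumor-type biology of interest and would dilute the contrast — a
   decision, since the mean could also be taken over all training
   samples). Genes are ranked by increasing |d_r|, ties broken
   alphabetically, so the least type-confounded genes lead the list;
   planted batch-effect genes rank last and are excluded by
   construction before the signature can absorb them.
4. **Sequential MLS maximization.** For k = 2, 3, …, the top-k genes
   are used to Ward-cluster the training samples (Euclidean distance,
   Ward linkage, dendrogram cut at 2 clusters), and each k is scored
   with MLS = L_Inter/L_Intra, where L_Inter is the Euclidean distance
   between the normal-group and tumor-group centroids and L_Intra the
   mean over clusters of the mean within-cluster pairwise distance
   (singletons excluded; L_Intra = 0 returns the sentinel `Inf`). The
   selected size is the smallest k attaining the maximum. Centroid /
   mean-pairwise is one of several defensible readings of "intergroup"
   and "intragroup distance" (average linkage-style pairwise distances
   or dendrogram heights being the alternatives); all of them share the
   scaling behaviour discussed next.

### Why the MLS trace is flat on homogeneous planted effects

On synthetic data in which every planted signature gene carries the
same effect size and comparable noise, the MLS trace has no interior
maximum: both L_Inter and L_Intra are Euclidean lengths over k
coordinates and grow like √k, so their ratio is asymptotically constant
in k (to first order it *declines* like 1 + 1/(4k), and the Monte-Carlo
fluctuations are largest at small k). The argmax therefore tends to sit
at k = 2–3 regardless of how many genes were planted. This is a
geometric property of any distance-ratio score, not an implementation
artifact. An interior maximum — the behaviour seen on real cohorts,
where a specific gene-set size wins clearly — requires *heterogeneous*
per-gene signal: as genes are added in rank order the average
signal-to-noise of the set must first rise and then fall. The test
suite demonstrates both regimes: on a constructed fixture with varying
per-gene effects the selection recovers exactly the informative prefix,
while on homogeneous planted effects the selected set is a (correct but
small) subset of the planted genes. Users simulating benchmark data for
this stage should plant effect-size profiles, not a single effect.

## Cohort stratification

`stratify_cohort()` Ward-clusters all samples on the signature genes,
cuts at exactly k = 3 — the natural reading of a
normal/active/inactive split — and designates groups by rule: G1 is the
cluster with the highest fraction of normal tissue, G2 the remaining
cluster with the higher mean signature expression (up-regulated
signature genes only, when effect signs are available), G3 the other.
Ties send the larger cluster to G3, with a warning, so designation is a
deterministic function of the partition, the tissue flags and the
means. Mutant enrichment in G2 versus G3 is a one-sided Fisher's exact
test (a deterministic choice; the Monte-Carlo machinery of the hotspot
module could equally be used), applied separately to any set of mutant
flags — NRF2 mutants, KEAP1 mutants, carriers of a single hotspot
position, and so on.

## Codon substitution spectra

Every codon has exactly nine single-nucleotide neighbors.
`single_substitution_variants()` enumerates them against the standard
genetic code (translation table 1 — these are human nuclear genes) and
classifies each as synonymous, nonsense or missense; for the CGA codon
(arginine, e.g. NRF2 R34) the missense outcomes are exactly
{G, Q, P, L}. `variant_spectrum_bias()` tests an observed spectrum of n
events at one position against the null that each event picks one of
the nine substitutions uniformly, aggregated to amino-acid outcomes;
enrichment is the upper tail and depletion the lower tail, both with
the (b + 1)/(m + 1) estimator and BH adjustment across the missense
outcomes. Stop-gain outcomes are reported but excluded from testing.
The uniform-substitution null is a decision; because hotspots are often
transversion-driven, a transition/transversion-weighted null is
available through `kappa` (transition substitutions weighted κ : 1).

## Half-life kinetics

Cycloheximide-chase densitometry series (intensities normalized to a
loading control, timepoints in minutes with t = 0 at the start of the
chase) are fitted per construct and replicate by ordinary least squares
of ln(intensity) on time: N(t) = N0·e^(−λt), λ = −slope,
t½ = ln 2/λ. The log-linear fit is closed-form, deterministic, and
exact on noiseless data — the reasons it is the default — with an
optional `nls` refinement on the raw scale behind `nonlinear = TRUE`.
Fits require at least three distinct timepoints (two would be an
interpolation, not a fit), strictly positive intensities, and flag
non-decaying series (slope ≥ 0) with an NA half-life instead of
reporting a negative one. Construct comparisons run on per-replicate
half-lives — each biological replicate is fitted separately and the
replicate t½ values are compared — with a two-tailed Welch t-test by
default (the safer choice when variance equality is unknown; pooled
variance available via `var_equal = TRUE`).

## The synthetic-cohort generator

`sim_config()` + `simulate_mutations()` / `simulate_expression()` /
`simulate_chase()` generate cohorts with the statistical structure the
pipeline assumes, under one global seed from which each stage derives a
deterministic substream (so regenerating only the expression matrix
never perturbs the mutation tables). Defaults describe a
two-tumor-type (LUSC-like vs LUAD-like) cohort of 200 tumors and
24 normals:

* **Mutations.** Per-case true event counts are Poisson (default mean
  8); events fall uniformly over a 40-gene universe — 5 driver genes
  with real protein lengths (NFE2L2 605 codons, KEAP1 624, …) plus 35
  generic passenger genes — so that the fraction of cases carrying a
  driver-gene mutation lands at realistic cohort levels (roughly a
  quarter) instead of saturating. Events in the hotspot gene land on
  the planted codon (NFE2L2 position 34) with probability 0.4,
  otherwise uniformly; hotspot events are always missense with
  alternate residues drawn G : P : Q = 2 : 1 : 1 and L absent, so the
  codon-spectrum stage has a planted bias to find. Substitutions are
  transitions with 2 : 1 odds. Each of the four callers reports each
  true event independently with probability 0.9; spurious events carry
  exactly one caller flag (so the ≥2-caller filter removes exactly the
  spurious set) and never collide with true keys.
* **Activation.** Tumor cases with a nonsynonymous NFE2L2 or KEAP1
  event are activated; random non-mutant tumors are added until 40 % of
  tumors are activated. Mutants are therefore a strict subset of the
  activated group, which is what makes the G2-vs-G3 mutant-enrichment
  test meaningful.
* **Expression.** Counts are negative binomial with variance
  μ + αμ² (α = 0.05), log-normal baselines (median ≈ 100 counts), a
  +4 log2 activation effect on six signature-true genes named after
  canonical NRF2 targets (AKR1B10, AKR1B15, GPX2, TXNRD1, GCLM, GCLC),
  and a +3 log2 LUSC-specific batch offset on six disjoint keratin-like
  genes applied to *all* samples of that type — tumor and normal — so
  that it is a pure tumor-type batch effect which the |d_r| ranking
  must remove and the tumor-vs-normal filter must ignore.
* **Chase series.** N0 = 100, timepoints 0/30/60/90/120 min (harvests
  every 30 minutes), multiplicative log-normal noise (sd 0.1), three
  replicates, with default true half-lives of 15 (wild type), 22
  (R34L), 31/40/49 (other R34 mutants) and 58 (E82G) minutes.

What the generator deliberately does **not** emulate: genomic
coordinates are synthetic (one pseudo-chromosome per gene);
there are no trinucleotide mutational signatures, copy-number events or
isoform structure; expression noise is independent across genes (no
correlated regulatory programs); and signature genes carry *only* the
activation effect, so NRF2-inactive tumors and normal tissues are
identically distributed on them. That last point means separating
inactive tumors from normals (G3 from G1) is not a recoverable feature
of the synthetic data — in real cohorts it rides on residual tumor
biology — and stratification accuracy is therefore assessed as the
sensitivity and specificity of G2 assignment for activated tumors.
Passing tests on this generator show the machinery is correct, not that
the pipeline's thresholds are optimal for any particular real dataset.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale by choice:
permutation depths of 10³–10⁵ (the add-one estimator is valid at any
m), cohorts of 60–600 cases, 500-gene expression matrices, 20-seed
replication for recovery claims, and 300–500-replicate simulations for
error-rate and calibration claims. All of these are arguments, not
constants; scaling m to 5×10⁶ or cohorts to TCGA size changes runtime,
not code paths.

## Known limitations

* The positional null ignores sequence context and codon mutability;
  positions differ in their true mutability, so uniform-null hotspot
  p-values are anti-conservative at highly mutable positions.
* The built-in differential-expression filter is a Welch test on
  transformed counts, adequate for the planted-truth validation it
  serves; for real cohorts, plug in a dedicated count-model DE table.
* The MLS criterion cannot resolve signature size on homogeneous
  signals (see above); its selected set is then a correct subset rather
  than the full signature.
* Monte-Carlo p-values are bounded below by 1/(m + 1); BH-adjusted
  values inherit that floor.
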