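# hotsig

Somatic gain-of-function mutations in the NRF2/KEAP1 axis are focal:
they pile up on a handful of protein residues (the DLG and ETGE motifs
of NRF2, and single positions such as R34), drive constitutive
activation of the NRF2 antioxidant program, and mark tumors with poor
prognosis. `hotsig` implements, as a reusable and fully tested R
pipeline, the computational analyses such a study needs:

* **Consensus mutation cataloguing** — merge MAF-style call sets from
  the four TCGA callers (MuSE, MuTect2, SomaticSniper, VarScan2), keep
  records called by at least `min_callers` of them, classify
  substitutions as transitions/transversions, compute per-case burden,
  mutant case sets, case-set overlaps and burden/activation
  correlations.
* **Monte-Carlo hotspot enrichment** — per-residue enrichment under a
  uniform positional null with the add-one permutation estimator
  *p&#770; = (b + 1)/(m + 1)*, where *b* is the number of permutations whose
  enrichment reaches the observed one out of *m* permutations,
  Benjamini–Hochberg adjusted across tested positions; plus
  tumor-type-restricted enrichment and hotspot transversion-bias
  testing.
* **Activation-signature derivation** — variance-stabilizing transform,
  tumor-vs-normal differential expression filter, ranking of candidate
  genes by increasing tumor-type bias |d_r|, and sequential Ward
  clustering that grows the gene set one gene at a time and scores each
  size with the machine-learning score *MLS = L_Inter / L_Intra*
  (between-group centroid distance over mean within-cluster pairwise
  distance).
* **Cohort stratification** — Ward clustering (k = 3) of all samples on
  the signature genes, designation of G1 (normal), G2 (active) and G3
  (inactive), and one-sided Fisher tests for mutant enrichment in G2
  versus G3.
* **Codon substitution spectra** — enumeration of the nine
  single-nucleotide neighbors of any codon under the standard genetic
  code (for CGA/R34: the missense outcomes are exactly G, Q, P, L) and
  Monte-Carlo enrichment/depletion tests of observed variant spectra.
* **Half-life kinetics** — log-linear fits of cycloheximide-chase
  densitometry to *N(t) = N0·e^(−λt)*, *t½ = ln 2 / λ*, and Welch
  comparisons of replicate half-lives between constructs.
* **A seeded synthetic-cohort generator** — TCGA-like mutation tables
  with controllable caller concordance and spurious singleton calls, a
  planted per-residue hotspot, negative-binomial RNA-seq counts with a
  planted activation signature and a tumor-type batch effect, and noisy
  exponential-decay chase series. Every downstream stage can be
  validated against this planted truth.

## Worked example

```r
library(hotsig)

cfg <- sim_config(seed = 42)              # 200 tumors + 24 normals
sim <- simulate_mutations(cfg)
consensus <- merge_caller_calls(sim$per_caller, min_callers = 2)
nrow(consensus)
#> [1] 1534

counts <- position_counts(consensus, "NFE2L2", protein_length = 605)
enr <- positional_enrichment(counts, m = 100000, seed = 42)
head(enr[order(enr$q), ], 3)
#>   protein_pos observed    b      m        p_hat            q
#> 1          34       10    0 100000 0.0000099999 0.0001699983
#> 2          47        1 4161 100000 0.0416195838 0.0438795612
#> 3          66        1 4387 100000 0.0438795612 0.0438795612
```

The planted hotspot at codon 34 carries 10 of the gene's events; no
permutation out of 100,000 reached it, so its p-value sits at the
estimator floor 1/(m + 1) and it dominates the adjusted ranking.
(Positions seen once are borderline here only because the synthetic
gene carries few events in total.)

```r
expr <- simulate_expression(sim$sample_sheet, cfg)
design <- training_design(sim$sample_sheet)   # 12 tumors vs 12 normals
sig <- derive_signature(expr, design)
sig$trace
#> MLS trace over k = 2..6; selected k = 2 (MLS = 9.05)
#> genes: TXNRD1, GCLM

strat <- stratify_cohort(sig$vst, sig$signature$gene,
                         sim$sample_sheet$tissue == "normal")
strat
#> Cohort stratification (Ward, k = 3)
#>  cluster group size normal_fraction mean_expression
#>        1    G2   80       0.0000000        8.890282
#>        2    G3   37       0.1351351        5.310731
#>        3    G1  107       0.1775701        4.879303

mut <- sim$sample_sheet$case_id %in% mutant_case_sets(consensus, "NFE2L2")
group_enrichment(strat$groups[sim$sample_sheet$case_id], mut)$p_value
#> [1] 4.837002e-05
```

All selected signature genes are planted activation genes and none is a
batch gene; the G2 cluster collects the activated tumors and the
NRF2-mutant cases are strongly enriched in G2 over G3. (Why the MLS
trace tends to stop early on homogeneous planted effects is discussed
in the methods vignette.)

```r
fits <- fit_chase(simulate_chase(sim_config(seed = 42,
  chase_spec = list(half_lives = c(WT = 15, R34L = 22, E82G = 58),
                    timepoints = c(0, 30, 60, 90, 120),
                    noise_sd = 0.1, replicates = 3))))
round(tapply(fits$t_half, fits$construct, mean), 1)
#> E82G R34L   WT
#> 56.6 22.5 15.2
```

With 10 % multiplicative noise and three replicates, the log-linear fit
recovers the three true half-lives (15, 22 and 58 minutes) to within a
few percent; with `noise_sd = 0` the inversion is exact.

## Documentation

See the methods vignette (`vignettes/hotsig-methods.Rmd`) for the
statistical models, the null hypotheses of each permutation test, the
design decisions taken where the procedure was underdetermined, and the
known limitations of the synthetic-data generator.
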