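# revscreen

Transcriptome-reversal drug-repurposing screens with multi-level
meta-regression.

## The problem

For brain disorders with no approved pharmacotherapy — cocaine use
disorder being the motivating case — one discovery route is *signature
reversal*: compare the disease's differential-expression profile, measured
across several brain regions, against a library of compound perturbation
signatures (L1000-style gene-level scores per compound × cell line × dose
× time), and look for compounds whose signatures run *opposite* to the
disease. `revscreen` packages that screen end to end for analysts who want
it reproducible and testable:

1. **Disease input** — per region, three gene categories: all
   differentially expressed genes (BH FDR < 0.05), every curated pathway
   gene regardless of significance, and directly measured landmark genes
   belonging to one of the first two.
2. **Connectivity** — every signature vs. every region × category slice by
   Pearson correlation `r` with sampling variance
   `(1 - r²)² / (n - 1)` over the `n` shared genes.
3. **Meta-regression** — per compound, the multi-level random-effects model

   `r_ij = θ + u_i + w_ij + ε_ij`,  `u_i ~ N(0, τ₁²)` per region/study,
   `w_ij ~ N(0, τ₂²)` per category-within-region, `ε_ij ~ N(0, v_ij)`
   known — estimated by REML (compiled likelihood + analytic gradients),
   with the GLS pooled estimate `M_r`, normal Wald test, and
   Benjamini–Hochberg FDR across the library. Significant negative
   compounds are reversal candidates; positives mimic the disease.
4. **Benchmarking & follow-up** — comparison against a benchmark set
   (e.g. drugs in clinical trials), re-scoring of candidates in
   independent datasets (dose × time or brain region as the single random
   level, FDR within the candidate family), and a pluggable
   prioritization rule (negative everywhere, significant somewhere).
5. **Behavioral statistics** — for the fly validation assay: dye standard
   curves with inverse prediction, type-III factorial ANOVA
   (sex × treatment) via full-vs-reduced comparisons under sum-to-zero
   contrasts, pooled-variance post-hoc t tests, and two-sided Fisher's
   exact tests for seizure incidence.
6. **Synthetic data** — a first-class generator that emulates the
   statistical structure of all inputs (multi-region DE tables with exact
   truth sets, signature libraries with planted pooled correlations and
   region/category variance components, follow-up datasets, behavioral
   records), so the whole pipeline is testable offline.

## Worked example

Plant one reverser (true pooled correlation −0.5) among 19 null compounds,
run the screen, and prioritize against two concordant follow-up datasets:

```r
library(revscreen)

cfg <- sim_config(n_genes = 800, n_compounds = 20,
                  signatures_per_compound = c(3, 3),
                  planted_effects = c(CMPD0007 = -0.5), seed = 42)
sim <- simulate_disease_profiles(cfg)
lib <- simulate_compound_library(cfg, sim)
input <- build_input(sim$profiles, sim$pathway_genes, sim$landmark_genes)
obs <- match_all(lib, input)
cl  <- fdr_classify(meta_screen(obs))
cl$negative[, c("compound_id", "k", "M_r", "se", "p", "p_adj")]
#>   compound_id  k        M_r         se            p        p_adj
#> 7    CMPD0007 18 -0.4966949 0.03195852 1.806611e-54 3.613223e-53

fu <- simulate_followup_dataset(cfg, sim, concordant = TRUE, "invitro")
fus <- list(invitro = followup_score(cl$negative$compound_id, lib,
                                     fu$profiles, dataset_id = "invitro"))
prioritize(cl$negative, fus)
#>   compound_id n_datasets n_negative n_significant mean_abs_M_r rank
#> 1    CMPD0007          1          1             1    0.1914566    1
```

The planted compound is recovered with a pooled correlation within
sampling error of −0.5 (18 observations: 3 signatures scored against the
region × category slices that pass the 10-gene overlap minimum — at this
gene-namespace size the small landmark slices drop out), survives
library-wide FDR control, stays significantly negative in the follow-up,
and ranks first. Null compounds stay unflagged. `run_pipeline(pipeline_config(...))` performs the same staged
flow (including benchmark comparison and behavioral statistics) and
writes each stage's table plus a JSON manifest to disk.

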