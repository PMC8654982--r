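---
title: "Methods: transcriptome-reversal screening with multi-level meta-regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-reversal screening with multi-level meta-regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

`revscreen` implements a connectivity-map style drug-repurposing screen for
disorders characterized by multi-region brain transcriptome changes, with
cocaine use disorder (CUD) as the motivating application. The premise of
signature reversal is simple: if the differential-expression profile of a
disease describes how the transcriptome departs from health, a compound
whose perturbation signature is *negatively* correlated with that profile
may push the transcriptome back, and is therefore a candidate therapeutic.

The screen consumes three kinds of input:

1. **Disease profiles**: per-gene differential-expression statistics
   (signed, log2-fold-change-like) with p-values, one table per brain
   region or study (e.g. dlPFC, hippocampus, midbrain).
2. **A compound signature library**: gene-level perturbation scores for
   each compound measured at a particular cell line, dose and time
   (the shape of L1000 level-5 moderated z-scores restricted to neuronal
   cell types).
3. **Gene sets**: a curated disease pathway (e.g. the KEGG cocaine
   addiction pathway) and the list of directly measured "landmark" genes.

## The disease input: three gene categories

For each region the query input is assembled in three categories:

* `DEG` — every gene at Benjamini–Hochberg FDR < 0.05 in that region;
* `PATHWAY` — every curated pathway gene present in the profile,
  *regardless of significance*. The pathway category targets the disease's
  behavioral biology rather than statistical extremity; we read the
  category definition literally and apply no significance filter.
* `LANDMARK` — directly measured genes that already belong to at least one
  of the first two categories, guarding against imputation error.

Each region × category pair (a *cell*, labelled e.g. `PATHWAY_dlPFC`)
becomes one grouping unit of the downstream model. Gene symbols are
upper-cased, and duplicate symbols within a profile collapse to the
smallest-p row, so the mapping from symbols to rows is deterministic.

The correlated disease quantity is the signed effect statistic. The
original description leaves open whether a t-statistic or fold-change was
correlated; both enter identically here (any affine transform of either
vector leaves a Pearson correlation unchanged), so the choice is
immaterial to the screen's conclusions.

## Connectivity scoring

Every signature is scored against every cell by the Pearson
product-moment correlation $r$ over the shared genes (sorted by gene id),
with the large-sample sampling variance on the raw correlation scale

$$\widehat{\mathrm{var}}(r) = \frac{(1 - r^2)^2}{n - 1},$$

where $n$ is the gene overlap. A Fisher-z route
($z = \operatorname{atanh} r$, variance $1/(n-3)$) is available behind
`variance_method = "fisher_z"`; the test suite asserts it reproduces the
same signs and the same FDR classification. Observations with fewer than
10 shared genes (`min_overlap`) are dropped and logged: the variance
formula is unstable at tiny overlaps. Correlations of exactly $\pm 1$ are
reported as such but clamped to $|r| \le 0.999999$ inside the variance
formula so every observation keeps a positive variance.

## The multi-level meta-regression

For one compound with effect observations $r_{ij}$ (signature × cell) the
model is

$$r_{ij} = \theta + u_i + w_{ij} + \varepsilon_{ij}, \qquad
u_i \sim N(0, \tau_1^2),\; w_{ij} \sim N(0, \tau_2^2),\;
\varepsilon_{ij} \sim N(0, v_{ij}),$$

with $u_i$ a random effect per region/study, $w_{ij}$ a random effect per
category-within-region (cells are encoded as composite
`region:category` keys so they nest uniquely), and $v_{ij}$ the known
sampling variances. $\tau^2$ parameters are estimated by restricted
maximum likelihood; $\theta$ is the generalized least-squares mean at the
REML solution, $z = \theta / \mathrm{se}(\theta)$, and the two-sided
normal p-value is reported (the metafor-style default; a
Knapp–Hartung-type small-sample adjustment is deliberately not the
default, to match standard practice for this screen).

Numerical choices:

* Optimization is bounded quasi-Newton (L-BFGS-B) on
  $\log \tau^2 \in [\log 10^{-10}, \log 10]$ with analytic gradients
  (compiled, using the Woodbury identity for large observation counts) and
  five deterministic restarts, the fifth a moment-based start; the best
  restart is polished at tight tolerance.
* Convergence is declared when the projected gradient norm is below
  `1e-6`; at the $\tau^2 = 0$ boundary the KKT condition (outward-pushing
  gradient) is used, because the profiled likelihood is flat to within
  numerical precision near the boundary.
* A random level observed with a single group (e.g. a follow-up dataset
  with one region) is dropped from estimation: its variance is not
  identifiable under REML — the restricted likelihood is exactly flat in
  it — and retaining it would make the reported standard error depend on
  an arbitrary start value.
* Observations are canonically sorted internally, so the fit is exactly
  permutation invariant.
* Non-converged compounds are excluded from the FDR family and reported
  separately, with the family size logged.

Compounds are classified by BH-adjusting the per-compound Wald p-values
jointly across the library: significant compounds with $\theta < 0$ are
reversal candidates; significant positives mimic the disease profile.
Benchmark compounds (e.g. drugs currently in clinical trials for the
disorder) are reported with their pooled estimates, adjusted p-values and
a flag for membership in the negative set; benchmark compounds absent from
the library are listed rather than silently ignored.

## Follow-up and prioritization

Candidates are re-scored against independent datasets (an in vitro
neuronal exposure design grouped by dose × time; an in vivo
self-administration design grouped by brain region) with the same
machinery but a *single* random level and no category nesting. The BH
family for follow-up is the candidate set only, not the whole library:
a follow-up of a small discovery set tests only those compounds, and the
reported adjusted p-values are only consistent with a small family.
The default prioritization rule keeps compounds negative in *every*
follow-up dataset and significant in at least one, ranking by the number
of significant datasets and then by the mean absolute pooled estimate
across follow-up datasets (the rule is pluggable). Mouse-like data are
first restricted to one-to-one orthologs; ambiguous (many-to-many)
ortholog families are dropped entirely to avoid double-counting genes in
correlations.

## The behavioral module

The validation assay statistics are implemented exactly as a fly
startle/seizure/consumption experiment needs them:

* an OLS standard curve (absorbance at 630 nm vs. dye concentration,
  standards spanning 0–6 µg/mL) with inverse prediction and extrapolation
  flags; duplicate wells are averaged *before* inversion; concentrations
  convert to consumed dye mass through the 300 µL extraction volume;
* a two-way fixed-effects factorial ANOVA (sex × treatment) with type-III
  sums of squares, computed as full-vs-reduced model comparisons under
  sum-to-zero contrasts — the construction that the phrase "type-III SS
  with unequal cell sizes" pins down; with balanced cells it provably
  equals the sequential decomposition, and the tests assert this;
* pooled-variance (Student) two-sample t tests for post-hoc contrasts,
  two-sided, with Welch correction available but off by default;
* Fisher's exact test (two-sided, by summation of hypergeometric
  probabilities at or below the observed table's) for seizure incidence.

## What the synthetic generator emulates — and what it does not

All inputs are generated by the `synthetic_data` module so that every
stage is testable without any external download.

**Disease profiles.** Gene effects are
$d_{rg} = L_g + B_{rg} + \sigma \eta_{rg}$: a shared latent disease
component ($2\%$ of genes by default), a region-private component ($10\%$
of genes per region), and unit-scale region noise. P-values come from the
known-variance z model $d/\sigma$, so the set of true effect carriers is
exact and BH-threshold selection can be tested against ground truth. The
shared/private split reproduces two robust features of real multi-study
brain data: minimal overlap of DEG sets across regions, and weak (near
zero) inter-region correlation of pathway-gene effects. Defaults use a
1,000-gene namespace, a 50-gene pathway (the scale of the curated cocaine
addiction pathway) and an 80-gene landmark set (the ~8% of the genome the
L1000 assay measures directly).

**Signatures.** A compound's planted pooled correlation $\theta_c$,
region deviations $u \sim N(0, \tau^2_{\mathrm{region}})$ and cell
deviations $w \sim N(0, \tau^2_{\mathrm{category}})$ define per-cell
correlation targets $\theta_c + u_r + w_{rc}$. The generator builds each
signature as a loading pattern over per-cell basis vectors (the centered
disease effects restricted to each cell's gene subset), solving a small
regularized linear system against the realized covariance structure of
those subsets so that the *expected correlation on each analyzed subset*
matches its target; independent gene-level residual noise brings each
signature to unit variance. Solving on the analyzed subsets matters:
DEG subsets are selected for large effects, and a naive global loading
would inflate realized correlations on them well beyond the planted
value. Because the three categories share genes by construction
(LANDMARK nests inside DEG ∪ PATHWAY), heavily overlapping cells make
the system ill-conditioned; the small ridge term then attenuates the
*category-level* deviations slightly. Noise enters at the gene level, so
sample correlations genuinely fluctuate with the advertised sampling
variance.

**What passing tests do and do not show.** The generator reproduces the
statistical *structure* the pipeline assumes, not real biology: no
probe-level noise, no L1000 deconvolution artifacts, no
compound-specific pharmacology, no correlated gene modules beyond the
planted components. A known consequence of the shared-gene structure is
that the sampling errors of one signature's correlations are positively
dependent across overlapping cells and across regions sharing latent
effects — a dependence the nested random-effects model (like any
meta-analysis treating observations as conditionally independent) absorbs
only partially, and which the real screen shares. Together with the
intrinsically non-normal behavior of Wald inference when a variance
component is estimated from only three level-1 groups — conservative when
the true heterogeneity is zero (boundary estimates), anti-conservative
when it is small but positive — per-compound null p-values are close to,
but not exactly, uniform. At the defaults the null z-scores have standard
deviation around 1.1–1.2. This leaves false-discovery control after BH
intact by a wide margin (the all-null library flags far fewer than 5% of
compounds), but a sufficiently large pooled sample of null p-values will
fail a strict uniformity test; the calibration suite measures exactly
this, and the result should be read as a property of z-based multi-level
meta-regression at three regions, not as an implementation defect.

**Behavior.** Group sizes default to the validation assay's reported
numbers (61/140/132 control/cocaine/cocaine+drug males, 66/141/142
females, drug-only 66/68). Movement times are truncated normals on the
45 s assay window (seizing flies score as stationary, which the group
means already reflect); seizures are Bernoulli per group; absorbances are
generated from consumed dye mass through the calibration line with
well-level noise, in duplicate. Planted effect sizes mirror the assay's
qualitative narrative — cocaine halves male movement, co-treatment
restores it in both sexes, male seizure incidence drops strongly under
co-treatment — with the female seizure reduction deliberately small
(0.14 → 0.115 at ~140 flies per group): an a-priori power analysis shows
this is the regime in which a true reduction exists but the test is
expected to stay non-significant, which is the pattern being modelled.
Note a structural fact checked by the suite: no effect size can make the
*observed* direction negative *and* non-significant simultaneously in
much more than two-thirds of replicates (the observed z must fall in
(0, 1.96)); the reproducible pattern is therefore "non-significant female
test at lower female incidence", with the reduction planted in the truth.

## Scales, seeds and runtime

Simulation-based checks run at desk scale chosen so the full suite
completes in minutes on one CPU: 600–1,000 gene namespaces, 100–200
compound libraries, 200 replicates for calibration/recovery/benchmark
properties, 100 seeds for the behavioral pattern, 500 for ANOVA null
calibration. All generators are seeded; per-entity sub-streams are derived
by stable hashing of entity ids, so outputs are bit-reproducible and
insertion-order independent. The acceptance script derives every seed it
uses from its `--seed` argument.

## Known limitations

* The pooled estimate reported for a compound is the model-based GLS
  mean; figure-style "weighted averages" of per-region correlations are
  the same quantity here by construction.
* The generator's variance parameters are chosen for testability; no
  attempt is made to match per-study sample-level variances of the real
  datasets, which the source material does not report.
* Expression-detection filtering of pathway genes is not modelled; the
  pathway category includes every pathway gene present in a profile.
* The Fisher-z and raw-correlation pipelines agree on classification in
  all tested regimes but are not numerically identical; only the raw
  route is the default.
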