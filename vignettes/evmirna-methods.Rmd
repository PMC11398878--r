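---
title: "Methods: plasma EV miRNA qPCR quantification and diagnostic evaluation"
author: "evmirna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma EV miRNA qPCR quantification and diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmirna)
```

# Scope

`evmirna` implements a complete relative-quantification and diagnostic
workflow for an eight-miRNA amyotrophic lateral sclerosis (ALS) fingerprint
measured by SYBR-green qPCR in plasma neural-enriched extracellular
vesicles, compared across four cohorts (ALS, primary lateral sclerosis,
Parkinson's disease, healthy controls). The stages are: plate-level Cq
import, spike-in / signal / haemolysis quality control, inter-plate
calibrator (IPC) correction, reference-miRNA validation, Livak
2^-ddCq quantification with extreme-outlier filtering, nonparametric group
comparison with signed fold regulation, and three classifier designs.
Because raw plate data for such studies are rarely deposited, the package
ships a synthetic cohort generator with known ground truth so that every
stage is testable end to end.

# The quantification model

All computation happens on the quantification-cycle (Cq) scale, which is a
log2 expression scale under the standard assumption of 100% amplification
efficiency (one cycle = a factor of two in template; the Livak method's
assumption, see Livak & Schmittgen 2001). The chain is:

1. **Replicate collapse.** Duplicate wells of one (sample, target) are
   averaged arithmetically on the Cq scale — equivalent to a geometric mean
   of the linear quantities. Replicate ranges above 1.0 cycle are flagged in
   a discordance report rather than rejected; single surviving replicates
   are annotated. An absent Cq ("Undetermined" within 40 cycles) is a
   missing value, never imputed as 40: imputing the cycle ceiling would
   bias every downstream dCq.
2. **IPC calibration.** Each plate carries triplicate inter-plate
   calibrator reactions. Plate p's correction is L − m_p, where m_p is the
   plate's mean IPC Cq and L is the grand mean of the m_p. This
   mean-centring has no privileged plate; a reference-plate mode is offered
   because centring conventions differ between laboratories. Corrections
   cancel within a sample, so dCq is invariant under calibration — the
   calibration matters only for quantities compared across plates on the
   raw Cq scale (QC windows, stability analysis).
3. **Normalization.** dcq(s, t) = Cq(s, t) − mean of the sample's reference
   Cqs (miR-146a-5p, miR-29b-3p, miR-126-5p by default). The arithmetic
   mean of reference Cqs is the log2 of the geometric mean of their linear
   expressions. Note the deliberate quirk of this assay: two references are
   also fingerprint targets, so their own fold changes are partially
   self-referential. The package reproduces this design and exposes
   configuration to separate the sets.
4. **Relative quantification.** ddcq(s, t) = dcq(s, t) − mean control dcq
   of target t; fold change = 2^-ddcq. Two algebraic identities follow and
   are property-tested: the control group's mean ddcq is 0 per target, and
   the geometric mean of control fold changes is exactly 1.

# Quality control

* **Haemolysis.** ΔCq = Cq(miR-23a-3p) − Cq(miR-451a). miR-23a-3p is stable
  in plasma while miR-451a is erythrocyte-enriched, so large ΔCq indicates
  red-cell contamination. The flag threshold is ΔCq ≥ 7 cycles (inclusive).
  Flagged samples are **retained with a note** when their fingerprint Cqs
  lie inside Tukey fences (k = 1.5) computed over the run's pooled
  fingerprint Cq values; exclusion happens only on explicit configuration.
  Quartiles use linear interpolation (`quantile` type 7); the convention is
  stated because quartile rules differ across software.
* **Spike-ins.** UniSp2/4/5 monitor RNA extraction; UniSp6 and
  cel-miR-39-3p monitor reverse transcription. No fixed acceptance cycles
  exist for these assays, so windows are learned from the run itself as
  mean ± 2 SD per spike-in and logged. This follows common spike-in
  practice; with a 2-SD window roughly 5% of clean samples per spike-in
  will be flagged, which is why spike-in flags are reported rather than
  used to drop samples automatically.
* **Signal.** The mean Cq over six endogenous miRNAs (miR-142-3p,
  miR-451a, miR-23a-3p, miR-30c-5p, miR-103a-3p, miR-191-5p) summarizes
  how much amplifiable material a sample yielded; the default low-signal
  threshold is a mean above 35 cycles.

# Reference validation

* **Stability.** `normfinder_stability()` is a variance-components
  estimator in the manner of NormFinder (Andersen et al. 2004), computed on
  −Cq. Per candidate and cohort it separates the candidate-by-cohort bias
  (how much the candidate moves with disease status) from the intra-cohort
  variance (after removing per-sample effects, with a 1/(1 − 1/I) rescale
  to undo the shrinkage introduced by candidate-centring). The stability
  value is the mean over cohorts of |bias| + SE; lower is more stable. The
  Bayesian shrinkage of the original NormFinder software is omitted — at
  these group sizes it changes little and the unshrunk estimator is
  transparent and directly testable against an independent two-way
  variance-component computation.
* **Pairwise variation.** `pairwise_variation()` follows Vandesompele et
  al. (2002): NF_n is the per-sample mean Cq of the best n candidates and
  V[n] is the SD across samples of NF_n − NF_{n+1}, in cycle (log2-ratio)
  units; V[3] < 0.15 means a fourth reference adds nothing. On synthetic
  data V tends to sit above what real panels show, because the generator
  draws each miRNA's biological variation independently, while real
  reference miRNAs are co-regulated and correlated — one of the stated
  limits of the simulation.

# Outlier policy and group statistics

Extreme cells are masked per target on the fold-change scale:
|FC − mean| > 4 SD with mean and SD pooled over all cohorts, in a single
pass (no re-iteration, so one extreme batch cannot cascade into removing
ordinary samples). Samples with ≥ 50% of their fingerprint cells masked are
invalid and removed entirely. Pooling across cohorts is a choice — the
alternative (per-cohort moments) would mask moderate values in tight
cohorts; the pooled rule matches the small removal counts that motivated
it. A caveat worth knowing: on a lognormal fold-change scale the pooled
4-SD threshold sits only ~2.5–3 SD up in log space, so with realistic noise
a few tenths of a percent of legitimate cells are masked; the rule is kept
because it is the assay's stated policy and the attenuation it causes is
small against the ±30% recovery band used in validation.

Group comparison is nonparametric: Kruskal–Wallis H (tie-corrected, p from
chi-square with cohorts − 1 df; the critical value at p = 0.001 with 3 df
is 16.27) gates two-tailed Mann–Whitney post-hoc pairs (ALS vs HC, ALS vs
PLS, ALS vs PD). U is reported with |Z| from the tie-corrected normal
approximation without continuity correction; at total n ≤ 8 without ties
the exact distribution is used instead. Fold regulation converts a ratio r
of group mean fold changes to a signed value: r if r ≥ 1, else −1/r, so
|FR| ≥ 1 and FR(r) = −FR(1/r). Group means drive FR (medians are reported
alongside); no multiple-testing correction is applied across the eight
targets by default, mirroring the assay's reporting, with a flag to enable
it.

# Classifier designs

All three designs consume normalized dCq features for ALS and control
samples, without removing outliers (the filtering applies to the group
statistics only):

1. **Logistic, 80/20.** Stratified split with train size = ceiling
   (fraction × n) — the only rounding consistent with n = 269 giving a
   216-sample training set (null df 215; residual df 207 with 8 features).
   Coefficients, deviances and Fisher iteration count are reported;
   predicted probability ≥ 0.5 classifies as disease. If the IWLS fit does
   not converge or coefficients diverge (|coef| > 15 log-odds per cycle),
   the run is flagged as separated and the coefficient table is withheld,
   because those numbers are not maximum-likelihood estimates.
2. **Random forest, 79/21, iterative removal.** 500 trees by default; the
   lowest mean-decrease-in-Gini feature is dropped one at a time and the
   subset with the best held-out accuracy is kept (ties favour fewer
   features). The stopping rule is a package choice — accuracy-maximization
   is the simplest rule consistent with "iteratively removing low-
   contribution markers".
3. **Cross-cohort forest.** Trained wholly on an independent cohort
   (synthetic stand-in: a 50/50 ALS/HC cohort of 100 with shifted base Cqs
   and permuted plate offsets), tested wholly on the current cohort, with
   features aligned by miRNA name. A global batch shift on all targets —
   references included — cancels exactly in dCq, which the tests verify.

AUC uses the rank (Mann–Whitney) formulation with ties counted half, so it
is invariant under monotone transforms of the scores; ROC curves are
computed on the held-out test set by default with a whole-set option,
since figure legends in this literature are often ambiguous about which
set the ROC used. Seeds 375 (random splits) and 101 (cross-cohort) are the
assay's stated analysis seeds and are pipeline defaults; cross-library
seed-for-seed equivalence with other implementations is explicitly not
promised — validation is property-based.

# The synthetic cohort generator

`simulate_run()` draws, for sample s, target t, well w:

    Cq = base_t − effect_{t, cohort(s)} + u_s + b_{s,t} + plate_{p(s)} + ε_w

with u ~ N(0, sigma_sample²) (global input shift, 1.5 cycles; cancels in
dCq), b ~ N(0, sigma_target²) (per-target biological variation), and
ε ~ N(0, sigma_noise²) (0.25 cycles, duplicate wells). Gaussian noise on
the cycle scale is the standard lognormal model of qPCR expression noise.
Spike-ins and IPC wells take base + plate offset + well noise only. Cohort
sizes default to ALS 119, HC 150, PD 20, PLS 42; effects default to the
fingerprint's published ALS-vs-control fold regulations converted to log2
(e.g. miR-10b-5p: −log2(7.38)), with PD and PLS left at control level, so
every ALS-vs-other comparison carries signal. The two references that are
also fingerprint targets keep their real effects — zeroing them would
contradict the assay they emulate; only miR-126-5p is a pure reference.

`sigma_target` is per-target and heteroscedastic (0.3–1.0 cycles;
references lowest). These values were fixed once, by simulation, to jointly
satisfy: Kruskal–Wallis H values in the tens-to-low-hundreds; reliable
(±30%) recovery of the designed fold-regulation magnitudes from 100-seed
replication; and NormFinder ranking the three references on top. The two
goals pull against each other for the strongest marker — a variance large
enough to hold its H under ~140 makes its ratio-of-means fold regulation
unstable — and recovery was given priority, so miR-10b-5p's H sits near
the rank-statistic saturation (~200) in default runs. These sigmas are
configuration describing a plausible cohort, not claims about any real
population.

`corrupt_run()` injects three artefacts with ground truth: haemolysis
(miR-451a lowered by 5 cycles in 2% of samples; the baseline ΔCq of 4 then
jumps past the 7-cycle flag), extreme cells, and invalid samples (5 of 8
fingerprint targets displaced in 3 samples). Displacement is defined on the
fold-change scale: a corrupted cell's Cq is set so its eventual 2^-ddCq
equals the target's clean pooled mean + 8 pooled SDs. Computing the
displacement through the normalization path (rather than as a fixed Cq
shift) is what makes single-pass 4-SD masking recover the injected cells
exactly: a fixed shift would inherit the cell's own random draw and, for a
reference target, drag the sample's other cells. Displaced targets are
restricted to the six non-reference fingerprint miRNAs for the same reason.
The arithmetic only works while injected cells stay below ~5% of a
target's values — beyond that the injected cells inflate the pooled SD
faster than they separate from it, and no single-pass rule can find them.

What the generator does **not** emulate: correlated (co-regulated) miRNAs,
amplification-efficiency differences between assays, melt-curve failures,
plate-position effects, censoring beyond the hard 40-cycle cut, and cohort
confounding (age/sex structure is random). Passing tests therefore validate
the pipeline's arithmetic, bookkeeping and statistical behaviour under a
plausible noise model — not the clinical performance of the fingerprint on
real plasma.

# Numerical and degenerate-input choices

* Quartiles: type 7 (linear interpolation); IQR multiplier k = 1.5.
* Constant inputs: Kruskal–Wallis on all-tied values returns H = 0, p = 1;
  AUC on constant scores is 0.5 with a degeneracy note; zero-SD targets
  mask nothing; IQR fences of a constant sequence collapse onto it.
* Missing data: a dCq cell is absent if the target Cq or any reference Cq
  is missing; samples with every reference missing are excluded and
  reported. Pairwise-variation entries use pairwise-complete samples with
  counts reported. Indeterminate haemolysis (either marker absent) is
  reported as such, never passed silently.
* Split rule: train size = ceiling(fraction × n), apportioned across
  classes by largest remainder.
* Problem sizes used in the shipped validation: the full 331-sample design
  for single runs, 100 seeded replicates for fold-regulation recovery, 50
  seeds for classifier behaviour, and exhaustive enumeration (all 560 label
  arrangements of an n = 8 fixture; all C(n, m) group splits for
  Mann–Whitney) for the rank-statistic oracles.

# Known limitations

* The self-referential normalization (two references inside the
  fingerprint) attenuates those two targets' fold changes; it is
  reproduced, not resolved.
* Fold regulation from ratios of arithmetic means on a lognormal scale is
  heavy-tail sensitive; medians are emitted alongside for that reason.
* The iterative-removal stopping rule and the spike-in windows are package
  choices where the field has no single convention; both are configurable
  and logged.
* Classifier metrics on synthetic cohorts characterize the pipeline, not
  the biomarker; no clinical claim follows from them.

# References

* Livak KJ, Schmittgen TD (2001) Analysis of relative gene expression data
  using real-time quantitative PCR and the 2^-ddCT method. Methods 25:402-8.
* Andersen CL, Jensen JL, Orntoft TF (2004) Normalization of real-time
  quantitative RT-PCR data: a model-based variance estimation approach.
  Cancer Res 64:5245-50.
* Vandesompele J et al. (2002) Accurate normalization of real-time
  quantitative RT-PCR data by geometric averaging of multiple internal
  control genes. Genome Biol 3:research0034.
* Blondal T et al. (2013) Assessing sample and miRNA profile quality in
  serum and plasma or other biofluids. Methods 59:S1-6.
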