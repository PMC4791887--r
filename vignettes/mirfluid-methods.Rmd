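---
title: "Methods: miRNA RT-qPCR biomarker screening in CSF and blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA RT-qPCR biomarker screening in CSF and blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfluid)
```

## The problem

Small exploratory dementia cohorts are often profiled with RT-qPCR miRNA
panels: a few hundred assays, one measurement per assay per sample, in two
biofluids (cerebrospinal fluid and plasma/blood), with two clinical groups —
Alzheimer's disease (AD) versus other dementias — of about ten patients each.
`mirfluid` implements the full analysis such a screen needs: deciding which
measurements count as detected, normalizing quantification cycles (Ct) into
relative expression levels, screening for quantitative and presence/absence
markers, estimating classification performance, and checking the cohort and
the blood–brain barrier. Because raw Ct data from such studies are rarely
deposited, the package ships a synthetic cohort generator with the same
statistical structure, so every stage is testable end to end.

## Detection filtering

A Ct value is a log2-domain quantity: one cycle is one doubling of template.
A measurement is called *detected* only when all of the following hold:

* the reaction amplified at all (Ct present),
* `Ct < ct_max` (default **37 cycles**, the panel's limit of detection),
* the assay's negative control is at least `control_margin` cycles above the
  sample (default **3 cycles**, i.e. `negctrl − Ct ≥ 3`), and
* any externally supplied per-measurement QC flag (melting curve /
  amplification efficiency, computed upstream of this package) passes.

Two boundary conventions are deliberate. The control margin is *inclusive*
(`≥ 3`): the inclusion rule is stated as a requirement of three cycles, not a
strict inequality, and `margin_strict = TRUE` flips the convention for
sensitivity analysis. A *missing* negative control is treated as "the control
never amplified", the cleanest possible control outcome, so it passes the
margin. Undetected cells are masked — they are missing downstream, never
zero (except in the one place where the zero-fill is the documented method;
see leave-one-out classification).

Spike-in channels (synthetic RNA/DNA templates added at a fixed amount to
every sample) are run-level QC, not analytes. A spike-in passes when it
amplified everywhere and its Ct standard deviation is at most
`sd_threshold = 1.0` cycles — "steady levels" is not a quantified criterion
in the field, and one cycle (a two-fold difference) is a conventional bound.

## Normalization

The default normalizer is the **global mean**: per sample, the arithmetic
mean Ct over the assays detected in *every* sample of that fluid. Then

    dCt(a, s) = Ct(a, s) − norm(s),      REL(a, s) = 2^−dCt(a, s)

Normalization is computed per fluid independently. Two exact consequences are
tested to `1e-9`: the geometric mean of REL over the detected-in-all set is 1
in every sample, and adding a constant to every Ct of one sample (a loading
or RNA-content shift) leaves that sample's RELs unchanged.

`rank_normalizers()` justifies the choice with a NormFinder-style stability
value. Candidates are the detected-in-all assays plus the pseudo-candidate
`"global_mean"`, whose per-sample value is entered as if it were a gene. For
each candidate the two-way (candidate + sample) residuals within each group
give an intra-group variance with the unbiased small-sample scaling
`k/((k−1)(n_g−1))`; the inter-group bias is the difference of group means
after centering each candidate and each group; and

    stability = sqrt( max(bias² − Var̂(bias), 0) + (s²_AD + s²_control)/2 )

The bias term is shrunk by its own sampling variance so a noisy candidate
cannot look unbiased for free; lower stability is better. With ten samples
per group the estimator is kept closed-form (no shrinkage across candidates).
Note one structural property: because the global mean *is* the fitted sample
effect of the two-way model, its residuals vanish and it ranks first whenever
no candidate gene is exactly stable — which is the empirically expected
outcome for this panel design, not a distortion of it.

## Differential screen (quantitative)

Per fluid, miRNAs detected in at least `min_detect = 9` of 10 samples in
*both* groups enter the table. Group medians and ranges are computed over
detected values only; the fold change is the ratio of full-precision medians
(AD / control) — ratios of rounded medians can differ in the last printed
digit. The test is the two-sided Mann–Whitney: exact by the full rank-sum
null when the pooled n is at most 25 and tie-free, otherwise the normal
approximation with mid-ranks, tie correction and continuity correction. The
exact branch is cross-checked in the tests against a complete enumeration of
all `choose(n, n_x)` rank assignments for all group sizes up to 6.

All table p-values are Benjamini–Hochberg corrected. `adjust_bh(p, m)`
accepts an `m` larger than the number of supplied p-values (unlisted tests
count as 1), which is how the package reproduces the study-level conclusion
that p-values of 0.005–0.019 among 52 tests do not survive correction: the
smallest adjusted value is `52 × 0.009 / 2 = 0.234`. (Note the step-up
minimum: the naive `52 × 0.005 / 1 = 0.26` is not the BH minimum.)

## Categorical screen (presence/absence)

Detection itself can be the marker. For each miRNA the 2×2 table (rows AD /
control, columns detected / undetected) is tested with the two-sided Fisher
exact test using the *probability method* — the p-value sums all tables with
the observed margins whose probability does not exceed the observed table's
(this, and not tail doubling, reproduces the printed values 0.03 and 0.06
from tables 5/10 vs 0/10 and 6/10 vs 1/10). The odds ratio is `(ad)/(bc)`,
with the Haldane–Anscombe 0.5 correction added to all four cells *only when
a zero cell occurs* — the only convention consistent with printed values of
13.5 (no zero cell, uncorrected) and 21 (zero cell, corrected). Sensitivity
is the detected fraction of AD patients, specificity the undetected fraction
of controls, in percent. The screen keeps miRNAs more frequent in AD with
Fisher `p ≤ 0.1` (configurable; chosen so markers at p = 0.03–0.06 are
captured) and stars `p < 0.05`.

`fluid_partition()` classifies each miRNA detected anywhere as present in
both fluids, blood only, or CSF only (present = detected in ≥ 1 sample), and
categorizes by per-fluid detection frequency.

## Classification

`loo_accuracy()` estimates each miRNA's predictive power by leave-one-out
cross-validated univariate logistic regression, with missing REL set to 0
("not expressed") before fitting. The fitter is deliberately deterministic:
iteratively reweighted least squares with a ridge penalty of `1e-6` on both
coefficients and a 50-iteration cap. With n = 20 and LOO, complete separation
is routine; under the ridge the iterates stay finite and the held-out
prediction follows the diverging sign, and such folds are counted
(`separated_folds`), not treated as errors. Two analytic anchors are tested:
a perfectly separated predictor scores accuracy 1, and a *constant* predictor
scores exactly 0 in a balanced design — each LOO training set is 9 vs 10, the
fit predicts the training majority, and the held-out sample is always the
minority of its own training set. "Above random" means accuracy strictly
greater than 0.5.

`fit_ratio_model()` builds the two-miRNA ratio biomarker
`REL[num]/REL[den]`: candidate cutoffs are midpoints between consecutive
distinct observed ratios plus a point beyond each extreme; both decision
directions are scanned; the cutoff maximizes Youden's
`J = sensitivity + specificity − 100`, with ties broken toward higher
specificity and then toward the lower cutoff. The direction is data-driven,
not hard-coded. `screen_ratio_pairs()` generalizes the hand-picked pair to
all ordered pairs, ranked by J and then by fewer excluded samples.

## Cohort statistics and the blood–brain barrier

Demographics and CSF routine markers are compared with the two-sided Student
t-test with pooled variance (the Welch variant is a flag), reporting the
AD-minus-control mean difference with its 95% confidence interval; 2×2
variables (sex) go through the Fisher exact test. The CSF/serum albumin
quotient is flagged as elevated when `Qalb > (age/15 + 4) × 10⁻³`, the
standard age-dependent reference limit (strict inequality; a fixed threshold
can be supplied instead, since reporting conventions differ between
laboratories). CSF–blood expression association is summarized per miRNA as a
Spearman rank correlation over a chosen sample subset, descriptively — with
fewer than five pairs a p-value would be meaningless, and with fewer than
three the correlation is undefined.

## Synthetic cohorts

`generate_cohort()` draws, per fluid,

    Ct(a, s) = baseline(a) + shift(s) + effect(a, group(s)) + ε

with per-assay baselines uniform on 22–36 cycles, per-sample shifts
`N(0, 1.0²)` (what global-mean normalization must remove), measurement noise
`N(0, 0.5²)`, planted group effects expressed as delta-delta-Ct shifts added
to the AD samples of chosen assays, censoring to missing at the limit of
detection (37 cycles), optional extra dropout concentrated within ~2 cycles
of the LOD, stable spike-in channels without sample shifts (spike-ins are
added at a fixed amount after extraction), and negative controls near 40
cycles with a 25% chance of not amplifying. Group sizes default to 10 + 10
and the panel to 372 assays, the design of the motivating study. Per-patient
shifts are *not* shared between the two fluids: CSF and blood levels of the
same patient are generated independently, matching the observed absence of
cross-fluid correlation. Noise is normal on the Ct (log2) scale, consistent
with `REL = 2^−dCt`; dropout is censoring at the LOD rather than
missing-at-random, which is how qPCR non-detection actually arises.

What the generator does **not** emulate: plate/batch effects, amplification
efficiency differences between assays, hemolysis or other pre-analytical
artifacts, and correlated miRNA co-regulation. Passing tests therefore show
that the pipeline recovers the structure it assumes — not that real cohorts
satisfy those assumptions.

## Calibration experiments and problem sizes

The test suite and the acceptance script run three simulation experiments;
panel sizes are 60 assays, large enough to leave ~55 null competitors in the
differential table (the published CSF table had 52 rows) while keeping the
suite fast.

* **Recovery.** Three planted `|ddCt| = 1` effects at n = 10 + 10 and
  σ = 0.5. Among planted effects that enter the differential table, ≥ 90% of
  placements rank in the 3 smallest p-values over 200 seeds. The measure is
  conditioned on table entry because the screen itself is conditioned on
  detection in ≥ 9/10 per group: an assay whose random baseline sits near
  the LOD and censors out is a detectability event, not a ranking failure.
  Two related quantities are deliberately *not* asserted, because they are
  mathematically out of reach at this signal-to-noise: the joint event that
  all three planted markers simultaneously occupy the top 3 holds in only
  ~65% of seeds (≈ 0.9³, driven by sampling of the realized effect, not by
  null competition), and the unconditional per-effect rate is ~0.87.
* **Null calibration.** On effect-free cohorts the differential p-values are
  exact-test p-values, hence discrete and super-uniform (the two-sided
  Wilcoxon p at 10 vs 10 has an atom of ~0.08 at 1). A plain
  Kolmogorov–Smirnov test against the uniform rejects a few percent of null
  seeds on discreteness alone, so the test first applies the randomized
  probability integral transform through the exact null CDF of the p-value
  (computable from the Wilcoxon distribution), under which null p-values are
  exactly uniform, then runs the per-seed KS at α = 0.01 over 100 seeds and
  bounds rejections by the binomial 99.9% envelope. The categorical screen
  on the same null cohorts produces no starred row in ≥ 95% of seeds.
* **Ratio-pair recovery.** With one up- and one down-regulated planted
  marker among two null candidates, the top-ranked ordered pair is the
  planted pair in ≥ 90% of seeds. With six or more candidates, ties at
  complete separation (J = 100) between the planted pair and single-planted
  pairs blur the top rank under the documented tie-breaks; the candidate set
  is kept small for that reason.

## Numerical choices and degenerate inputs

* Ct = 0 is invalid (cycles start at 1); missing amplification is an empty
  cell on disk and `NA` in memory.
* Delimiters are auto-detected among comma/tab/semicolon; decimal points
  only.
* Fisher's p is 1 by convention for any zero margin; undefined Mann–Whitney
  p (an empty group after missing-value exclusion) is reported as missing,
  never dropped silently.
* The stability model needs at least 3 candidates and 2 samples per group;
  fewer is an error, not a silent fallback.
* All ranking tie-breaks (stability, p-value, Youden J) end in assay-name
  order so results are deterministic and order-independent.
* Human-readable rendering rounds medians/FC to 2 decimals and p to 3 with
  `n.s.` above 0.05; machine-readable CSVs keep full precision (15
  significant digits, round-trip tested to 12).

## Limitations

The package ingests Ct tables and externally computed QC flags; it does not
parse instrument exports, analyze melting curves, or estimate amplification
efficiency from fluorescence data. No covariate adjustment or multivariate
logistic models are offered — with ten patients per group, single-predictor
models and a single two-miRNA ratio are already at the edge of what the
design supports, and model selection among multivariate fits would be
unstable. All classification estimates are internal cross-validation on a
small cohort; they are screening statistics, not validated diagnostic
performance.
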