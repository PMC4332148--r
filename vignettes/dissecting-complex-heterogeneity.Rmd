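---
title: "Dissecting supramolecular complex heterogeneity from quantitative MS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting supramolecular complex heterogeneity from quantitative MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large protein machines such as the proteasome are not a single species. A
20S core particle (CP) exists as a standard subtype (sP20S, catalytic
subunits β1/β2/β5), an immuno subtype (iP20S, β1i/β2i/β5i) and mixed
intermediates, and each core can be capped by different regulators (19S,
PA28αβ, PA28γ, PA200) or bound by PI31. A single affinity purification
against a shared subunit therefore recovers a *mixture* of complexes, and
bulk interactomics cannot tell which regulator is bound to which subtype.

This package implements two complementary, purely quantitative strategies to
resolve that heterogeneity from label-free MS data, plus a synthetic data
generator that plants a known ground truth so every stage can be validated:

1. **Gradient PCP.** Complexes are separated by density-gradient
   ultracentrifugation; proteins that sediment together belong together.
   Each protein's abundance profile across fractions is compared to a
   reference complex profile with a χ² distance.
2. **Cross-purification correlation (AP-MS PCP).** The same complex is
   purified from many biological contexts (here 24 purifications from nine
   cell lines). Proteins whose amounts rise and fall together across
   purifications are inferred to reside in the same sub-complex; agreement
   is measured as the squared Pearson correlation R².

## Quantification: calibrated TOP3 abundance indexes

The input is a long-form peptide table (`sample_id`, `protein`,
`peptide_id`, `xic_area`, optional `sn_ratio`, `is_standard`). Three steps
(`quantify()`):

* **Run calibration** (`calibrate_runs()`). Eight isotopically labeled
  standard peptides are spiked into every run at a constant amount. For each
  sample the scale factor is the *median* over standards of
  (cross-sample mean of the standard ÷ its intensity in this sample); all
  rows of the sample are multiplied by it. This removes per-run drift
  exactly when the standards carry only drift. Because the reference level
  is the cross-sample mean, calibration absorbs arbitrary per-sample scale
  factors up to a single global constant — every PAI *ratio* is restored
  exactly, which is all downstream stages consume.
* **Reference peptide selection** (`select_reference_peptides()`). Per
  protein, peptides are ranked by total calibrated intensity summed over all
  samples (missing = 0) and the top three are fixed as reference peptides
  for *every* sample; ties break lexicographically so the choice is
  deterministic. Proteins with one or two peptides keep what they have.
* **PAI** (`compute_pai()`). The protein abundance index in a sample is the
  arithmetic mean of its reference peptides' calibrated intensities there.
  When a reference peptide is unobserved in one sample the default is the
  mean over the observed ones (`missing_ref = "mean"`); imputing zero is
  available (`"zero"`). We default to the mean because dropout in these data
  is a stochastic low-intensity phenomenon, not evidence of absence of the
  protein; the choice is switchable because the opposite convention is
  defensible for true on/off situations.

## χ² profile distance (gradient mode)

Profiles are built per replicate: missing protein-in-fraction values are set
to 0 *before* normalization (in a gradient, no signal means no protein — the
physics differs from AP-MS dropout), and each profile is divided by its
total, so it sums to 1. The distance of protein profile $x$ from reference
profile $p$ over fractions $i$ is

$$\chi^2(x, p) = \sum_i \frac{(x_i - p_i)^2}{\max(p_i, \varepsilon)},
\qquad \varepsilon = 10^{-4}.$$

The reference sits in the denominator, so the distance is deliberately
asymmetric. Reference profiles are the fraction-wise *median* of the
detected member profiles, re-normalized to sum 1 afterwards (median first,
then renormalize; the alternative order differs only when members are
detected on different supports and the median route is the one that keeps
each member's profile a proper distribution). The ε floor handles fractions
where the reference is empty: dropping those fractions would *reward*
proteins that put mass where the reference has none, exactly the proteins
the screen must penalize. ε = 10⁻⁴ of unit mass keeps such terms finite but
dominant.

`pcp_screen()` requires the protein in all replicates, rebuilds the
reference within each replicate from its detected members (so a subunit
missing from one replicate does not distort that replicate's reference), and
ranks by the arithmetic mean χ² across replicates.

## Cross-purification correlation and the confidence filter

Reference sub-complex abundances are per-sample aggregates of member PAIs:
median for multi-subunit references (11-subunit non-catalytic core ncP20S,
19-subunit 19S, PA28α+PA28β), the single member's PAI for β5 (sP20S proxy),
β2i (iP20S proxy), PA28γ, PA200 and PI31. Member PAIs missing from a sample
count as 0 — in an AP-MS series against a fixed bait, absence from the
precipitate is informative, and pairwise-complete deletion would bias r
upward.

Correlations are Pearson on raw (untransformed) PAIs, matching the linear
panels the method is built around; R² = r². Records need ≥ 3 samples;
zero-variance vectors yield an undefined record that is excluded rather than
zero-filled. The confidence filter for putative interactors keeps proteins
with signed r > 0.8 against at least one of the three 20S subtype references
(signed, so strong *anti*-correlation does not pass), at least 2 reference
peptides, and median S/N > 10, and labels each survivor with its best
reference.

## Clustering conventions

* **Supervised**: proteins are clustered on their 8-dimensional reference-R²
  vectors. The linkage/metric is not dictated by the method itself; the
  default is Euclidean distance with average linkage, both configurable,
  with the reference (column) order kept fixed for heat-map export.
* **Pearson (n) PCA**: PCA on the correlation matrix of the variables,
  standardizing with the population (n-denominator) standard deviation —
  the "Pearson (n)" convention of common statistics suites. Missing
  normalized PAIs enter as 0 and zero-variance variables are dropped with a
  report. Component signs are fixed by making each component's
  largest-magnitude loading positive, so outputs are reproducible.
* **UPGMA**: proteins are observations, samples variables; dissimilarity is
  d = 1 − r. Undefined pairs (zero variance) get the maximum d = 2 and are
  reported. Heights of the unweighted pair-group average method equal the
  mean pairwise dissimilarity between merged groups; the test suite checks
  this against a naive O(n³) oracle.
* Before PCA/UPGMA, PAIs are max-normalized per protein (`max_normalize()`):
  the highest value of each protein becomes exactly 1, removing absolute
  abundance so that clustering sees *patterns*.

## Differential regulator association

For a regulator, the per-sample abundance is the *mean* of its member PAIs
(the multi-subunit references above use the median; the differential
analysis deliberately follows the mean convention, and both rules are
available — the discrepancy is documented rather than reconciled).
Normalizing by the ncP20S PAI per sample cancels global intensity and
loading, leaving regulator load per core particle. Ratios are formed per
sample *before* averaging, which keeps replicate variability for the
two-sided, two-sample, equal-variance Student t-test against the reference
condition (Welch available via `var_equal = FALSE`). The reference condition
is exactly 1 by construction. Following the per-regulator star convention,
no multiple-testing correction is applied by default; Benjamini–Hochberg is
available via `adjust = "BH"`.

## The synthetic data generator

`ground_truth_model()` fixes, per cell line, the subtype split of total 20S
and, per regulator × subtype, an association propensity in [0, 1] (expected
bound regulator per core of that subtype). An AP-MS sample then has
per-protein true abundance

* core (non-catalytic) subunits: capture_yield × total 20S,
* catalytic subunits: capture_yield × (sum of the subtypes containing them),
* regulator subunits: capture_yield × Σ_subtype abundance × propensity.

Defaults and why (all switchable):

| parameter | default | rationale |
|---|---|---|
| capture_yield | 0.87 | the purification yield the protocol achieves |
| noise_cv | 0.2 | multiplicative CV per measurement *and* per-replicate biological perturbation of each subtype pool |
| peptides_per_protein | 5 | enough that TOP3 selection is a real choice |
| efficiency_sigma | 0.4 | fixed per-peptide ionization factors spread ~3-fold, typical of tryptic peptides after the upstream intensity-based selection |
| missing_rate | 0.01 | the upstream pipeline re-extracts XICs across aligned runs, so missingness for complex subunits is rare |
| loading_cv | 0.1 | per-sample loading/capture factor shared by all complex-derived proteins (injected amounts differ between IPs); contaminants do not scale with it, since background binding does not track bait amount |
| run_drift_sigma | 0.2 | per-run intensity drift, removed by the standards |
| n_standards | 8 | spiked isotopically labeled peptides per run |
| n_fractions | 19 | fractions carrying proteasome activity in the gradient |

The generator records the full truth (per-sample subtype abundances,
per-protein true abundances, per-run scale factors) so recovery tests
compare estimates to planted values, and is byte-identical under a fixed
seed.

**The nine-line AP-MS design.** The default purification series uses nine
generically named lines (three immune-lineage, six epithelial/fibroblast)
with iP20S fractions 2–55%, small β5i-type intermediates (2–5%) and total
20S spanning roughly 0.6–1.7 arbitrary units, with 3,3,3,3,3,3,2,2,2
replicates (24 samples). Two structural facts shaped these choices:

* Because total = standard + immuno + intermediates, the standard-subtype
  signal can only decorrelate from total 20S if another component trades
  against it across lines. That trade is carried by a wide immuno range;
  immune-lineage cells genuinely reach such immunoproteasome contents.
* Every intermediate core contains β2 (and the β5i type also β1). Large
  intermediate pools would therefore force β1/β2 to track total 20S instead
  of β5, which contradicts the clustering behaviour the method is meant to
  recover; small intermediate fractions are the regime consistent with it.

Planted propensities (sP20S / iP20S): 19S 0.5/0.5, PA28αβ 0.05/0.9,
PA28γ 0.15/0.6, PA200 0.7/0.05, PI31 0.8/0.05; intermediates inherit the
iP20S row (they associate with the same regulators as the
immunoproteasome). These are calibration choices for recovery tests, not
measured constants. A known limitation of the single-propensity model: a
regulator like PA28γ that correlates with the immuno subtype across cell
lines but stays flat under interferon-γ induction cannot be represented by
one propensity row — in the simulated time course PA28γ follows its
propensities.

The differential model (`hek_ebna_model()`) is a separate study condition:
two lines assembling only sP20S or only iP20S, with a fourfold PA28αβ
(0.1 → 0.4) and an eightfold PI31 (0.4 → 0.05) contrast planted; setting
equal propensities turns it into the null model used for type-I-error
calibration. The time-course model (`ifng_model()`) starts from a low-immuno
line whose composition is chosen so that the default induction schedule (immuno ×8,
standard ×0.5 at 72 h, geometric interpolation in between) leaves total 20S
essentially unchanged.

**Gradient species.** The default gradient plants, from dense to light:
doubly capped 30S, 26S (standard and a β1iβ5i-intermediate core), free 19S,
PA200-, PA28γ- and PI31-bound standard cores, the iP20S–PA28αβ species, and
free 20S (standard and β5i-intermediate), each a Gaussian over fraction
index with declared center and width. β2i occurs *only* in the PA28αβ-capped
species, while β1i/β5i also sediment with intermediate-core species
elsewhere — so the screen's expected answer (β2i uniquely closest to the
PA28αβ reference) is planted, and the other immunosubunits provide realistic
near-misses. Contaminants get random peaks or flat profiles, uncorrelated
with any species.

**What the simulator does not emulate** — hence what green tests do *not*
demonstrate about real data: retention-time alignment and XIC extraction
(the pipeline starts from validated quant tables), identification errors and
FDR, interference/co-elution between peptides, intensity-dependent
missingness, saturation, shared peptides between proteins, protein grouping,
and any structural basis of the planted propensities.

## Numerical choices and degenerate inputs

* TOP3 ranking ties break lexicographically by peptide id; UPGMA merge ties
  follow the smallest-index convention of the agglomeration; PCA signs are
  fixed as above. All outputs are deterministic given a seed.
* A sample with no observed standards, a reference with no detected member,
  and an unknown subunit name are hard errors naming the offender; all-zero
  profiles, all-missing rows and zero-variance variables are excluded *with
  a report*, never silently.
* χ² uses ε = 10⁻⁴; correlation records need n ≥ 3; the reference condition
  of a differential analysis needs n ≥ 2.

## Problem sizes used by the test and acceptance suites

Recovery checks run the full study conditions (24-sample series, 19-fraction
two-replicate gradients) over 20 seeds each; oracle-equivalence checks use
50–100 random instances; the null calibration of the t-test uses 1000
simulated two-condition datasets with a reduced background (10 contaminants)
— sizes chosen so the whole suite runs in about a minute while keeping the
binomial margins of the ≥90%/≥95% success criteria meaningful.

## Worked example

```{r example}
library(proteoPCP)

sim <- simulate_apms(default_apms_model(seed = 1))
pai <- quantify(sim$peptide_table)
cat6 <- default_catalog()
refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
cm <- correlation_matrix(pai, refs)
filter_pips(pai, cm$r)
```

The numbered scripts under `analysis/` run the three studies end to end and
write their tables under `results/`; `scripts/acceptance.R` recomputes the
headline quantities from scratch.
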