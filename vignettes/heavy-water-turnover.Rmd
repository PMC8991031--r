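---
title: "Measuring protein and nucleic-acid turnover with heavy-water labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein and nucleic-acid turnover with heavy-water labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heavywater)
```

## The measurement

Deuterium oxide (D₂O) is a universal metabolic tracer: once an animal's body
water is enriched in deuterium, every newly synthesized macromolecule —
protein, DNA, RNA — incorporates deuterium at carbon-bound hydrogen
positions through intermediary metabolism. Because heavy water equilibrates
with all tissue water, labeling can run for weeks to months through the
drinking water, which is what makes slowly turning-over tissues such as
articular cartilage measurable at all.

For a peptide, incorporation shows up as a redistribution of the isotope
envelope: the monoisotopic peak (M0) loses relative abundance to M+1, M+2,
… as deuterated copies of the peptide accumulate. The fraction of the
protein pool replaced after `t` days of labeling under first-order turnover
is `1 - exp(-k t)`, so the relative M0 abundance declines as

```
M0(t) = M0_plateau + (M0_nat - M0_plateau) * exp(-k * t)
```

where `M0_nat` is the natural-abundance level and `M0_plateau` the level of
material synthesized entirely at the body-water enrichment `p`. The
rate constant `k` (per day) converts to a half-life `ln(2)/k`. This package
implements that forward model, the fits that invert it, and the quantities
built on top of it (concentrations, absolute synthesis rates, DNA/RNA
fraction-new, and the age-group comparison layer).

## Isotope envelopes

`natural_envelope()` convolves per-element isotope patterns (¹³C 1.07%,
²H 0.0115%, ¹⁵N 0.364%, ¹⁷O/¹⁸O 0.038/0.205%, ³³S/³⁴S/³⁶S
0.75/4.25/0.01%) over the elemental composition returned by
`composition_of_peptide()`. The constants are shipped fixed so envelopes
are deterministic across platforms. Two numerical points:

* Convolution only moves probability mass upward in nominal mass, so
  truncating intermediate arrays at `n_peaks` leaves the tracked
  probabilities exact; the renormalized envelope is therefore exact by
  construction, and the dropped tail mass is recorded as an attribute
  (with a warning if the tracked window misses more than 5% of the
  envelope).
* `n_peaks` defaults to 5 (M0 through M+4), which covers the visually
  informative part of a tryptic peptide's envelope; M0 is always reported
  as *relative* abundance — the first peak divided by the tracked sum — so
  the quantity is self-consistent whatever the window.

`labeled_envelope()` gives the plateau envelope: the peptide's
deuterium-accessible hydrogen sites carry heavy-isotope probability
(natural ²H + `p`) while everything else stays natural. Per-residue
accessible-site counts are not measurable from first principles; the
package ships the standard literature MIDA table
(`extdata/residue_formulas.csv`, column `exchangeable_H`) and treats it as
an explicit, swappable input so results are reproducible bit-for-bit given
a configuration. Fractional total site counts are handled by linear
interpolation between the envelopes at the two neighbouring integer counts
— interpolating the hydrogen channels separately before convolution would
create cross terms with the wrong total hydrogen count.

## Precursor (body water) kinetics

The labeling protocol is an intraperitoneal bolus followed by enriched
drinking water, so serum enrichment is modelled as
`p(t) = p_max - (p_max - p_0) exp(-k_p t)`: a nonzero offset `p_0` at
`t = 0` capturing the bolus, rising to the plateau `p_max`. The bolus is a
parameter rather than a mechanistic two-compartment model because with a
handful of serum time points anything richer is overfit.
`calibrate_enrichment()` maps raw analyzer readings through the inverse of
an ordinary least-squares standard curve first when standards are supplied.

When serum is drawn only at euthanasia (days ≥ 15) the rise is
unidentifiable; the fit then degrades deliberately — first re-fitting with
the bolus pinned at zero, and finally falling back to a flagged
constant-plateau estimate — because the plateau is the only precursor
quantity consumed downstream. Downstream plateau computations use a single
cohort-level `p_max` by default (the flat plateau makes per-animal values
indistinguishable); a fixed `p` (e.g. 0.055) can be supplied instead via
`run_pipeline(fixed_p = )`.

## Peptide and protein kinetics

`fit_peptide_k()` fits the M0 decay by nonlinear least squares
(Levenberg–Marquardt, `minpack.lm`), with `k` bounded in `[0, 2]`/day and a
log-linearized starting value; a golden-section fallback on the
sum-of-squares handles pathological series. Choices that matter:

* **Plateau treatment.** `M0_plateau` is computed from the labeled envelope
  at the cohort precursor plateau and held fixed. With only 3–4 labeling
  durations, additionally fitting the asymptote per protein is
  underdetermined; the fixed-plateau default keeps one free parameter per
  peptide.
* **Natural anchor.** When unlabeled control animals are present, their
  observed relative M0 anchors `M0_nat` empirically (absorbing any
  instrument-specific envelope distortion); otherwise the theoretical
  natural envelope is used.
* **Measurability.** A fit is flagged measurable only when the fitted total
  M0 decline over the observed window exceeds 3× the residual SD. Slight
  M0 reductions otherwise convert to absurdly long half-lives; the point
  estimate is still reported, but the flag (and the dash rendering) keeps
  such values out of naive downstream use.
* **Duration subsets.** Any subset of durations can be excluded from the
  fits (`exclude_durations`), supporting designs where a labeling cohort
  must be discarded.

Peptide rate constants are combined per protein by `aggregate_protein()`:
the mean `k` across retained peptides, with a pooled SD formed as the
df-weighted mean of per-peptide residual variances. Before pooling,
`grubbs_filter()` applies the iterative two-sided Grubbs test (α = 0.05 by
default, removing at most one value per iteration, never testing below
n = 3); the critical value comes from the t-distribution formula, and the
filter is order-invariant.

## Quantification

Protein concentration uses a bovine serum albumin internal standard: a
known spike (default 8 pmol into 0.05 mg total protein) is digested with
the sample, so the geometric mean of peptide-to-BSA area ratios converts
to pmol per mg total protein. The geometric mean keeps the estimate
invariant to uniform area rescaling and balances peptides of very
different ionization efficiency. The default uses all quantified peptides;
a `top2` mode (two largest-area peptides) is provided because panel-style
assays sometimes restrict to best detectors — the two conventions differ,
and the mode is recorded in output metadata.

Absolute synthesis is concentration × k (pmol/mg/day) by default; a
division-by-half-life mode is retained because published tables sometimes
use it, and the two differ by exactly ln 2 — an identity asserted in the
test suite rather than left as a footnote.

## DNA/RNA fraction-new and the two-pool model

Nucleic-acid incorporation is measured as a heavy-to-base isotopomer ratio
of a derivatized ribose/deoxyribose, corrected for natural abundance
against an unenriched derivative standard:
`f = (r_sample - r_unlabeled) / (r_max - r_unlabeled)`, clipped to [0, 1]
with clip events counted and surfaced. The full-turnover ratio `r_max`
comes from binomial site labeling at the precursor plateau
(`max_ratio_for_precursor()`, excess `n p/(1-p)` over the natural base
ratio); the derivative's accessible-site count defaults to 4 and is a
config input, as instrument-specific derivatization chemistry varies.

A fraction-new series that is flat across durations at a level below 1 is
the signature of two pools: a fast pool (fraction `F`) fully labeled
before the first duration and a turnover-resistant pool effectively
unlabeled over the window. `two_pool_fit()` first tests whether the slope
over durations is significantly nonzero (linear regression at 0.05). If
not, it reports plateau semantics: `F` = mean level, fast half-life ≤
`min(t) ln2/ln 20` (a pool within 5% of plateau by the first duration),
slow half-life ≥ the longest duration. Otherwise it fits
`F (1 - exp(-k_fast t))`. Only bounds are reported for the pool
half-lives because the design (first duration ≥ 15 d) cannot localize a
2-day pool any more precisely — a deliberate refusal to over-report.

## Group comparisons

Age effects are tested per protein with the unpaired Welch t-test
(two-tailed, Welch–Satterthwaite df), difference convention old minus
young, and flagged with Benjamini–Hochberg at q = 0.05 within each table
family (concentrations, half-lives, absolute synthesis) separately, so a
family's flags match its own multiplicity burden. The Welch test is used
unpaired: the two age cohorts are different animals with different group
sizes, which precludes pairing. `invert_comparison()` recovers group means
from a (fold-change, mean-difference) pair — the identity used both to
seed realistic simulation truths from published tables and to check
printed values against each other in the acceptance tests.

## What the synthetic generator emulates — and what it does not

`generate_study()` produces the full data bundle (serum, peptide
isotopomer areas, nucleic ratios, ground truth) from a validated
`study_config()`. Its defaults are the study conditions: durations
15/30/45/60 d, 3–5 animals per duration and age, 3 unlabeled controls,
bolus 2% rising at 0.5/day to a 5.5% plateau, 8 pmol BSA into 0.05 mg,
multiplicative log-normal area noise at CV 2%, additive Gaussian noise
(SD 0.02) on fraction-new readings, and a DNA/RNA truth of `F = 0.6` with
fast/slow half-lives of 2 and 2000 days. The noise magnitudes are modelling
choices (no instrument noise model is published for this design); CV 2% is
typical of integrated high-resolution peak areas, and they are set where a
single knob controls them.

`paper_like_truth()` seeds a 36-protein configuration from published
fold-change/difference pairs via `invert_comparison()`; entries that
cannot be reconstructed (fold exactly 1, dashes, or sign-inconsistent
pairs) receive flagged placeholders, and peptide sequences are synthetic
tryptic-like placeholders except the one documented example peptide.

The generator emulates measurement noise on top of an exact forward model.
It does **not** emulate: chromatographic interference or integration error,
retention-time drift, charge-state effects, peptide-specific digestion
efficiency, dynamic protein pool-size changes during labeling, or
between-animal biological variance in `k` (noise enters through areas, not
rates). Passing recovery tests on this generator therefore demonstrates
the correctness of the estimators, not robustness to every failure mode of
real LC-MS data.

## Numerical choices and problem sizes

* All nonlinear fits use Levenberg–Marquardt with box constraints; rate
  starting values come from log-linearization, guarded for flat series.
* Degenerate inputs fail loudly (empty peptides, singular calibrations,
  single-duration series) or return flagged results (non-convergence,
  non-measurable kinetics) — never silent NAs.
* Half-lives of non-measurable proteins render as dashes, never infinity.
* The test and acceptance suites use deliberately small problem sizes
  chosen to keep the full suite fast while leaving Monte-Carlo margins
  wide: the shared pipeline fixture uses 3 proteins × 2 peptides × 20
  animals; recovery checks use 25–100 seeds with medians compared at
  tolerances several times the Monte-Carlo SE.

## Known limitations

* The exchangeable-hydrogen table is a literature default; laboratory
  re-calibration (e.g. against a fully-labeled standard) is expected for
  absolute accuracy of `M0_plateau`.
* The fixed-plateau fit assumes the dynamic pool is the whole pool; if a
  protein's turnover-resistant fraction differs between groups, its `k`
  comparison inherits that bias (the per-protein plateau mode exists for
  exactly this diagnosis, at the cost of a second parameter).
* Cohort-level precursor enrichment ignores animal-to-animal plateau
  variation; with a flat 5.5% plateau this is second-order, but designs
  with early euthanasia days would warrant per-animal precursor values.
* The two-pool fit reports `F` and half-life bounds only; resolving the
  fast pool's rate requires labeling durations shorter than the first
  plateau crossing.
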