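---
title: "Quantifying CT air trapping against the single-breath nitrogen test"
author: "airtrapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CT air trapping against the single-breath nitrogen test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtrapr)
```

## The measurement problem

Small airways (below about 2 mm internal diameter) are the main site of
obstruction in chronic airway disease, yet routine spirometry barely sees
them. Two indirect windows exist. Expiratory CT shows *air trapping*: lung
regions that fail to gain attenuation on expiration because gas cannot
leave them. The single-breath nitrogen washout test (SBNT) shows
*ventilation inhomogeneity*: after a vital-capacity inhalation of pure
oxygen, the exhaled N₂ concentration is recorded against expired volume,
and the slope of its alveolar plateau (phase III, "dN2", in %N₂ per litre)
rises when units empty unevenly; dN2 > 2.5 %N₂/L is the conventional
obstruction threshold, applied strictly (the boundary value is negative).

This package implements both measurements and the comparison layer between
them, and — because the cohort data the design is drawn from were never
deposited — ships a synthetic-data layer so that every computational claim
is checked against constructions with known ground truth.

## CT quantification

**Segmentation** is deliberately minimal and fully specified: parenchyma
candidates are voxels in [−1024, −500] HU; 6-connected components touching
the lateral image border are discarded (exterior air); the near-air
component (≤ −950 HU) reaching the most cranial slice is removed as the
tracheal/bronchial air column; components below `min_component_voxels`
(default 1000) are dropped. Both lungs are kept. Commercial tools do more
(morphology, lobe splitting), but on anything with threshold-separable
lungs this pipeline is exact, and its behaviour is fully testable.

**Densitometry.** For a mask and slice we report MLD (mean HU) and two
low-attenuation percentages, LAA% in [−1024, −850] and in [−910, −850].
Bounds are inclusive at both ends, which makes the nested-range invariant
(narrow ≤ full) exact even at integer HU. The narrow range's −910 floor
exists to exclude near-air densities produced by emphysema or cysts, which
would otherwise masquerade as trapping. Summaries are taken at four
caller-supplied slice positions — in the emulated acquisition these are the
upper lobes, the carina and two levels between carina and diaphragm,
matched manually between phases, which is why the package takes the
z-positions as input rather than detecting landmarks — and the fifth
"mean" row is their unweighted average (no weighting is obviously better,
and equal weights keep the mean interpretable). Left and right lungs are
pooled voxel-wise by default; side-wise averaging is available via
`combine = "average"` since the pooling convention of the original
software is unknowable.

**Indices.** For each basis the paired criteria are E/I, E−I and (E−I)/I,
computed on raw signed values. Signed-HU ratios are the convention that
makes published MLD thresholds (E/I around 0.89) attainable: −780/−860 =
0.907. Consequences worth knowing: on the MLD basis E/I is positive (both
values negative) and *decreases* as the expiratory lung densifies toward
0 HU, and E−I carries HU units while the LAA-based differences carry
percentage points — the fields are kept separate and never mixed. The
identity (E−I)/I = E/I − 1 holds to machine precision and is enforced by
test. A zero inspiratory LAA value leaves the two ratio criteria `NA` with
a warning; the difference survives.

## SBNT analysis

The analyzer takes the curve as (expired volume, %N₂) samples plus the
vital capacity VC, with an optional flow trace checked against the
0.3–0.5 L/s protocol window over mid-expiration (25–75% of VC; at least
90% of samples in range).

Two numerical decisions matter and are configurable:

- **Phase III window**: ordinary least squares over [30% of VC, phase IV
  breakpoint]. The 30% start is conventional SBNT practice (the analyzer
  hardware this emulates does not publish its window); windows shorter
  than 0.5 L are refused rather than fitted.
- **Closing volume**: the breakpoint minimising the total squared error of
  a *continuous* two-segment linear fit, by exhaustive search over sample
  positions in the second half of expiration (each candidate solved in
  closed form, so the search equals a brute-force oracle by construction).
  A phase IV is only accepted when the terminal slope exceeds twice the
  plateau slope; otherwise noise on a straight tail would constantly
  produce phantom closing volumes. CV = VC − breakpoint, else 0.

At the protocol noise level (0.05 %N₂ SD), recovery is tight: mean
absolute slope error about 0.005 %N₂/L with bias under 0.002, and closing
volumes within 5% of VC in 100/100 simulations (stage 3 of the analysis
workflow prints the table; the acceptance script recomputes it).

## The synthetic-data layer

The phantom is two ellipsoidal "lungs" in a soft-tissue cylinder
surrounded by air, with a vertical ~−1000 HU airway tube entering the
apical slice. Normal parenchyma is Gaussian: N(−880, 20) HU at inspiration
shifting to N(−750, 20) at expiration; trapped voxels keep an
inspiratory-like N(−880, 15) on expiration. Trapped voxels form focal
clusters around random seeds, but their *count* matches the requested
fraction exactly, so expiratory densitometry follows the two-component
mixture in closed form: MLD → 0.7·(−750) + 0.3·(−880) = −789 HU and
LAA% → the mixture tail probability, at trapped fraction 0.30. A length-2
`trapped_fraction` produces a linear cranio-caudal gradient (per-slice
exact counts) for testing level-wise monotonicity. What the phantom does
*not* model — real parenchymal texture, partial-volume boundaries,
respiratory motion, lobar anatomy — bounds what the green tests mean: they
certify the measurement chain, not robustness to anatomy. Segmentation
Jaccard of 1.0 on phantoms says the thresholds and topology rules are
implemented correctly, nothing more.

The washout generator builds the four phases analytically: zero N₂ dead
space, a logistic phase II rescaled to meet phase III continuously (its
exact shape is unconstrained by the schematic it imitates, and nothing
downstream depends on it), then two exact linear segments. Defaults:
VC 4 L, plateau start 25 %N₂ at 0.8 L expired, closing volume 0.8 L,
sampling 0.01 L, noise 0.05 %N₂, phase IV slope 3·dN2 + 6 (clearly above
the 2× acceptance gate across the simulated slope range 1–6).

The cohort generator works at the index level: each subject has a latent
trapped fraction f ~ U(0.05, 0.95); dN2 = 0.5 + 4·f + N(0, 0.3) (about
half the cohort crosses 2.5, matching the roughly balanced prevalence such
a study design needs); and all nine criteria are affine functions of f
through the same mixture formulas as the phantom, plus independent
per-criterion noise scaled to each criterion's latent SD. The noise
defaults (0.2× for E/I_MLD, 1.4× for the rest) are chosen for test power,
not realism: they give the statistics layer a *known, well-separated
ranking* to recover, which is what makes "the top-AUC criterion is the
generatively strongest one" a sharp test. Anatomical levels get
multipliers (0.7, 0.9, 1.1, 1.3) on f, emulating the gravity-dependent
cranio-caudal trapping gradient and powering the Friedman test. One
directional subtlety the generator exposes: E−I on the MLD basis
*decreases* with trapping (the expiratory lung fails to densify, shrinking
the HU gap), so its expected correlation with dN2 is negative while all
eight other criteria are positive — `airtrap_criteria()` records the signs.

## Statistics layer

- **Spearman** with midranks and a two-sided t-approximation p-value;
  constant columns are an error, not a silent NA.
- **Dendrogram**: distance 1 − |ρ_spearman|, average linkage (the
  clustering method is otherwise unconstrained; correlation distance is
  the natural metric for "similarity between criteria", and |ρ| treats
  anti-correlated criteria as informative). Criteria are ranked by
  cophenetic distance from dN2 and the closest three go to ROC, mirroring
  the correlate → cluster → ROC workflow.
- **ROC**: empirical curve over all observed thresholds, AUC via midranks,
  DeLong confidence interval (the standard choice when the CI method is
  unstated), best threshold by Youden J with ties resolved toward higher
  specificity, and reading direction chosen automatically so AUC ≥ 0.5
  (reported, since a "lower is positive" criterion like E−I_MLD is
  legitimate).
- **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures, from the mean-square decomposition — the variant appropriate
  when both readers are interchangeable raters of every subject and
  systematic bias should count against agreement. Other variants can be
  derived from the returned mean squares.
- **Friedman** across the four levels, with an exact permutation p-value
  when the permutation space (k!)ⁿ fits in 5·10⁵ (tie correction is
  permutation-invariant, so the enumeration compares the raw statistic),
  chi-square approximation otherwise. Fully tied data give statistic 0 and
  p = 1 by convention.

## Problem sizes and numerical tolerances

The test suite uses 48³–64³ phantoms for structural checks and one 256³
phantom (about 1.9 million lung voxels) for the densitometry oracles,
where tolerances are 3 standard errors of the analytic mixture; washout
recovery uses 100 curves per condition; the cohort layer uses 50 subjects
× 100 seeds. These sizes put the Monte-Carlo error well below every
tolerance asserted while keeping the suite quick to run. Throughout, the
generators are pure functions of (spec, seed) — the RNG state is saved and
restored around every draw — so all results are bit-reproducible.

## Known limitations

- Segmentation is threshold-plus-topology only; real CT with pleural
  effusion, dense consolidation, or lungs touching the chest-wall border
  violates its assumptions.
- Closing capacity (CV + residual volume) is not computed: RV is not
  measured by anything in this package.
- The level positions are inputs; there is no anatomical landmark
  detection.
- No registration between inspiratory and expiratory volumes: indices
  compare level summaries, not matched voxels.
- The cohort generator makes no attempt to mimic any real population's
  index distributions; it is an instrument for validating the statistics
  layer, and conclusions about real cohorts require real data.
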