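---
title: "Quantifying FT-IR chemical maps of the hippocampal formation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FT-IR chemical maps of the hippocampal formation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippospec)
```

## The analysis problem

FT-IR microspectroscopy records an infrared absorbance spectrum at every
pixel of a tissue section. In the electroshock kindling model, 12-µm
sections of the rat dorsal hippocampal formation are imaged in
transflection at ~25 µm pixels over 900–4000 cm⁻¹, and the question is
whether repeated stimulation (the kindled group, K) changes the
biochemical composition of the four cellular layers — granular (GR),
pyramidal (PY), multiform (MU) and molecular (MO) — relative to controls
(N), and whether those changes track the severity of the evoked
seizures.

`hippospec` implements that analysis chain end to end: band and massif
quantification with trapezoidal baseline correction, ratio chemical
maps, per-layer region-of-interest statistics, Mann–Whitney group
comparisons, and Ward clustering of cumulative seizure behavior into
severity subgroups. Because studies of this kind rarely deposit raw
hyperspectral cubes, the package also ships a first-class synthetic-data
module that generates layered tissue phantoms and seizure logs with
known ground truth; every stage of the pipeline is validated against
those phantoms.

## Band quantification

The quantified signal for a band with integration window $[\nu_l,
\nu_h]$ is the baseline-corrected integrated absorbance. A straight
baseline is drawn between the mean absorbance in the two anchor
sub-windows $[\nu_l, \nu_l + w]$ and $[\nu_h - w, \nu_h]$ (anchored at
each sub-window's mean wavenumber) and subtracted; the trapezoid rule is
then applied over the window:

$$A = \int_{\nu_l}^{\nu_h} \left[ s(\nu) - b(\nu) \right]\, d\nu .$$

Two consequences of this definition are load-bearing and tested as
invariants: the operation is *linear* in the spectrum, and any affine
function of wavenumber integrates to exactly zero (the baseline absorbs
it). Corrected areas can be negative; they are retained and flagged
rather than clipped, because silently clipping at zero would bias group
means upward in low-signal regions.

The parameter panel (`parameter_registry()`) covers 17 parameters: six
absolute intensities — amide I (1658 cm⁻¹, protein), the C–H stretching
massif (2800–3000 cm⁻¹, lipid), the phosphate bands (1080 and
1240 cm⁻¹), the CH₂/CH₃ bending massif (1360–1480 cm⁻¹, lipids and
cholesterol species) and the carbonyl ester band (1740 cm⁻¹) — and
eleven ratios: the β-sheet/α-helix structure ratio 1635/1658, the
lipid-chain ratio 2924/2955, and each band or massif relative to protein
(`/1658`) and to lipid (`/2800-3000`).

### Integration limits

The exact windows and baseline points used in the original instrument
software are not public, so the registry defaults are explicit,
documented choices, all overridable through `read_registry()`:

| band type | window | anchors |
|---|---|---|
| single bands (1080, 1240, 1740, amide I) | centre ± 24 cm⁻¹ | 8 cm⁻¹ half-width |
| massifs | printed range (2800–3000, 1360–1480) | 8 cm⁻¹ |
| amide I sub-components 1635 / 1658 | centre ± 8 cm⁻¹ | 4 cm⁻¹ |
| CH stretches 2924 / 2955 | centre ± 12 cm⁻¹ | 4 cm⁻¹ |

The sub-component windows are deliberately narrow so the paired bands
stay disjoint; that choice trades a little signal for interpretability
of the ratio. A practical resolution limit follows from the window
arithmetic: a ±8 cm⁻¹ window sampled at an 8 cm⁻¹ step contains two
channels, both of which are baseline anchors, so its corrected area is
identically zero. The default 4 cm⁻¹ grid (the usual 2× digitisation of
an 8 cm⁻¹ instrument resolution) gives 4–5 channels per narrow window,
which is workable but coarse — `integrate_band()` refuses windows with
fewer than two channels rather than returning a misleading number.

Ratio parameters guard against division blow-ups with a denominator
floor (default $10^{-3}$ AU·cm⁻¹); pixels below it are marked invalid
and excluded from all downstream statistics, never silently zeroed.

## ROI statistics

Pixels are attributed to layers by an integer label mask. Following the
field's practice of avoiding layer-boundary pixels, each layer region is
eroded before extraction (default radius 1 pixel ≈ 25 µm; the kernel is
the exact Euclidean disc, with off-image pixels counting as background).
Per-animal, per-layer means are the unit of analysis — the section is
the experimental unit, so pixel-level testing would pseudoreplicate.
Quality control enforces minimum pixel counts per layer (120 GR, 150 PY,
300 MU and MO; "several hundred" interpreted as 300 and configurable);
failing animal × layer × parameter cells are excluded from comparisons
and listed in the run report.

Group differences use the Mann–Whitney U test (two-sided by default):
exact p by the complete null distribution when both groups have ≤ 9
observations without ties, otherwise the normal approximation with tie
and continuity corrections. Significance is flagged per comparison at
α = 0.05 with no multiplicity correction, matching the per-comparison 5%
convention of the source analyses; a Benjamini–Hochberg column is
reported alongside for transparency but does not drive the flag. A fully
degenerate comparison (every value identical in both groups) returns
p = 1 with direction "none".

## Severity subgroups

For each animal the daily clonic and tonic records are totalled over the
21-day stimulation period, giving two features per seizure type:
cumulative intensity and cumulative duration (seconds). Animals are
clustered by Ward's minimum-variance method in the classic dialect —
the Lance–Williams Ward update applied to pairwise *squared* Euclidean
distances (`ward.D` on squared distances), matching the convention of
the legacy statistical packages used in this literature; `ward.D2` is
available by flag. The clonic tree is cut at k = 3 (CS / ICS / LCS:
severe, intermediate, light clonic seizures) and the tonic tree at k = 2
(TS / LTS), with labels ordered by cluster-mean cumulative intensity.

Whether to standardize the two features first is genuinely open (the
source analyses do not say). The package defaults to z-scoring because
intensity scores (unitless, ~0–100 cumulative) and durations (hundreds
to thousands of seconds) are incommensurate, and unstandardized
clustering would be dominated by whichever feature has the larger
variance; `standardize = FALSE` reproduces the raw-feature behaviour.
Subgroup comparisons (CS vs N, LCS vs N, CS vs LCS; TS vs N, LTS vs N,
TS vs LTS) exclude the intermediate clonic animals, mirroring how
severe-vs-light contrasts are reported in this literature.

## The synthetic-data module

Phantoms emulate the banded laminar architecture of the dentate
gyrus/cornu ammonis region as horizontal stripes (MO, GR, PY, MU from
top) on a background border, 50 × 35 pixels by default — chosen so every
layer clears its QC pixel minimum after 1-pixel erosion (GR 144, PY 192,
MU/MO 384). Each layer's noiseless spectrum is a sum of Gaussian bands
(Lorentzian available) at the registry's wavenumbers with layer-specific
amplitudes in the 0.1–1 AU range; Gaussians were chosen because their
closed-form (truncated) areas make exact ground truth available to the
oracles. Group effects are multiplicative factors on band amplitudes per
(group, layer, band centre).

The default effect map encodes exactly the anomaly directions the
pipeline is expected to detect — ↑1635 in MO, ↑1080 in GR and PY, ↓1240
in MU and MO, ↑1740 everywhere, ↓1360–1480 everywhere, ↑C–H massif in
PY — at ±15%. The magnitude is a free parameter: the source literature
reports significance marks, not effect sizes, so ±15% (within the
spec'd ±10–20% band) was fixed a priori as a moderate, detectable
effect. Other fixed-in-advance noise choices: additive i.i.d. Gaussian
pixel noise at 0.01 AU, per-pixel order-2 polynomial baseline drift with
0.005 AU coefficients, and a 5% between-animal log-normal CV on band
amplitudes, which is what gives the group comparison a realistic
animal-level variance component (with only pixel noise, per-animal means
would be nearly identical within group).

Seizure logs plant three clonic tiers (5/5/6 animals; daily intensity
means 4.2/2.2/0.4 on the 0–5 clonic scale) and two tonic tiers (7/9;
means 2.3/0.4 on the 0–3 tonic scale) in the 16-animal stimulated
cohort, with within-tier daily SDs of ~0.3–0.5 score points, so
cumulative features separate by >10 pooled SDs and the planted partition
is unambiguous. Daily scores are rounded and clamped to their scales;
durations are truncated at zero. Tonic tiers are assigned by a seeded
permutation so the two severity axes are not aligned animal-by-animal.

What the phantoms deliberately do **not** model: transflection optical
artifacts (standing-wave effects), Mie scattering, spatial correlation
of noise, within-layer biochemical gradients, and registration error
between mask and map (masks are ground truth by construction). Passing
the recovery tests therefore demonstrates that the *analysis chain* is
correct and unbiased under its stated noise model — not that it is
robust to every artifact of real transflection data.

## Numerical and degenerate-input choices

* All randomness flows from a single seed, fanned out into per-animal
  and per-stage sub-seeds (`simulate_study()`), so any stage can be
  reproduced in isolation; the analysis itself (`run_study()`) uses no
  randomness.
* Descending wavenumber axes are re-sorted ascending on ingestion and
  flagged in metadata.
* Merge ties in Ward clustering follow `stats::hclust`; the
  all-identical-features case is deterministic and warns.
* A zero tier dispersion is valid in the seizure simulator (it produces
  constant logs, useful for tests); only negative dispersions error.
* The map container is plain text: a one-line JSON header plus a CSV
  pixel × channel payload written at 17 significant digits, so
  write→read round trips are bit-exact.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` validate at the study's own
design size — cohorts of 16 K vs 10 N phantoms at the default 50 × 35
geometry and 776-channel axis — using 50 seeded effect runs and 30 null
runs in the test suite (12 + 12 in the faster acceptance script), 100+
random draws for the integration oracle, the complete enumeration of all
tie-free Mann–Whitney patterns with n₁, n₂ ≤ 6, 500 (200 in the script)
random point sets for the Ward reference, and 50 (25) seeds for severity
-tier recovery. These sizes were chosen to give stable empirical
fractions while keeping a full validation run in the minutes range on
one CPU.

## Known limitations

* The integration limits are defaults, not the original instrument
  settings; absolute parameter values are therefore not comparable
  across software, only within a configuration (ratios are more
  portable).
* Height-mode "intensity" is available but the default quantification
  is area, following the "area of one peak" phrasing of the method this
  package operationalises; on real data the two can disagree for
  overlapping bands.
* No scattering/EMSC correction is applied; strongly scattering samples
  would need preprocessing outside this package.
* The Mann–Whitney normal approximation is conservative near n ≈ 10–16
  (empirical type-I ≈ 0.043 at α = 0.05 in the shipped null
  simulation), which is the standard behaviour of the continuity
  correction, not a bug.
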