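# hippospec

Layer-wise biochemical analysis of FT-IR hyperspectral maps of the rat
hippocampal formation in the electroshock kindling model, plus
seizure-severity subgrouping of the stimulated animals.

## What it does, for whom

FT-IR microspectroscopy images a tissue section as a hyperspectral cube:
an infrared absorbance spectrum (900–4000 cm⁻¹) at every ~25 µm pixel.
Neurochemists use the integrated absorbance of characteristic bands as
proxies for biomolecule classes — amide I (1658 cm⁻¹) for protein, the
C–H stretching massif (2800–3000 cm⁻¹) for lipids, 1080/1240 cm⁻¹ for
phosphate-containing compounds, 1740 cm⁻¹ for carbonyl esters, the
1360–1480 cm⁻¹ massif for lipids/cholesterol, and the 1635/1658 ratio
for protein β-sheet content.

`hippospec` is for researchers running exactly this kind of study. It
provides:

1. **Band quantification.** For a band window $[\nu_l,\nu_h]$, a straight
   baseline through the mean absorbance of anchor sub-windows at each
   edge is subtracted and the trapezoid-rule integral
   $A=\int_{\nu_l}^{\nu_h}(s(\nu)-b(\nu))\,d\nu$ is computed per pixel
   (`integrate_band()`, `compute_parameter()`), for a standard panel of
   17 parameters (6 absolute, 11 ratios; `parameter_registry()`).
2. **ROI statistics.** Per-layer pixel populations (granular, pyramidal,
   multiform, molecular) with border erosion and pixel-count QC,
   per-animal means, and Mann–Whitney U comparisons of kindled (K) vs
   control (N) groups and of severity subgroups at α = 0.05
   (`layer_summaries()`, `run_comparisons()`).
3. **Behavior clustering.** Cumulative 21-day seizure intensity and
   duration per animal, Ward-clustered (squared Euclidean distances)
   into severe/intermediate/light clonic subgroups (k = 3: CS, ICS,
   LCS) and severe/light tonic subgroups (k = 2: TS, LTS)
   (`ward_cluster()`, `assign_subgroups()`).
4. **Synthetic ground truth.** Layered tissue phantoms whose spectra are
   Gaussian-band mixtures with known group × layer effects, and seizure
   logs with planted severity tiers (`make_phantom()`,
   `make_seizure_logs()`, `simulate_study()`), so the whole chain is
   testable against closed-form truth.

See the vignette (`vignettes/ftir-hippocampus-methods.Rmd`) for the
model, the defaults, and their rationale.

## Worked example

Simulate a full study at the design size (16 kindled + 10 control
animals) with the default effect map, run the complete analysis, and
look at the significant K-vs-N differences:

```r
library(hippospec)
study  <- simulate_study(seed = 42)
result <- run_study(study)
result
#> <study_result> 26 animals, 1768 summaries, 3 comparison table(s)
#>   group: 68 comparisons, 41 significant at alpha = 0.05
#>   clonic: 204 comparisons, 79 significant at alpha = 0.05
#>   tonic: 204 comparisons, 77 significant at alpha = 0.05

tab <- result$comparisons$group
head(tab[tab$significant, c("parameter", "layer", "direction", "p")])
#>    parameter layer direction            p
#> 4       1658    MO      down 2.509438e-02
#> 8  1635/1658    MO        up 1.643099e-04
#> 10 2800-3000    PY        up 2.789325e-05
#> 17      1080    GR        up 1.071557e-04
#> 18      1080    PY        up 1.071557e-04
#> 23      1240    MU      down 3.513962e-05
```

The table reads: in the molecular layer the β-sheet/α-helix ratio
(1635/1658) is significantly *elevated* in the kindled group (p ≈
2·10⁻⁴, Mann–Whitney U, n = 16 vs 10) — which is exactly the effect the
default phantom injects there; likewise ↑2800–3000 in PY, ↑1080 in
GR/PY, ↓1240 in MU. (The `1658 MO` row is a chance false positive: no
effect is injected on amide I, and at α = 0.05 a few of the 68
comparisons will flag by chance.)

The severity clustering recovers the planted behavioral tiers:

```r
table(merge(result$subgroups, study$seizure_truth)$clonic_subgroup,
      merge(result$subgroups, study$seizure_truth)$clonic_tier)
#>       intermediate light severe
#>   CS             0     0      5
#>   ICS            5     0      0
#>   LCS            0     6      0
```

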