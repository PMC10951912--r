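# nucleospat

Quantitative 3D analysis of how point-like nuclear objects — telomere and
centromere foci imaged by high-resolution fluorescence microscopy — are
organized inside the cell nucleus, for cell biologists asking whether that
organization is random, peripheral, clustered, regular or polarized, and how
it changes across the cell cycle.

The nucleus is represented by a binary voxel mask (isotropic grid, 100 nm by
default) plus a watertight triangular boundary mesh; objects are a set of
centers, volumes and equivalent-sphere radii bound to that shape. The package
covers the full chain from raw multi-channel volumes to population-level
statistics:

* **Segmentation** — nucleus from a lamin channel (directional closing,
  extended-minima markers, 3D watershed); point-like spots (echo suppression
  for axial reconstruction ghosts, h-maxima, automatic threshold selection
  minimizing the coefficient of variation of object size); sized blobs
  (dual-threshold with constrained dilation); per-object morphometrics; and
  median object-to-region distances from a Euclidean distance map.
* **Spatial statistics** — empirical distance functions per nucleus
  (**B** object→border, **C** object→center, **F** empty space,
  **G** nearest neighbor, **H** all pairwise), Monte-Carlo null models
  (completely random, optionally with a hard-core non-intersection
  constraint; orbital, preserving each object's border distance), and the
  **Spatial Distribution Index**. With observed summary `s_obs` (mean of the
  distance sample) and `n` simulated summaries,

      SDI = (k + u · (t + 1)) / (n + 1),   k = #{sims < s_obs},  t = #{ties},
                                           u ~ Uniform(0, 1)

  which is exactly uniform on [0, 1] under the null. SDI ≈ 0 means observed
  distances are smaller than the model predicts (attraction to the border for
  B, clustering for G/H); SDI ≈ 1 the opposite. At the population level a
  Kolmogorov–Smirnov test against Uniform(0, 1) decides whether a cohort of
  nuclei rejects the model.
* **Pattern metrics** — polarity index along each nuclear principal axis
  (`max(N⁺, N⁻)/(N⁺+N⁻)`: 0.5 balanced, 1 fully one-sided), peripheral
  fraction at a distance cutoff (0.5 µm telomeres / 1 µm centromeres by
  convention), 2D circularity `4πA/P²` of projected nuclei.
* **Enrichment** — ΔΔCt fold enrichment for proximity-labeling qPCR:
  `fold = 2^−((Ct_target − Ct_ref)_sample − (Ct_target − Ct_ref)_control)`,
  with condition-level folds normalized to a named control condition.
* **Synthetic data** — ground-truthed generators for nuclei (digitized
  ellipsoids of requested volume/elongation), object patterns (csr,
  hard-core, clustered, peripheral/orbital bands, polarized), two-channel
  image volumes with axial echo ghosts and noise, and qPCR Ct tables; these
  drive every test in the package.

## Worked example

```r
library(nucleospat)

nuc <- make_nucleus(volume_um3 = 800, elongation = 1.5, spacing_nm = 150,
                    seed = 1)
tel <- sample_pattern(nuc, pattern_spec("peripheral", n_objects = 142,
                                        band_width_um = 0.6, seed = 2),
                      stage = "eG1")
peripheral_fraction(tel, cutoff_um = 0.5)
compute_sdi(tel, "B", null_model_spec("random", n_sims = 99, seed = 3))
```

```
<nuclear_shape> V = 800.1 um^3 (mesh 798.7), A = 428.7 um^2, sphericity 0.972, elongation 1.50, 28154 vertices
<periphery_result> 115/142 objects within 0.50 um (81.0%)
<sdi_result> B-SDI = 0.001 (random model, 99 sims)
```

The generated nucleus hits the requested 800 µm³; 81% of the 142 objects sit
within 0.5 µm of the envelope (they were drawn in a 0–0.6 µm band, so a
fraction fall just beyond the cutoff); and the B-SDI of 0.001 says the
observed border distances are far below anything the completely random model
produces — a strong peripheral attraction, the signature expected of early-G1
telomeres. A cohort of truly random patterns, in contrast, gives uniform
SDIs:

```r
sdis <- vapply(1:20, function(i) {
  p <- sample_pattern(nuc, pattern_spec("csr", 30, seed = 10 + i))
  compute_sdi(p, "B", null_model_spec("random", seed = 100 + i))$sdi
}, numeric(1))
population_uniformity_test(sdis)
#> <population_test> n = 20, KS D = 0.1224, p = 0.9253 (not rejected at 5%)
```

ΔΔCt enrichment on a synthetic Ct table built with a true 10-fold telomere
enrichment and a condition at half the control's tethering:

```r
tb <- make_qpcr_table(c(telomere = 10, "LAD-CFHR3" = 30),
                      conditions = c(control = 1, siLAP2 = 0.5),
                      noise_sd = 0.1, seed = 4)
ddct_enrichment(tb, "telomere", control_condition = "control")
#> <enrichment_result> telomere vs iLAD-SMIM2
#>   condition     fold normalized_fold
#> 1   control 9.792827       1.0000000
#> 2    siLAP2 4.702348       0.4801829
```

The estimator recovers the 10-fold enrichment (9.79 under Ct noise) and the
control condition normalizes to exactly 1.

`run_spatial_analysis()` chains all of the per-nucleus computations over a
cohort and `write_report()` emits CSV tables, a provenance JSON and a text
summary.

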