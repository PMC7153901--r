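# gonadscan

Quantitative analysis of protein and mRNA accumulation along the
distal–proximal axis of the *C. elegans* germline, for researchers studying
niche–stem-cell signaling (Notch/GLP-1 acting through the CSL protein LAG-1
and its transcriptional targets *lst-1* and *sygl-1*) or any system where
levels must be compared along a tissue axis in **cell-diameter (cd)
coordinates** — one germ-nucleus row per unit of distance from the distal
tip.

The package implements, end to end:

* **Axis quantitation** — chain DAPI nucleus centroids into a cd coordinate
  system (`trace_axis()`, or hand-drawn lines via `manual_axis()`/
  `read_axis()`); extract 75-px-wide linescans with a per-pixel maximum over
  z-slices (`linescan()`); average into per-cd profiles (`profile_by_cd()`).
* **Profile pipeline** — subtract untagged-strain background, normalize each
  co-stained batch so the wild-type control's mean peak is 100, summarize as
  mean ± SD, and compute peak/base statistics
  (`subtract_background()`, `normalize_to_control()`, `summarize_profiles()`,
  `peak_base()`, `run_panel()`). Comparisons use a two-tailed Welch t-test
  for n < 30 and a Z-test for n ≥ 30, with tiers
  `***`/`**`/`*`/`NS` at p ≤ 10⁻⁴/10⁻³/10⁻² (`compare_levels()`).
* **Genetic decomposition** — split a reference peak into
  pathway-independent, target-mediated and other pathway-dependent
  percentages:
  `independent = 100·pathway_null/ref`,
  `via_targets = 100·(ref − targets_null)/ref`,
  `other = 100 − independent − via_targets`
  (`decompose_peak()`, `decompose_panel()`, `fold_at()`).
* **smFISH quantitation** — 3D connected-component spot detection with
  intensity-weighted centroids (`detect_foci()`), assignment to cd bins
  within a 100-px band (`assign_foci_to_cd()`), and spatial density
  comparisons between cd windows (`foci_density_summary()`).
* **Target classification** — CPM, a documented Welch test on
  log2(CPM + 0.5) with Benjamini–Hochberg FDR (`de_table()`), the
  ≥2-fold / FDR < 0.05 / CPM > 2 dependence filter (`filter_regulated()`),
  ChIP ∩ expression intersection (`intersect_targets()`), degradation
  time-course primary/secondary classification (`classify_timecourse()`),
  half-life upper bounds from fold-drop tables (`half_life_bound()`), and
  ΔΔCt relative quantitation (`delta_ct()`).
* **Synthetic data with planted truth** — genotype profile panels
  (`generate_profiles()`, shipped panel YAMLs), multi-channel gonad image
  stacks (`generate_gonad_image()`), and negative-binomial expression
  studies with planted primaries/secondaries and exponential decay
  (`generate_expression()`), so every stage is testable without instrument
  data.

## Worked example

Run the full profile pipeline on the LAG-1 genotype panel (20 simulated
germlines per genotype with replicate noise) and decompose peak
accumulation:

```r
library(gonadscan)
library(dplyr)

panel <- load_panel("fig3")
res <- run_panel(panel, seed = 1)

wt <- filter(res$summary, genotype == "wt")
peak_base(wt, panel$peak_window, panel$base_cd, panel$peak_stat)
#> # A tibble: 1 × 5
#>   genotype peak_mean base_mean fold_ratio infinite_ratio
#>   <chr>        <dbl>     <dbl>      <dbl> <lgl>
#> 1 wt             100      15.3       6.54 FALSE

decompose_panel(res$summary, panel,
                ref = "gld2_gld1",
                pathway_null = "gld2_gld1_glp1",
                targets_null = "gld2_gld1_lst1_sygl1") |> tidy()
#> # A tibble: 3 × 3
#>   component       percent percent_rounded
#>   <chr>             <dbl>           <dbl>
#> 1 independent        39.0              39
#> 2 via_targets        29.5              30
#> 3 other_dependent    31.5              31
```

Wild-type LAG-1 peaks at 4 cd (anchored at 100 by the internal control) and
falls to a proximal base of ~15% of peak — a ~7-fold drop (6.5 in this
noisy draw; the zero-noise fixture gives exactly 7.0). In the
meiotic-entry-defective reference background, 39% of the peak survives loss
of the signaling pathway, so 61% is pathway-dependent, about half of it
(30%) mediated by the two transcriptional targets.

The expression side, on the paper-like synthetic study (2000 genes, 137
bound, 94 planted dependent):

```r
cfg <- expression_config()
sim <- generate_expression(cfg, seed = 1)
tab <- de_table(sim$on_off,
                group_a = grep("^OFF", colnames(sim$on_off)),
                group_b = grep("^ON", colnames(sim$on_off)),
                contrast = "ON_vs_OFF")
dependent <- filter_regulated(tab, "up")
length(dependent)
#> [1] 94
intersect_targets(sim$bound_genes, dependent)
#> [1] "primary_01" "primary_02"
```

The dependence filter recovers exactly the 94 planted dependent genes, and
intersecting them with the 137-gene bound list yields exactly the two
planted primary targets.

See `vignettes/gonad-quantitation.Rmd` for the full account of the models,
conventions and design choices.

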