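# cardiohep

Quantitative analytics for rodent studies that link nonalcoholic fatty
liver disease (NAFLD) to cardiovascular risk. The package covers the four
measurement arms such studies combine, as a tidy, seeded, fully testable R
pipeline:

- **Cardiomyocyte morphometry.** Cross-sectioned cells from labeled
  histology fields are measured for area and four shape descriptors —
  aspect (major/minor axis of the moment-equivalent ellipse), area/box
  (area over the principal-axis-aligned bounding box), roundness
  (perimeter² / 4π·area) and radius ratio (max/min centroid-to-boundary
  distance) — which combine into the **cardiomyocyte irregularity index**

  CII = aspect − area/box + roundness + radius ratio.

  A perfect circle scores (1, π/4, 1, 1), so the CII fixed point is
  3 − π/4 ≈ 2.215; every kind of irregularity raises it. Cells are then
  gated on the area-versus-CII plane against control-population quantiles
  into six classes — N (normal), I (normal-size irregular), HR/HI
  (hypertrophic regular/irregular), AR/AI (atrophic regular/irregular) —
  and summarized per animal (class percentages, mean CII, area
  coefficient of variation).
- **Collagen quantification.** Picrosirius-red-stained liver fields are
  quantified by red-channel dominance, R − (G+B)/2 > t (Otsu default),
  yielding stained area fraction and intensity, averaged over the ten
  fields per animal the protocol prescribes.
- **Serum analytics.** Atherogenic lipid ratios — Castelli's Risk Index I
  (TC/HDLc), II (LDLc/HDLc) and the atherogenic coefficient
  ((TC − HDLc)/HDLc) — and circulating-miRNA relative expression by the
  2^−ΔΔCt method against a cel-miR-39 spike-in normalizer.
- **Group statistics.** The normality-gated comparison workflow:
  Shapiro–Wilk on every group routes each variable to one-way ANOVA +
  Tukey HSD (parametric) or Kruskal–Wallis + Dunn's test (nonparametric),
  with a compact letter display (groups sharing a letter are not
  significantly different) and route-matched summaries (mean ± SD or
  median with IQR).

Because studies of this design rarely deposit raw images or per-animal
values, the package ships a first-class **synthetic-data generator**:
seeded cell fields with per-cell ground truth (class, area, elongation,
boundary noise), collagen fields with known stained fraction, serum panels
with group structure, and Ct tables encoding known fold changes. Every
downstream stage is validated by recovering that truth.

## Worked example

```r
library(cardiohep)

# a 1000-cell control population defines the gates
control    <- measure_cells(render_field(sample_cell_truth(
  cell_population_spec(c(N = 1), n_cells = 1000, seed = 1))), pixel_size = 0.4)
thresholds <- derive_thresholds(control)
thresholds
#> <morph_thresholds> area band [232.9, 368.7] um^2, CII cutoff 2.845 (n = 1000 control cells)

# a diseased animal: 70% normal, 20% hypertrophic, 10% atrophic cells
cells <- measure_cells(render_field(sample_cell_truth(
  cell_population_spec(c(N = 0.7, HR = 0.2, AR = 0.1),
                       n_cells = 500, seed = 7))), pixel_size = 0.4)
head(cells, 3)
#>   cell_id  area aspect area_box roundness radius_ratio   cii
#> 1       1  90.6   1.30    0.778     0.963         1.33  2.81
#> 2       2 181.    1.01    0.760     0.965         1.04  2.26
#> 3       3 247.    1.19    0.768     0.979         1.21  2.61

population_profile(classify_cells(cells, thresholds))
#>   n_cells percent_N percent_I percent_HR percent_HI percent_AR percent_AI mean_cii area_variability
#> 1     500      60.6       2.6       23.6        1.6       11.2        0.4    2.542            0.432
```

The profile reads: 60.6% of this animal's cardiomyocytes are normal in
both size and shape, 23.6% are hypertrophic with regular outlines, 11.2%
atrophic — the hypertrophy/atrophy burden injected by the generator, seen
through the default 5/95-quantile control gates (which, by construction,
also relabel ~15% of truly normal cells; see the vignette). The area
coefficient of variation (0.43) is the per-animal size-variability
statistic.

```r
atherogenic_ratios(tibble::tibble(animal_id = c("r1", "r2"),
                                  TC = c(200, 80), LDLc = c(120, 25),
                                  HDLc = c(50, 35)))
#>   animal_id    TC  LDLc  HDLc CRI_I CRI_II    AC
#> 1 r1          200   120    50  4     2.4    3
#> 2 r2           80    25    35  2.29  0.714  1.29

ct    <- sim_ct_table(c(control = 1, NAFLD = 4), "control", seed = 11)
folds <- fold_change_ddct(ct, "control")
dplyr::summarise(dplyr::group_by(folds, group), mean_fold = mean(fold))
#>   group   mean_fold
#> 1 NAFLD        4.18
#> 2 control      1.01
```

Animal r1 carries a CRI-I of 4.0 (high cardiovascular risk); the Ct table
generated with a true 4-fold up-regulation is recovered at 4.18 from ten
noisy samples. `compare_groups()` then takes any such per-animal table and
returns omnibus p-values, adjusted pairwise comparisons and letters;
`run_study_pipeline(seed, out_dir)` drives all four arms end to end over a
five-group study design and writes tidy CSVs.

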