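# telofish

Quantitative FISH (qFISH) telomere length analysis from two-channel
fluorescence microscopy images, in R.

## The problem

In telomere qFISH, tissue sections are hybridized with a Cy3-labelled
telomere-specific PNA probe and counterstained with DAPI. Because the probe
signal is linearly proportional to telomere repeat length, relative telomere
length can be measured per cell from digital images: each telomeric spot is
scored by its Cy3 fluorescence intensity multiplied by its area, the spot
values of a cell are summed, and the sum is normalized to the cell's total
DAPI signal, giving the **telomere fluorescence intensity**

```
TFI_cell = ( Σ_spots I_spot · A_spot ) / D_cell
```

where `I` is mean spot intensity on the unenhanced Cy3 image, `A` is the
spot area and `D` the integrated DAPI signal over the cell's nuclear ROI.
Three derived quantities carry the biology:

* **epithelial/stromal ratio** `R = TFI_epithelial / mean(TFI_stromal)`
  per image — stromal telomeres are stable across disease stages, so the
  ratio corrects staining and exposure variation between specimens;
* **specimen mean** — mean TFI (or mean ratio) over all cells of one
  biological specimen;
* **TLV (telomere length variation)** — the sample standard deviation of
  the per-cell telomere value within a specimen; low TLV indicates uniform
  telomere lengths, consistent with clonal expansion.

The package is aimed at groups studying telomere dynamics in tissue
(e.g. the gastric cardia → Barrett's esophagus → dysplasia → adenocarcinoma
sequence, or telomerase-deficient mouse models): it implements the whole
measurement chain plus the group statistics used to compare tissue classes,
and — because raw qFISH images are rarely deposited — a synthetic image
generator with per-cell ground truth so the chain can be validated end to
end.

## What is in the package

* `simulate_specimen()` / `simulate_cohort()` — render two-channel 16-bit
  specimens: crypt-arranged epithelial nuclei vs scattered stromal nuclei,
  per-cell telomeric spots with compartment-specific lognormal integrated
  intensities, DAPI nuclei (with vacuole holes for mucus/goblet cells),
  background offset + gradient, PSF blur, Poisson–Gaussian noise, and a
  ground-truth table (`T_true`, `D_true` per cell).
* `subtract_background()`, `sharpen()`, `rolling_ball()`,
  `segment_spots()`, `extract_spots()`, `quantify_cells()` — the spot
  measurement chain: background normalization, 3×3 unsharp sharpening,
  rolling-ball (grayscale opening) enhancement, thresholding with size
  filtering and label-preserving mask growth, then measurement on the
  *unenhanced* Cy3 image and per-cell TFI assembly.
* `epithelial_stromal_ratios()`, `specimen_mean()`, `tlv()`,
  `subtype_means()`, `summarize_specimens()` — specimen-level metrics.
* `t_from_summary()`, `t_unpaired()`, `t_paired()`, `anova_oneway()`,
  `tukey_hsd()`, `pooled_group_summary()`, `positive_ratio()`,
  `organoid_norm()` — the statistics layer, including summary-statistic
  t-tests so published `mean ± SD (n)` triples can be re-analyzed.
* `run_pipeline()` / `make_report()` and a thin CLI
  (`inst/scripts/telofish`) — simulate → quantify → metrics → stats as one
  reproducible, seeded run writing `cells.csv`, `specimens.csv`,
  `ratios.csv`, `tests.csv`, `run.log` and a markdown report.

## Worked example

Re-analyze a published comparison from its printed summaries — γH2AX
positive:negative cell ratios of 0.36 ± 0.13 SD (n = 8) vs 0.22 ± 0.09 SD
(n = 8):

```r
library(telofish)
t_from_summary(group_summary(0.36, 0.13, 8), group_summary(0.22, 0.09, 8))
#> student: statistic = 2.504, df = 14, p = 0.02525
```

The pooled two-sample t-test gives t = 2.50 on 14 df, p ≈ 0.025 — the
"p < 0.03, unpaired t-test" significance of the original comparison.

Simulate one cardia-like specimen (65 crypt epithelial + 35 stromal cells,
true epithelial:stromal signal ratio 0.9) and measure it:

```r
sp  <- specimen_template("cardia", epithelial_stromal_ratio = 0.9, seed = 1)
sim <- simulate_specimen(sp)
q   <- quantify_image(sim$cy3, sim$dapi, sim$labels)
cells <- q$cells
ann <- sim$truth[match(cells$cell_label, sim$truth$cell_label), ]
cells$compartment <- ann$compartment; cells$subtype <- ann$subtype
cells$specimen_id <- cells$image_id <- "cardia_01"
cells$tissue_class <- "cardia"
summarize_specimens(cells)[, c("specimen_id", "n_cells", "mean_tfi",
                               "mean_ratio", "tlv")]
#>   specimen_id n_cells  mean_tfi mean_ratio       tlv
#> 1   cardia_01     100 0.5752172  0.8690715 0.2711727
```

All 100 cells are quantified; the estimated epithelial/stromal ratio 0.869
recovers the generating value 0.9 within a few percent, and `tlv` is the
cell-to-cell SD of epithelial TFI for this specimen.

The same analysis from the shell:

```sh
Rscript inst/scripts/telofish run --config my_cohort.yaml --out results_dir
```

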