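# kinetoquant

Quantitative analysis of kinetochore protein levels from fixed-cell
immunofluorescence z-stacks, plus label-free affinity-purification
interactome analysis — the two computational workflows behind a typical
"does protein X still localize to kinetochores after depleting protein Y?"
study.

## Who this is for

Cell biologists (and their analysts) who image mitotic cells on a widefield
system (e.g. 0.2 µm z-steps, 0.08 µm pixels), co-stain with an
anti-centromere antibody (ACA) plus one or more antibodies of interest, and
need per-kinetochore, background-corrected intensities feeding honest group
statistics; and proteomics users with label-free protein-group intensity
tables from bait-vs-control pull-downs who need a volcano classification.

## What it computes

**Imaging flow.** For each cell:

1. a cuboid region of interest around the Otsu-thresholded DAPI signal;
2. 3D segmentation of kinetochores from the ACA channel: Otsu threshold,
   connected components (26-connectivity), minimum object size 70 voxels;
3. each ACA mask is expanded in-plane by 4 px (0.32 µm) to capture the outer
   kinetochore; local background is the mean intensity in a 2-px annulus
   separated from the mask by a 1-px gap, excluding all neighbouring masks;
4. per kinetochore and channel, the background-corrected integrated
   intensity

   corrected_sum = Σ_mask I − mean_annulus(I) · |mask|

5. per-cell summaries (mean of corrected sums; the cell is the sampling
   unit) are compared across conditions: Shapiro–Wilk-gated unpaired
   Student's t-test vs Mann–Whitney for two groups, Kruskal–Wallis ANOVA on
   ranks with Dunn's post hoc for three or more, with the usual star tiers
   (\*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05).

**Interactome flow.** From a bait-vs-control LFQ table (4 replicates each):
valid-value filtering (≥ 2 present per group, no imputation), per-protein
log2 fold change of mean log2 intensities, unpaired Student's t-test on
log2 values, and significance at p < 0.05 with positive fold change;
−log10 p vs log2 FC are the volcano coordinates.

**Synthetic data.** Because such studies rarely deposit raw stacks, the
package ships a ground-truthed generator: sister-kinetochore pairs rendered
as voxel-integrated anisotropic Gaussians inside a nuclear ellipsoid,
Poisson shot noise + Gaussian read noise, and LFQ tables with planted
enrichment — every stage of the pipeline is testable offline.

## Worked example

A simulated 65 % depletion experiment, 10 cells per group:

```r
library(kinetoquant)
ctrl  <- sim_image_params(grid_dims = c(16, 56, 56), n_pairs = 4, seed = 1)
cells <- simulate_depletion_experiment(ctrl, depleted_fraction = 0.65,
                                       n_cells_per_group = 10, seed = 1)
summ <- do.call(rbind, lapply(cells, function(cc) {
  regs <- segment_kinetochores(cc$stack, crop_dapi_roi(cc$stack))
  summarize_cell(measure_cell(cc$stack, regs, channels = "Bod1"),
                 cell_id = cc$cell_id, condition = cc$condition)
}))
head(summ, 3)
#>    cell_id condition phase channel  summary n_regions
#> 1 cell_001   control  <NA>    Bod1 25881.96         8
#> 2 cell_002   control  <NA>    Bod1 26849.30         8
#> 3 cell_003   control  <NA>    Bod1 32340.09         7

norm <- normalize_to_reference(summ, "control")
aggregate(normalized ~ condition, norm, mean)
#>   condition normalized
#> 1   control   1.000000
#> 2  depleted   0.370856

route_two_group_test(summ$summary[summ$condition == "control"],
                     summ$summary[summ$condition == "depleted"])
#> t-test: groups [a, b], n = [10, 10]
#> statistic = 12.91, p = 1.541e-10 (***)
```

The depleted group's mean corrected intensity comes back at 0.371 of
control (truth: 0.35 after a 65 % amplitude reduction; the residual is
10-cell sampling noise), and the normality gate routed the comparison to a
pooled-variance t-test, which is highly significant.

The same stages are scriptable through a YAML config and the
`simulate` / `quantify` / `compare` / `volcano` subcommands of `run_cli()`;
see `?run_cli` and `?read_pipeline_config`.

## Documentation

The methods vignette (`vignettes/kinetoquant-methods.Rmd`) describes the
measurement model, the noise model, every tunable parameter with its
default and rationale, what the synthetic generator does and does not
emulate, and the package's documented deviations where the published
description is ambiguous.
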