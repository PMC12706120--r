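# lysodyn

Quantitative analysis of endo-lysosomal function: lysosome motility from
live-cell videos, degradative capacity from two-channel DQ-BSA imaging and
plate-reader cathepsin assays, and differential expression of
lysosome-enriched proteomes.

Lysosomes are the cell's degradative endpoint, and their positioning and
transport are tightly coupled to their function: directed, microtubule-based
movement delivers cargo and enzymes, while a near-immobile perinuclear pool
handles bulk degradation. In neurodegenerative disease models both arms go
wrong at once — transport slows, endocytic uptake and proteolytic output
shift, and the lysosomal proteome remodels. Measuring this requires a chain
of small, error-prone steps: detecting diffraction-limited spots, linking
them into tracks, summarising motility per track, comparing groups with
appropriate nonparametric statistics, and testing thousands of proteins with
few replicates. `lysodyn` implements that chain as composable, tibble-first
functions, and pairs **every** analysis stage with a synthetic-data
generator that knows the ground truth, so each estimator is validated
end-to-end without any raw microscopy data.

The package is tidyverse-native: inputs and outputs are tibbles, fitted
objects have `tidy()`/`glance()` methods, and `plot_*()`/`autoplot()`
helpers draw the standard figures (rose plots, rainclouds, volcano plots,
MSD curves).

## What's inside

| module | entry points |
|---|---|
| synthetic data | `simulate_tracks()`, `render_video()`, `simulate_dqbsa_field()`, `simulate_intensity_matrix()`, `simulate_platereader()` |
| spot detection | `detect_spots()`, `preprocess_frame()`, `cell_rois()`, `summarize_spots()` |
| tracking | `link_spots()`, `evaluate_tracking()` |
| motility | `track_metrics()`, `ensemble_msd()`, `classify_mobility()`, `displacement_angles()` |
| statistics | `bootstrap_parameter()`, `compare_groups()`, `dunn_test()`, `rose_histogram()`, `raincloud_summary()` |
| proteomics | `build_matrix()`, `moderated_ttest()`, `apply_cutoffs()`, `overlap_sets()`, `ora_hypergeometric()`, `crossref_curated()` |
| assays | `segment_cells()`, `per_cell_ratio()`, `cathepsin_activity()` |

## Worked example

Simulate two motility conditions (a control and a slowed-transport
condition), summarise per-track metrics, and compare the groups:

```r
library(lysodyn)
library(dplyr)

ctrl_p <- motility_params(p_mobile = 0.6, speed_mobile = 1)
slow_p <- motility_params(p_mobile = 0.6, speed_mobile = 0.6)
ctrl <- track_metrics(simulate_tracks(ctrl_p, 300, seed = 11))
slow <- track_metrics(simulate_tracks(slow_p, 300, seed = 12))

summarise(ctrl, mobile_fraction = mean(mobile),
          mean_velocity_um_s = mean(mean_velocity_um_s),
          msd_um2 = mean(msd_um2))
#> # A tibble: 1 × 3
#>   mobile_fraction mean_velocity_um_s msd_um2
#>             <dbl>              <dbl>   <dbl>
#> 1            0.63               1.06   0.179

bootstrap_parameter(ctrl$mean_velocity_um_s, "mean", n_boot = 1000, seed = 13)
#> <boot_result> mean = 1.0559, 95% percentile CI [0.98134, 1.1286] (1000 replicates of 300)

df <- data.frame(value = c(ctrl$mean_velocity_um_s, slow$mean_velocity_um_s),
                 group = rep(c("control", "slow"), each = 300))
compare_groups(df, design = "two_group")
#> <group_comparison> student t (unpaired, two-tailed): statistic 3.3915, p 0.000741
```

Differential expression on a simulated lysosome-enriched proteome
(2000 proteins, 4 samples per group, 10% of proteins shifted by one log2
unit), with the empirical-Bayes moderated t-test and the two printed cutoff
regimes:

```r
sim <- simulate_intensity_matrix(de_sim_params(), seed = 14)
de <- moderated_ttest(sim$matrix, "case", "control")
glance(de)
#> # A tibble: 1 × 7
#>   n_proteins df_prior  s0_sq n_up_stringent n_down_stringent n_up_lenient
#>        <int>    <dbl>  <dbl>          <int>            <int>        <int>
#> 1       2000     3.92 0.0631             49               55          116
#> # ℹ 1 more variable: n_down_lenient <int>

hits <- apply_cutoffs(de, stringent_regime())
str(hits[c("up", "down")], list.len = 2)
#> List of 2
#>  $ up  : chr [1:49] "P0022" "P0027" "P0036" "P0041" ...
#>  $ down: chr [1:55] "P0002" "P0005" "P0006" "P0011" ...
```

(The estimated variance-prior hyperparameters — `df_prior` 3.92, `s0_sq`
0.0631 — recover the generator's truth of 4 and 0.0625.)

Cathepsin activity from a plate-reader table, blank-corrected and
normalised to incubation time and protein load:

```r
plate <- simulate_platereader(3, rate_rfu_per_min = 8.5, blank_level = 2000,
                              inhibited_fraction = 0.1, seed = 15)
cathepsin_activity(plate)
#> # A tibble: 3 × 5
#>   sample activity_rfu_min_mg inhibited_activity_rfu_min_mg specific_activity_rfu_min_mg clamped
#>   <chr>                <dbl>                         <dbl>                        <dbl> <lgl>
#> 1 S01                     85                           8.5                         76.5 FALSE
#> 2 S02                     85                           8.5                         76.5 FALSE
#> 3 S03                     85                           8.5                         76.5 FALSE
```

The full imaging chain — render a video from simulated tracks, detect
spots, link them, and score the result against ground truth — is shown in
the methods vignette (`vignettes/lysodyn-methods.Rmd`), along with the
models, parameter rationales and numerical choices.

## Tests

The suite (unit, property-based and end-to-end acceptance tests, with
independent brute-force oracles for the assignment, filtering and ROI
logic, and `limma` as an external oracle for the moderated t-test) runs
with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "lysodyn", load_package = "installed")'
```
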