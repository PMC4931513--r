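# hcsnano

Analysis of high-content RNAi screens for nanoparticle (NP) trafficking
to lysosomes.

In such a screen, cells depleted of one gene product per well are pulsed
with fluorescent NPs, fixed, and stained for nuclei (Hoechst) and the
lysosomal membrane protein LAMP1. The question per well is how much of
the internalized NP signal has reached LAMP1-positive compartments. The
readout is the **LAMP1-associated NP ratio**

```
R_well = mean over cells( total NP intensity inside LAMP1 spots )
       / mean over cells( total NP intensity inside the cell mask )
```

normalized to non-targeting control wells (NEG), so R < 1 means reduced
delivery of NPs to lysosomes relative to control. `hcsnano` implements
the full chain for this readout, plus the statistics a screen needs
around it:

* rolling-ball background subtraction (`subtract_background`, radius
  10 px by default),
* nucleus / cell-body / LAMP1-spot segmentation (`segment_nuclei`,
  `segment_cells`, `detect_spots`), per-cell measurement and QC
  (`measure_cells`, `qc_filter_cells`: border, apoptotic, mitotic cells
  removed), and the per-well ratio (`well_ratio`),
* viability filtering (< 50 cells in any well or < 150 across
  replicates discards a treatment), NEG normalization, phenotype calls
  at 2 SD (mild) / 3 SD (strong) below the NEG mean, k-of-n siRNA
  validation and one-tailed Student's t-tests (`screen_statistics`,
  `validate_screen`, `control_readouts`),
* rank-weighted colocalization (RWC) for confocal-style validation
  (`rwc`, `percent_colocalized`),
* a seeded synthetic-microscopy generator with exact planted ground
  truth (`simulate_field`, `simulate_screen`, `simulate_well_table`),
  used by the test suite and usable for power analysis of screen
  designs,
* an end-to-end pipeline with TIFF/CSV/YAML interfaces
  (`run_pipeline`, `run_config`) and a thin CLI (`inst/cli/hcsnano`).

The per-cell RWC of NP with a marker channel is

```
RWC = sum_{i in C} I_NP(i) * (n - |rank_NP(i) - rank_M(i)|)/n
    / sum_{i in A} I_NP(i)
```

over the n pixels of a cell, with A the NP-above-threshold pixels and C
those above both thresholds: the fraction of NP intensity colocalizing
with the marker, discounted by rank disagreement.

## Worked example

A small end-to-end screen: five gene depletions (three planted
trafficking effects, two nulls) with four NEG wells per replicate, three
replicates, three imaged fields per well.

```r
library(hcsnano)

lay <- make_screen_layout(c("DNM2", "CLTC", "RAB7A", "CTRL1", "CTRL2"),
                          n_replicates = 3, n_neg_wells = 4)
cfg <- run_config(mode = "all", out_dir = "demo_run", seed = 42,
  layout = lay,
  effects = list(DNM2 = 0.5, CLTC = 0.55, RAB7A = 0.7,
                 CTRL1 = 1, CTRL2 = 1),
  sim_config = simulation_config(n_cells_per_field = 30),
  fields_per_well = 3)
res <- run_pipeline(cfg)
res$treatments[, c("treatment_id", "normalized_ratio_mean",
                   "normalized_ratio_sem", "total_cells", "viable",
                   "phenotype")]
#>   treatment_id normalized_ratio_mean normalized_ratio_sem total_cells viable       phenotype
#> 1         DNM2                 0.491              0.00579         197   TRUE strong_decrease
#> 2         CLTC                 0.552              0.01149         196   TRUE strong_decrease
#> 3        RAB7A                 0.731              0.02540         196   TRUE strong_decrease
#> 4        CTRL1                 1.074              0.02512         197   TRUE   mild_increase
#> 5        CTRL2                 1.001              0.01263         199   TRUE            none
```

Reading the table: every treatment retained enough analyzed cells to be
viable; the planted 0.5×/0.55×/0.7× reductions in lysosomal delivery
are recovered as normalized ratios 0.49/0.55/0.73 (mean ± s.e.m. over
the three replicates) and called as decreases against the NEG
distribution, while the nulls sit near 1. `report_screen(res)` prints
the hit list sorted by ascending ratio; all stage outputs (`wells.csv`,
`cells.csv`, `treatment_results.csv`, `validation.csv`, a JSON run
manifest) land in `out_dir`, and rerunning with the same seed reproduces
them byte for byte.

The same run can be driven from a shell:

```sh
Rscript inst/cli/hcsnano all --config run.yaml --seed 42 --out demo_run
```

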