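# actomap

Quantification of actin dynamics, membrane-protein recovery, endomembrane
compartments and mutant mapping in plant root cells — the numerical
backbone of phenotyping a cytoskeleton-pathway mutant, implemented as one
tested R package with synthetic ground-truth generators for every stage.

## Who this is for

Plant cell biologists (and anyone doing live-cell imaging of filament
networks) who need the standard readouts behind mutant phenotyping:

* **Actin dynamics** from single-plane time-lapse stacks: for frame *i*,
  the mean Pearson correlation and mean absolute per-pixel difference
  against every other frame *j ≠ i*,
  `C_i = mean_{j≠i} corr(F_i, F_j)`, `D_i = mean_{j≠i} mean|F_i − F_j|`,
  summarized per cell. A frozen (actin-stabilized) cell scores C = 1,
  D = 0; faster remodeling lowers C and raises D.
* **Filament architecture** from z-stacks: per-slice threshold →
  small-object removal → Zhang–Suen thinning → union projection; bundling
  as the skewness `g1 = m3 / m2^(3/2)` of projected intensities at
  skeleton pixels, and occupancy as skeleton pixels over cell-mask area.
* **FRAP** (fluorescence recovery after photobleaching): normalization to
  the pre-bleach mean, then a bounded least-squares fit of
  `F(t) = F0 + A (1 − exp(−k t))`, reporting mobile fraction
  `Mf = A / (1 − F0)`, halftime `t½ = ln2 / k`, and R².
* **BFA compartments**: threshold → 8-connectivity particle labeling →
  per-particle area and mean intensity measured on the original image.
* **SNP-index mapping**: strict FASTQ quality filtering (discard iff
  > 10% of bases under Q30), wild-type-substituted reference construction,
  per-site SNP-index `alt / (ref + alt)`, and homozygous-candidate
  extraction at depth > 5 and index > 0.9 (both strict).
* **Expression and statistics**: `2^−ΔCp` relative qPCR expression and the
  t / ANOVA + Tukey HSD harness used to present per-replicate results.

Each analysis has a seeded simulator with known ground truth
(`make_filament_timelapse()`, `make_frap_trace()`, `make_bfa_image()`,
`make_allele_counts()`), so the whole pipeline is testable without a
microscope or sequencer.

## Worked example

```r
library(actomap)

# a remodeling cell vs a frozen (stabilized) control, same seed
mock   <- make_filament_timelapse(remodeling_rate = 0.3, seed = 42)
frozen <- make_filament_timelapse(remodeling_rate = 0,   seed = 42)
framewise_dynamics(mock$stack)
#> <dynamics_result> sim_seed42: 25 frames, stack correlation 0.1847, stack absolute difference 0.2336
framewise_dynamics(frozen$stack)
#> <dynamics_result> sim_seed42: 25 frames, stack correlation 0.9954, stack absolute difference 0.02259
```

The remodeling cell decorrelates (0.18) while the frozen control stays
near 1 with an order-of-magnitude smaller per-pixel difference — the
control's only variation is the simulated camera noise.

```r
# FRAP: simulate 2% noise at the reference design, then fit
sim <- make_frap_trace(pre_bleach_level = 1, mobile_fraction = 0.6,
                       t_half = 5, noise_sigma = 0.02, seed = 42)
fit_recovery(normalize_trace(sim$trace))
#> <frap_fit> Mf = 0.574, t_half = 4.78 min (k = 0.145 /min), F0 = 0.310, R^2 = 0.9522
```

The true mobile fraction 0.6 and halftime 5 min are recovered to within
the noise-limited precision of a single 40-minute trace.

```r
# BFA bodies: noisy 12-body field, Otsu threshold
blob <- make_bfa_image(n_bodies = 12, noise_sigma = 2, seed = 42)
tab  <- quantify_particles(blob$image, threshold = "otsu", min_area = 4)
nrow(tab)
#> [1] 12

# mutant mapping on 2,000 simulated sites
vs   <- make_allele_counts(n_sites = 2000, seed = 42)
cand <- extract_homozygous(compute_snp_index(vs$counts))
nrow(cand)
#> [1] 496
```

All 496 extracted candidates are truly homozygous sites in the generator's
truth table (`vs$truth`).

Whole pipelines (simulate → analyze → CSV + manifest) run through
`run_analysis()`; see `?run_analysis`.

## Package layout

* `R/` — module sources: synthetic generators (`synth-*.R`), dynamics,
  architecture + morphology primitives, FRAP, compartments, SNP index,
  reporting, TIFF/CSV I/O and the pipeline dispatcher.
* `tests/testthat/` — unit, property and end-to-end tests (brute-force
  oracles for labeling, thinning, disk rasterization and the SNP filter
  live in the test helpers).
* `vignettes/quantifying-root-cell-dynamics.Rmd` — the methods notes: the
  models, parameter choices, degenerate-input conventions and known
  limitations.
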