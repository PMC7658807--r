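---
title: "Quantifying actin dynamics, membrane recovery and mutant mapping with actomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin dynamics, membrane recovery and mutant mapping with actomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actomap)
```

## Scope and scientific setting

Phenotyping a cytoskeleton-pathway mutant in plant roots rests on a handful
of quantitative readouts, each simple on its own but easy to get subtly
wrong: how fast the actin network remodels, how bundled it is, how much of
the cell it occupies, how quickly a bleached membrane protein recovers, how
strongly secretory compartments aggregate under brefeldin A (BFA), where
the causal mutation sits in the genome, and how transcript levels shift.
`actomap` implements these quantifications as one tested pipeline. Because
the underlying biological measurements require plants, confocal microscopes
and sequencers, every analysis stage is paired with a seeded synthetic-data
generator with known ground truth; the package's correctness claims are
claims about recovering that ground truth.

## Actin dynamics: all-pairs frame correlation and difference

A time-lapse stack of one cell (frames $F_1,\dots,F_n$ at a fixed interval,
typically 2.5 s over a minute) is summarized by two per-frame statistics,

$$C_i = \frac{1}{n-1}\sum_{j \ne i} \mathrm{corr}(F_i, F_j), \qquad
  D_i = \frac{1}{n-1}\sum_{j \ne i} \overline{|F_i - F_j|},$$

where $\mathrm{corr}$ is the Pearson correlation over the (optionally
masked) pixels and $\overline{|\cdot|}$ the mean absolute per-pixel
difference. The stack summaries are the unweighted means of $C_i$ and
$D_i$. A pharmacologically frozen network scores $C = 1$, $D = 0$; the
faster the turnover, the lower $C$ and the higher $D$. Averaging each frame
against *all* others (not only neighbors) is deliberate: it makes the
statistic symmetric under time reversal and insensitive to the ordering of
remodeling events. A lag-resolved curve (mean correlation as a function of
frame separation) is available via `lag_profile = TRUE` for readers who
prefer the correlation-decay view.

Two choices deserve justification:

* **The difference is absolute, not signed.** A signed mean of $F_i - F_j$
  cancels for stationary fluctuations and could not separate a frozen
  control from a remodeling cell; the mean absolute difference is the only
  reading under which the difference statistic discriminates. A squared
  variant is available (`difference = "squared"`).
* **No intensity normalization before correlation.** Pearson correlation is
  invariant under positive affine transforms of either frame, so gain and
  offset drift do not bias $C$. The difference statistic uses raw
  intensities by default; `normalize_frames = TRUE` divides each frame by
  its mean first (for sessions with lamp decay), and the mode used is
  recorded in the result.

Degenerate inputs are errors, not silent values: a frame with zero variance
under the mask has no defined correlation and is reported by index, and
`corr2d` refuses zero-variance selections rather than returning 0.

## Filament architecture: bundling skewness and occupancy

Architecture is measured on z-stacks (15–20 optical sections). Each section
is thresholded (Otsu per slice by default; any fixed threshold can be
supplied and is recorded in the result), objects smaller than
`min_object_px` (default 10 px) are removed to suppress speckle, the binary
section is thinned to a one-pixel-wide skeleton, and slice skeletons are
combined by union projection. The intensity substrate is the maximum
intensity projection of the raw slices. Skeletonizing before projecting
follows the section-wise processing convention; the reverse order is
available behind a flag as a sensitivity check.

Thinning is Zhang–Suen iterative thinning, implemented in vectorized form
in the package (no installed R package offers 2-D skeletonization). It is
idempotent, preserves connectivity, and — like all thinning algorithms —
shortens the ends of a thick bar by roughly the bar's width; the tests
encode that band rather than pretending end pixels survive.

* **Bundling** is the Fisher–Pearson moment skewness
  $g_1 = m_3 / m_2^{3/2}$ of the projected intensities at skeleton pixels.
  Bundles concentrate reporter fluorescence into a heavy right tail, so
  higher $g_1$ means more bundling. The biased moment estimator is used
  rather than the small-sample-adjusted $G_1$: skeletons contribute
  thousands of pixels, where the two differ negligibly, and $g_1$ is the
  convention of the field's image-analysis workflows. $g_1$ is invariant
  under positive affine intensity transforms; a zero-variance sample is
  defined as 0 (a perfectly uniform network is unbundled) with a warning.
* **Occupancy** is the fraction of cell-mask pixels covered by the
  skeleton. It lies in $[0,1]$ by construction and requires a non-empty
  mask.

## FRAP: single-exponential recovery

Traces enter as (time, intensity) series with `n_prebleach` leading scans
(three by default). Normalization divides by the mean pre-bleach intensity
and re-zeroes time at the first post-bleach frame; when a reference trace
from an unbleached region is supplied, acquisition bleaching is first
divided out pointwise. The post-bleach recovery is fit to

$$F(t) = F_0 + A\,(1 - e^{-kt}),$$

with mobile fraction $M_f = A/(1 - F_0)$ and halftime
$t_{1/2} = \ln 2 / k$. One recovery component is the minimal model behind
reporting a single mobile fraction and halftime; diffusion-profile models
are out of scope because traces enter as numbers, not bleach-spot images.

Numerical choices: bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with $k \in (0, 10]\ \mathrm{min}^{-1}$ and
$A \in [0, 1.5]$; $A$ initialized at the observed span and $k$ at
$\ln 2 / t$ where $t$ is the first time half the observed span is reached.
$F_0$ is fixed at the first post-bleach sample by default — stable at
sparse (1-min) sampling — with co-fitting available (`fix_f0 = FALSE`). A
flat post-bleach trace is the immobile limit, returned as $M_f = 0$ with
the constant fit's $R^2$, not an optimizer failure; a genuinely failed
optimization returns `converged = FALSE` with diagnostics rather than an
exception. When the fitted halftime exceeds half the observation window
the plateau is an extrapolation and the fit carries a wide-confidence note
(slowly recovering cells genuinely look like this within a 40-min window).

Accuracy at the reference acquisition design (1-min frames, 40-min window,
2% noise) is characterized in the test suite as the *median over a grid*
of $M_f \in \{0.3, 0.6, 0.9\} \times t_{1/2} \in \{2, 5, 15\}$ min with 50
replicates per cell: the slow and small-amplitude corners of that grid
constrain the rate only weakly — a bounded-information fact of the design,
not of the optimizer, as the fit matches an oracle fit initialized at the
true parameters replicate for replicate — so per-cell accuracy claims
would overstate what any estimator could deliver there.

## BFA compartments: particle quantification

The particle workflow mirrors the standard threshold → binary → measure
chain: pixels strictly above the threshold (Otsu or a fixed, recorded
value) form the foreground, connected components are labeled with
8-connectivity (corner-touching pixels join, the convention of the common
particle-analysis tool; 4-connectivity is a flag), components smaller than
`min_area` (default 4 px) are dropped, and per-particle area, centroid and
mean intensity are measured **on the original image**, never on the binary
mask. Per-cell aggregation (mean body area/intensity) belongs to the
reporting stage, keeping this module purely geometric.

## SNP-index mutant mapping

Mapping-by-sequencing reduces, at desk scale, to four operations:

1. **Read QC**: a read is excluded iff strictly more than 10% of its bases
   have Phred quality below 30. The inequality is strict on the fraction,
   so a 100-base read with exactly 10 sub-Q30 bases is kept. Phred+33 is
   assumed; input that looks like Phred+64 is rejected loudly rather than
   silently rescaled.
2. **Substituted reference**: wild-type line SNPs are written into the
   public reference so that, after re-mapping mutant reads, only
   mutant-specific variants reach high SNP-index. Strict mode errors on a
   reference-base mismatch; lenient mode warns and skips, which makes
   re-application idempotent. The Hamming distance between input and output
   equals the number of effective substitutions by construction.
3. **SNP-index**: per site, `alt / (ref + alt)`; a zero-depth site is
   undefined (`NA`), never silently 0.
4. **Homozygous extraction**: keep sites with depth strictly greater than
   5 *and* index strictly greater than 0.9, both strict per the filter's
   definition, so the edge rows (depth = 5, index = 0.90) are excluded
   exactly.

Alignment and alignment filtering stay out of scope; counts enter from a
TSV or from VCF allelic depths (biallelic records only, multiallelic rows
skipped with a warning).

## Expression and group statistics

Relative qPCR expression is $2^{-\Delta C_p}$ against a per-sample
reference gene; the transform is shift-invariant in $C_p$ and halves per
extra target cycle. Group comparisons are presented exactly as figure
legends name them: two-tailed Student's t for two groups, one- or two-way
ANOVA with Tukey HSD otherwise. Two-way designs must be balanced — an
unbalanced two-way layout errors instead of silently producing
order-dependent sums of squares — while one-way Tukey on unequal group
sizes uses the standard Tukey–Kramer adjustment. Outputs carry the test
identity, statistics, p-values and conventional significance stars.

## What the synthetic generators emulate — and what they do not

* `make_filament_timelapse` renders continuous-coordinate anti-aliased
  segments, optionally blurred with a Gaussian of $\sigma$ = width/2 to
  mimic optics, and remodels by whole-filament death/birth at rate $p$ per
  frame. $p = 0$ is the frozen (actin-stabilized) control. Bundles of $b$
  filaments share one path, so bundled pixels carry $\sim b$-fold
  intensity, and remodeling acts on whole bundles (replacing one member of
  a path-sharing bundle would dissolve it). Noise is additive Gaussian —
  the simplest model with closed-form expectations — not Poisson shot
  noise. The generator does not model filament elongation, severing,
  sliding, depth attenuation or a realistic PSF, so passing tests show
  metric correctness and ordering, not robustness to every optical
  artifact of real confocal data.
* `make_frap_trace` emits the closed-form recovery exactly (to 1e-12
  relative, asserted) plus optional geometric acquisition bleaching and
  Gaussian noise. It does not simulate diffusion during the bleach or a
  finite bleach spot.
* `make_bfa_image` places non-overlapping disks with at least a 2-px gap
  (so 8-connectivity labeling cannot merge neighbors) and uniform per-disk
  intensity, giving an exact truth table; real BFA bodies are neither
  round nor uniform.
* `make_allele_counts` samples site depth from a negative binomial
  (over-dispersed, as real coverage is) and alternative-read counts from a
  binomial with genotype-determined success probability
  ($1 - e$, $0.5$, $e$ for homozygous/heterozygous/absent at error rate
  $e$). A `depth_min` floor supports exact-recovery scenarios. No aligner
  artifacts, mapping bias or indel noise are modeled.

Every generator is a pure function of its arguments including the seed,
and restores the caller's RNG state.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 128×128×25 stacks with 20
replicates per remodeling rate for the monotonicity ensemble, 20
seed-paired replicates for bundling discrimination, 50 replicates per cell
of the 3×3 FRAP grid, 12-body particle fields, and 10,000-site variant
tables — sizes chosen so the full suite characterizes the estimators
meaningfully while remaining quick to run on a laptop. All random numbers
derive from explicit seeds; `run_analysis()` writes a manifest (inputs
hashed, parameters, seeds, package version) and identical configurations
reproduce result CSVs byte for byte.

## Known limitations

* Dynamics metrics assume a registered, single-plane time lapse; drift
  correction and optical flow are out of scope.
* Skeleton statistics use 2-D thinning of sections; true 3-D
  skeletonization and branch/junction analytics are not provided.
* The FRAP model is a single exponential; reaction–diffusion decomposition
  and double-exponential fits are out of scope.
* The mapping module trusts the allele counts it is given; multi-mapping
  and indel-spanning reads are upstream concerns.
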