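---
title: "Quantifying biofilm architecture and reporter dynamics from confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm architecture and reporter dynamics from confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmr)
```

## The measurement problem

Flow-chamber experiments follow surface-attached bacteria (for instance
*Vibrio cholerae*) under continuous medium flow, imaged as confocal
z-stacks every 20--30 minutes: one constitutive fluorescence channel marks
all biomass, and optional reporter channels read out gene expression or
phage infection. Two architectures matter biologically: flat 2D monolayers
(cells never exceed a few micrometres in height) and genuine 3D biofilm
colonies that grow as dome-shaped cell clusters. The quantity separating
them is the **biofilm biovolume fraction**

$$ f \;=\; \frac{V(H > h)}{V_\mathrm{total}}, \qquad h = 3\,\mu m, $$

the biovolume at height $H$ above the substrate exceeding the cutoff,
divided by the total biovolume. A monolayer scores $f = 0$; a tall colony
approaches 1. `biofilmr` computes this statistic, its time courses and
dose-response summaries, plus two spatially resolved readouts: cube-based
distance-to-interface kymographs of ratiometric reporters, and
infected-biomass fractions from a phage infection reporter.

Because real acquisitions come with no ground truth, the package also
ships a synthetic scene generator that renders the same imaging scenarios
with exact per-cell geometry, so that every stage of the chain is
validated against known answers.

## Segmentation chain

`segment_stack()` turns the constitutive channel into a binary biomass
mask in four steps:

1. **Mean filter** (`mean_filter`): a box filter, default $5 \times 5$
   voxels in-plane and 3 along z, against photon shot noise. Borders are
   handled by symmetric padding, so constants are preserved exactly.
2. **Per-slice white top-hat** (`tophat_enhance`): image minus its
   grayscale opening with a flat disk, applied to every xy-slice. The disk
   radius is specified physically (default 5.5 µm, larger than a cell) and
   converted to voxels from the in-plane pitch at run time; a field of
   view narrower than the disk gets the largest disk that fits, recorded
   in provenance. The morphology is computed in exact double arithmetic
   with an edge-clamped structuring element: the top-hat of a flat slice
   is exactly zero and the output never exceeds the input.
3. **Discounted Otsu threshold** (`otsu_threshold`): the histogram split
   maximizing between-class variance (256 bins over the observed range,
   ties resolved to the lowest split), multiplied by a discount factor of
   0.2 so that dim objects are still captured. The discount is held
   constant across all stacks of an experiment.
4. **Floating-cell suppression** (`suppress_floating_cells`): connected
   components (26-connectivity by default) that both lack substrate
   attachment (no voxel within one z-slice of the glass) and are smaller
   than one cell volume (1.3 µm³) are removed; planktonic cells drifting
   through the flow chamber otherwise contaminate the biomass estimate.

**Noise-floor guard.** An Otsu threshold on a stack that contains *no*
signal splits the noise distribution itself; discounted by 0.2, nearly
every voxel passes, and the resulting speckle percolates into one large
substrate-touching component that the size filter keeps. The chain
therefore never thresholds below `median + 5 * MAD` of the enhanced
image. With signal present the guard sits far below the discounted Otsu
cut and is inactive; on signal-free stacks it produces the scientifically
correct answer, an (almost) empty mask. A stack with *no intensity
variation at all* short-circuits to an empty mask with a warning.

**Conventions.** The substrate is the lower face of the first acquired
z-slice; voxel heights use centre coordinates, `(z + 0.5) * pitch_z`, and
the cutoff comparison is strict (`H > 3` µm), which breaks boundary ties
deterministically. Biovolume is foreground voxel count times physical
voxel volume.

## Known limitation: absolute biovolume of thin structures

The discounted threshold is deliberately generous ("capture all
fluorescent objects"), and it sits well below the half-maximum of the
smoothed intensity profile of a 0.8 µm cell. The mask therefore includes
the smoothing halo around every cell, which inflates the *absolute*
biovolume of thin, resolved structures severalfold -- the validation
sweep in `scripts/acceptance.R` measures this directly
(`biovolume_recovery_median_rel_err`). This is a property of the
mean-filter + discounted-Otsu design itself, not of its implementation,
and it holds at any pitch at which the cell is only a few smoothing
lengths wide. Ratio quantities are robust to it: across the same sweep
the biofilm biovolume fraction stays within 0.05 of ground truth,
monolayers score exactly 0, and infected fractions and reporter ratios
(both normalized) are recovered to a few percent. Comparisons of absolute
biovolumes are meaningful between conditions segmented identically, but
should not be read as cell-volume totals.

## Cube kymographs

For spatially resolved reporters the mask is decomposed into cubes of
roughly 1 µm side (`cube_decompose`; realized as `round(side / pitch)`
voxels per axis, e.g. 5 x 5 x 2 at 0.2 x 0.2 x 0.5 µm pitch). Border
cubes keep their true partial occupancy. Cubes with biomass occupancy
below 0.1 are excluded from reporter statistics -- near-empty boundary
cubes otherwise contribute means computed over a handful of voxels.

Per-cube channel means are computed over foreground voxels only and
**background-subtracted** (`estimate_background`: median intensity
outside the mask). This matters for ratios: without it a reporter ratio
$r$ measures as $(b + A r)/(b + A)$, compressing the profile by
$A/(A+b)$ and destroying slope estimates.

The **biofilm-liquid interface** is the set of included cubes with an
excluded 6-neighbour, looking laterally and upward but not through the
substrate-facing face (the glass is not a liquid interface), and never
through the domain boundary. Every included cube gets the Euclidean
centre-to-centre distance to its nearest interface cube. Distances are
binned at 1 µm and the chosen per-cube value (typically the
reporter/constitutive ratio, `channel_ratio`, with a denominator floor
for essentially empty cubes) is averaged *unweighted* within each
(distance bin, timepoint) pixel -- the simplest averaging rule; per-pixel
cube counts are reported alongside so weighted alternatives remain
auditable. `kymo_fold_change` divides each pixel by its distance bin's
value at the first timepoint, so a time-constant scene maps to 1.

## Infection reporter

The infected fraction is **biovolume-weighted**: foreground voxels whose
infection-reporter signal exceeds a threshold, divided by all foreground
voxels. No single-cell segmentation is attempted, and the output records
this unit. Classification operates on the *normalized* reporter
(`normalize_reporter`): both channels are smoothed with the segmentation
kernel, background-subtracted and divided, which cancels the local
biomass cover -- a mask voxel on a cell rim then reads the cell's true
reporter level instead of a cover-diluted one.

Two threshold policies are provided (`infection_threshold`). The default
follows the phage-free reference design: an Otsu cut over foreground
reporter values of the first uninfected timepoint, held fixed across the
series, with a `median + 5 * MAD` guard because a phage-free foreground
histogram has only one class and a bare Otsu split lands inside it. For a
reporter whose fold induction $F$ is characterized (e.g. from bulk
measurements), the midpoint policy `fold = F` places the cut at
$(1 + F)/2$ times the reference baseline: under linear mixing of infected
and uninfected biomass within a voxel, the ratio crosses the midpoint
exactly when half the voxel's biomass is infected, so boundary voxels
split without bias. Peak infection (`peak_infection`) is the per-replicate
maximum over time (earliest timepoint on ties), averaged per group and
compared with a two-sided t-test.

## Replicate statistics

`ttest_two_sided` is the classical two-sample comparison, equal-variance
(pooled) by default because that is the standard reading of "Student's
t-test", with Welch behind a flag; two identical degenerate groups return
$p = 1$ by convention. `anova_bonferroni` runs a one-way ANOVA and
compares every non-control group against the control with pooled
two-sample t-tests, multiplying each raw p by the number of comparisons
and capping at 1. `dose_response` aggregates replicate fractions per
condition as mean, SD (with $n - 1$ denominator) and $n$.

## The synthetic scene generator

`generate_scene` renders rod-shaped cells as spherocylinders (default
2.5 µm tip-to-tip, 0.8 µm diameter -- plausible vibrio geometry, exposed
as configuration) on a voxel grid:

* **monolayer** mode places cells flat on the substrate with random
  in-plane orientations and overlap rejection (an explicit packing
  failure beyond the retry budget);
* **colony** mode fills a hemispherical cap either with a dense lattice
  (default 3.0 x 1.2 x 1.3 µm spacing, packing fraction about 0.29 with
  at-least-one-voxel gaps so the per-slice top-hat retains cell-scale
  texture, and with stable lattice identities for time series), by random
  sequential placement, or as a `solid` hemisphere -- the dense-biofilm
  limit used for geometric oracles;
* **mixed** combines both; free-floating planktonic cells can be added
  anywhere in the liquid and are flagged in the per-cell table but
  excluded from the ground-truth mask.

Channels are rendered as expected photon counts
`background + amplitude * occupancy` (defaults 100 and 300 photons --
typical of EM-CCD spinning-disk imaging of constitutive fluorescent
proteins, putting the default scenes at an SNR around 30, with validation
sweeps drawing amplitudes of 100-400), optionally with Poisson shot
noise. Reporter channels impose a depth profile $r(d) = a + b\,d$ in the
analytic distance $d$ to the colony surface; infection channels mark a
chosen fraction of cells at a fold induction over baseline. Ground truth
is reported from both the continuous geometry (analytic spherocylinder
volumes) and the rasterized mask (voxel counts); the rasterization error
halves as the pitch halves. Time series (`generate_timeseries`) support
radius growth, per-timepoint lysis (cells removed permanently, identities
preserved) and per-timepoint reporter profiles.

The default test pitch is 0.2 x 0.2 x 0.5 µm -- desk-sized stacks; the
acquisition-scale 63.2 nm xy pitch is supported and shipped as the
`profile_flowchamber.yaml` configuration. What the generator deliberately
does **not** emulate: optical point-spread-function blur, camera EM-gain
statistics, drift, bleaching, or cell-shape variability. Passing the
validation suite therefore demonstrates correctness of the quantification
chain on idealized optics, not robustness to every artefact of real
microscopes.

## Numerical choices

* Otsu histograms: 256 bins over the observed min-max range; threshold at
  the lower tie.
* Mean filter: exact separable running sums; symmetric (edge-repeating)
  padding.
* Morphology: flat-disk grayscale opening decomposed into horizontal
  runs with binary-doubling sliding extrema -- exact double arithmetic,
  identical to the per-offset definition, at $O(r \log r)$ matrix
  operations per slice.
* Connected components: run-length encoding along y with union-find
  across adjacent columns; 6- or 26-connectivity.
* Interface distances: exact nearest-interface-cube search (cube grids
  are small); distances in physical µm with anisotropic cube sizes.
* Determinism: every stochastic step derives from the scene seed;
  `run_pipeline` writes a provenance JSON (config echo, realized
  thresholds, package version, seed) sufficient to re-run exactly, and
  two runs of the same config are byte-identical.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate on scenes of 12-16 µm
lateral extent (60-80 voxels across, 12-16 z-slices), colonies of 4-6 µm
radius, 20-scene recovery sweeps, 1,000-histogram threshold oracles,
20-stack filter oracles, and a 10,000-replicate null calibration of the
t-test -- sizes chosen so the whole validation runs in minutes on one
core while every stage is still exercised at realistic geometry.
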