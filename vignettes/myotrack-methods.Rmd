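---
title: "MyoTrack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MyoTrack: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MyoTrack)
```

MyoTrack quantifies three readouts of cardiomyocyte differentiation:
spontaneous contractility from label-free video, single-cell stiffness from
AFM force spectroscopy, and marker expression from fluorescence images and
blot densitometry. This vignette explains the models behind each module,
the tunable parameters and their defaults, what the synthetic generators do
and do not emulate, and the design decisions taken where the underlying
procedures left genuine freedom.

## Contractility from frame differences

### Model

A video of $n$ frames $I_k(x,y)$ is reduced to the absolute per-pixel
change between consecutive frames, $\Delta I(x,y) = |I_k - I_{k-1}|$, and
the mean of each difference frame over the field of view forms a length
$n-1$ motion trace. Because the statistic is intensity change rather than
tracked edges, it responds to motion below the optical resolution limit and
interrogates the whole monolayer at once. Quiescent periods sit at the
noise floor; contraction–relaxation cycles appear as peak doublets (one
burst as the cells shorten, one as they relax).

The trace is baseline-corrected by fitting a line to the quiescent samples
and subtracting it; motion periods are then maximal contiguous runs of
samples strictly above a threshold. Per trace we summarize peak amplitude,
cycle width (run duration) and events per minute, each with SEM. Motion
maps accumulate $\Delta I$ per pixel over a stated window (default 60 s),
localizing the moving regions; inter-cluster delays are the lags maximizing
the normalized cross-correlation of per-ROI traces.

### Parameters

* `threshold` (default **0.1**, trace intensity units). The scale is
  acquisition-specific — a trace computed from 14-bit raw data lives on a
  different scale than one from 8-bit conversions — so the threshold is an
  explicit parameter and scales linearly with the pixel intensities (the
  trace is homogeneous of degree one).
* `mergeGap` (default **0 s**). A motion period is defined purely by
  threshold crossings, so a doublet whose trace dips below threshold
  between the contraction and relaxation peaks counts as two events. That
  is the faithful reading of a threshold-run definition; the doublet
  interpretation is phenomenological. Users who want one event per beat
  set `mergeGap` to roughly the doublet gap (0.2–0.3 s): sub-threshold
  gaps at most that long are fused. Event *frequency* therefore counts
  threshold runs by default, doublets when merging is enabled — both
  conventions are exposed because published "peaks per minute" figures do
  not always state which they use.
* Baseline fit: ordinary least squares **on the samples at or below the
  trace median** (two-pass), not the whole trace, because motion peaks
  would otherwise bias both slope and offset of a naive fit. For a flat or
  purely tilted quiescent trace this removes the baseline exactly.
* Frames are differenced at native resolution with no pre-smoothing —
  blurring would discard exactly the sub-resolution sensitivity that makes
  the statistic useful.
* `lagMax` (default **0.5 s**). Lags are estimated at frame resolution
  (0.04 s at 25 fps), without sub-frame interpolation, since the
  physiological delays of interest are hundreds of milliseconds. The
  search window must stay below half the beat period: regular beating
  makes the cross-correlation periodic, and a window wider than that can
  alias the estimate onto a neighboring beat.

## Hertz elasticity fitting

### Model

An approach force curve is modeled as a linear pre-contact baseline plus
the Hertz response of a spherical indenter on an elastic half-space:

$$F = \frac{4 E \sqrt{R}}{3(1-\nu^2)} \, \delta^{3/2},
\qquad \delta = \max(z - z_c, 0),$$

with Young's modulus $E$, probe radius $R$, Poisson's ratio $\nu$ and
contact point $z_c$. Defaults are $R = 2.385\,\mu m$ (a 4.77 µm diameter
silica colloid) and $\nu = 0.5$ (incompressible, the standard assumption
for live cells), both overridable.

The least-squares problem over $(E, z_c, \text{offset})$ is solved by
profiling: for fixed $z_c$ the model is linear in the offset and the Hertz
prefactor, so each candidate contact point costs one linear solve, and the
residual sum of squares is minimized over $z_c$ by a 41-point coarse grid
followed by golden-section refinement (tolerance 1/100 of the sample
spacing). This is algebraically the same optimum as a joint nonlinear fit,
but each step is convex and the whole fit costs a few milliseconds.
Pre-contact samples have a zero Hertz regressor, so they inform only the
offset — the post-contact data carry the modulus. Positions are assumed
already converted to indentation (tip–sample separation); curves that
still contain cantilever deflection should be converted before fitting,
and the TSV header's `mode` key records which convention a file uses.

### Contact point deviation

The quality criterion "contact-point deviation" needs a reference that the
fitting procedure itself does not provide. MyoTrack defines it as the
absolute difference between the least-squares contact point and an
independent threshold-crossing estimate: the first position from which 5
consecutive detrended samples exceed 3 baseline noise standard deviations
(`estimateContactPoint`, with `k`, `m` and the baseline fraction
configurable). This definition is a package choice — flagged prominently
here because other implementations may anchor the deviation differently —
but it is monotone in fit quality, offset- and tilt-invariant, and exact
to one sample spacing on noiseless curves. The crossing threshold is
floored at $10^{-6}$ of the force range so that an effectively noiseless
baseline cannot trigger on floating-point rounding.

### Quality filtering and aggregation

Filters are applied in a fixed order with **strict** inequalities
("smaller than"): residual RMS < 25 pN, contact-point deviation < 100 nm,
then $E$ strictly inside $[10^2, 10^4]$ Pa; each rejected curve is tagged
with the first criterion it fails, so the tally always sums to the batch
size. Boundary values (exactly 25 pN, exactly 100 nm, exactly $10^2$ or
$10^4$ Pa) are rejected. Curves with no detectable contact or a
non-positive fitted prefactor are "unfit" and never enter the accepted
set. Filtering is per curve, before any pooling of replicates.

Accepted fits aggregate to per-group mean ± SEM with $n$; requested groups
without data are reported with $n = 0$ rather than dropped, and a
single-measurement group has an undefined (NA) SEM. `methodDifference`
compares the same cell type across methods (e.g. adherent AFM vs
suspended-cell deformability cytometry) as an absolute difference of group
means; the deformability-cytometry inversion itself is out of scope and
only published group means enter that comparison. Mixed-effect inference
over measurement days is likewise out of scope: the package reports plain
group means ± SEM and the simple comparison statistics below, which will
differ slightly from least-squares means fitted with day random effects.

## Image quantification

* **Li threshold** — the iterative minimum cross-entropy scheme: from the
  image mean, repeat $t \leftarrow (\mu_0 - \mu_1)/(\ln\mu_0 - \ln\mu_1)$
  with $\mu_0,\mu_1$ the class means at or below / above $t$. Intensities
  are shifted by the image minimum plus $10^{-6}$ of the range so the
  logarithms stay finite; the scheme is exactly equivariant to positive
  scaling and invariant to constant offsets up to that shift.
* **Huang threshold** — minimizes fuzzy entropy over a 256-bin histogram
  (the 8-bit convention): memberships $1/(1+|g-\mu_c|/C)$ with $C$ the
  intensity range, Shannon entropy accumulated over bins. Resolution is
  one histogram bin, hence "equivariant up to quantization".
* **Connectivity** is 8 (diagonal neighbors connect) throughout, the
  ImageJ particle-analysis convention; it is an assumption, recorded here,
  and a `connectivity = 4` escape hatch exists. Labeling is a two-pass
  union-find over vertical runs.
* **Despeckle** is a 3×3 median filter with edge replication (the ImageJ
  definition), optional and intended for the fluorescence pipeline before
  thresholding. **8-bit conversion** is min–max scaling to [0, 255] with
  rounding, exposed as an explicit step because rounding quantizes the
  scale any later threshold lives on.
* **JC-1 ratio** — the pixelwise aggregate/monomer quotient is only
  defined where the monomer (denominator) channel is above a floor,
  defaulting to the monomer's Li threshold; without a floor, near-zero
  denominators dominate the mean. An empty valid mask yields an NA mean,
  never zero.
* **Mitochondrial networks** — the 100 µm² boundary is assigned to
  "small" (sizes *up to* 100 µm² inclusive; "large" is strictly above).
* **Band spacing** — dominant orientation from the structure tensor
  (mean outer product of image gradients), projection of intensities onto
  the band normal binned at 1 px, peaks as local maxima above the profile
  mean, spacing as the mean peak-to-peak gap times the pixel size. Needs
  at least 3 peaks; bins with fewer than half the median pixel count
  (diagonal corners) are discarded.
* **Densitometry** — band intensities are divided by the lane's total
  protein, then scaled per protein so the reference group's mean is
  exactly 1; a protein undetectable in the reference group falls back to a
  stated alternative group, which is recorded per row.

## Comparison statistics

Two-group comparisons use Student's t (equal variance, two-sided) by
default with a Welch flag; three or more groups use one-way ANOVA followed
by Tukey's HSD with family-wise adjusted p values. Stars follow the
caption convention * p < 0.05, ** p < 0.01, *** p < 0.001. The package
verifies its own calibration by simulation: under a Gaussian null the
t-test type-I error at $\alpha = 0.05$ and the Tukey family-wise error
across three equal groups are both checked over 1000 replicate draws.

## The synthetic generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed, not tuned.

**Beating videos** (`simulateBeatingVideo`) emulate 25 fps, 120 s
phase-contrast recordings (the acquisition regime of typical monolayer
experiments, 14-bit cameras analyzed on an 8-bit scale) at 48 × 48 px with
additive Gaussian pixel noise (sd 0.5 intensity units on a 255 scale).
Each cluster fires one contraction/relaxation doublet per beat: a burst is
a Gaussian-in-time envelope (sd 0.04 s, truncated at ±2σ) multiplying
fresh per-frame Gaussian perturbations of the cluster pixels (amplitude 40
intensity units). The per-frame re-draw is what makes $|\Delta I|$ track
the envelope for the burst's whole duration — a static displacement would
register only at its onset and end — and the truncation gives each burst
an exact frame support that the truth table records, so detected event
counts and widths can be compared to truth at frame precision. Cluster
delays of hundreds of milliseconds are programmed through `phaseDelay`.
Not emulated: optics and PSF, cell morphology, drift, photobleaching, or
realistic sarcomere mechanics. Passing recovery tests therefore shows the
analysis is correct for localized intensity-fluctuation sources over
noise, not that it is robust to every imaging artifact of real monolayers.

**Force curves** (`simulateForceCurve`) are the exact Hertz forward model
plus linear baseline tilt and i.i.d. Gaussian force noise, sampled over a
1 µm pre-contact approach and 500 nm maximum indentation at 200 points.
Real AFM curves add viscoelastic hysteresis, adhesion and instrument
drift, none of which are modeled — hence the forward/inverse tests
demonstrate estimator correctness (noiseless recovery to well under 0.1 %,
median error well under 5 % at 5 pN noise), not robustness to
un-modeled physics; the QC filters exist precisely to exclude such curves
in practice.

**Images** are flat backgrounds with rectangular/disc objects of known
pixel masks and intensities, optional per-object texture and global
Gaussian noise; ratio pairs share one noiseless structure so the in-mask
quotient is exactly the programmed ratio before noise; striation images
are cosine gratings of known period and orientation. Gaussian noise
everywhere is an explicit assumption — the actual noise statistics of the
emulated acquisitions are not published, and EMCCD noise is
Poisson-Gaussian; the limit behavior of the estimators (e.g. JC-1 error
decaying with noise) does not depend on that choice.

All randomness flows from one explicit seed per call through a private RNG
stream, so identical spec + seed is bit-identical and no generator
disturbs the caller's RNG state.

## Numerical choices and degenerate inputs

* Intensities are floating point on $[0, \text{bitScale}]$ throughout;
  quantization happens only in the TIFF writers (16-bit samples).
* Undefined statistics are NA, never silently 0: the SEM of one value,
  the mean of zero events, the mean ratio of an empty mask.
* Degenerate inputs error early with informative messages: single-frame
  videos, constant images under thresholding, clusters or objects outside
  the frame, non-positive thresholds and windows, sub-Nyquist striation
  periods, empty ROIs and non-disjoint ROI sets, zero lane totals.
* Ties in the detection threshold are resolved by the strict `>` in the
  run definition; ties in QC by strict `<`.
* Test problem sizes — 120 s videos at 48 × 48 px, 200 curves per
  modulus level, 1000 null replicates — are chosen so that the full suite
  and the acceptance script each run in well under a minute on one core
  while keeping simulation error far from every tolerance they check.

## Known limitations

* No AVI reader: videos are exchanged as multi-page TIFF.
* No viscoelastic or bottom-effect corrections in the Hertz module; thin
  or highly dissipative samples violate the half-space assumption.
* Band spacing assumes a single dominant orientation per image; crossing
  fiber populations need pre-cropping.
* The blot module quantifies tabulated band intensities; it does not
  detect lanes or bands in raw blot images.
* Statistics are deliberately simple (t / ANOVA + Tukey); hierarchical
  designs with day- or replicate-level random effects need a dedicated
  mixed-model analysis outside this package.
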