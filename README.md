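# MyoTrack

Quantitative phenotyping of differentiating iPSC-derived cardiomyocytes from
three label-complementary readouts:

- **Contractility** from phase-contrast video of beating monolayers, using
  frame-difference motion analysis;
- **Cell elasticity** from AFM approach force curves, using Hertz
  spherical-indenter fits with quality filtering;
- **Marker expression** from fluorescence images and Western-blot
  densitometry, using automatic thresholding and area-weighted intensity
  quantification.

It is aimed at cell-mechanics and stem-cell labs that record beating
monolayers, probe cells with colloidal AFM probes, or quantify
immunofluorescence, and want a scripted, testable pipeline instead of
interactive tooling. A synthetic-data module generates every input type with
recorded ground truth, so the full pipeline is testable end to end without
any raw acquisitions.

## The core computations

**Motion.** For a video of *n* frames *I<sub>k</sub>(x, y)*, the
frame-difference operation

> ΔI(x, y) = |I<sub>k</sub>(x, y) − I<sub>k−1</sub>(x, y)|

yields *n* − 1 difference frames; the mean of each over the field of view is
the motion trace. After baseline correction (ordinary least squares on the
quiescent samples), maximal runs of samples above a threshold (default 0.1)
are motion periods, from which peak amplitude, cycle width and events/min
are summarized. Per-pixel sums of ΔI over a time window give motion maps,
and cross-correlating per-ROI traces gives inter-cluster delays at frame
resolution.

**Elasticity.** Approach curves are fitted with the Hertz model for a
spherical indenter,

> F = 4 E √R δ<sup>3/2</sup> / (3 (1 − ν²)),

with Young's modulus *E*, indentation δ = max(position − contact point, 0),
probe radius *R* (default 2.385 µm) and Poisson's ratio ν (default 0.5).
The fit is least squares over (E, contact point, baseline offset). Quality
filters then keep curves with residual RMS < 25 pN, contact-point deviation
< 100 nm and *E* strictly inside [10², 10⁴] Pa, and accepted fits are
aggregated per cell type × treatment as mean ± SEM.

**Imaging.** Masks come from minimum cross-entropy (Li) or Huang fuzzy
thresholding; 8-connected components become patches with area
*A<sub>i</sub>* and mean intensity *F̄<sub>i</sub>*, summarized as the
area-weighted mean

> F = Σ A<sub>i</sub> F̄<sub>i</sub> / Σ A<sub>i</sub>.

Further operations: mitochondrial-network classification at the 100 µm²
boundary, pixelwise JC-1 aggregate/monomer ratio maps, per-nucleus signal
means, sarcomere band spacing from projection profiles, and
Ponceau-normalized blot tables.

## Worked example

```r
library(MyoTrack)

## beating monolayer: 120 s at 25 fps, one cluster beating every 3 s
sim <- simulateBeatingVideo(
  beatSpec(duration = 120, clusters = beatCluster(24, 24, beatPeriod = 3)),
  seed = 1)
tr <- baselineCorrect(frameDifferenceTrace(sim$video))
ev <- detectMotionPeriods(tr, threshold = 0.1, mergeGap = 0.2)
summarizeContractility(ev, 120)
#>   meanAmplitude semAmplitude meanWidth semWidth frequency nEvents traceDuration
#> 1          3.41       0.0245     0.519    0.001        20      40           120

## Hertz fit of a 1.2 kPa synthetic curve with 5 pN noise
fc <- simulateForceCurve(curveSpec(eTrue = 1200, noiseSd = 5e-12))
ft <- fitHertz(fc, probeSpec())
ft
#> HertzFit: E = 1.203 kPa, contact point 1.001 um, rms 5.27 pN, cp dev 31.9 nm
qcFilter(list(ft))$tally
#>    accepted         rms contact_dev     e_range       unfit
#>           1           0           0           0           0

## sarcomere band spacing from a striation image (1.65 um period)
img <- simulateStriationImage(1.65, 0.1, c(64L, 256L))
bandSpacing(img, 0.1)$spacing
#> [1] 1.65
```

The contractility summary reads: 40 contraction cycles detected in 2 min
(20 events/min, the programmed rate), mean cycle width 0.519 s. The Hertz
fit recovers the generating modulus within the noise (1.203 vs 1.2 kPa) and
passes every quality criterion; the band-spacing estimate returns the
generating sarcomere length exactly.

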