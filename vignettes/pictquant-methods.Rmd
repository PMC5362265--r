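---
title: "Quantifying PICT assays: models, parameters and design choices"
author: "PICTquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PICT assays: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PICTquant)
```

## The assay and its readout

PICT (Protein interactions from Imaging Complexes after Translocation)
reports protein--protein interactions in living yeast: rapamycin-induced
FKBP--FRB dimerization pulls an FRB-tagged bait onto an RFP-labelled
anchoring platform (here the spindle pole body, one or two per cell), and a
GFP-tagged prey co-translocates only if it interacts with the bait. The
quantitative readout is the **recruitment score**: segment anchor spots in
the red channel and prey spots in the green channel, take the pixels where
the two segmentations overlap ("yellow" pixels), and compute

$$
\mathrm{score} \;=\;
\frac{\bar{G}_{\mathrm{yellow}} \cdot A_{\mathrm{yellow}}}{A_{\mathrm{red}}}
\;=\;
\frac{\sum_{\mathrm{yellow}} G}{A_{\mathrm{red}}},
$$

where $G$ is the *raw* green intensity, $A_{\mathrm{yellow}}$ the summed
overlap area and $A_{\mathrm{red}}$ the summed area of all segmented
anchors. The second identity is exact and is asserted on every result the
package produces. Because only prey spots overlapping an anchor contribute,
sparse false-positive prey detections barely perturb the score. One score is
computed per biological replicate by summing intensities and areas over all
fields of that replicate *before* dividing (not by averaging field scores),
and condition-level statistics (mean, SD, normalization to a reference
condition, two-sided Welch t-test) operate on the replicate scores
(typically $n = 3$).

Two readings of the measured area are possible: overlap-only pixels, or the
whole area of every prey spot touching an anchor. The package defaults to
the overlap-only reading, which matches the explicit pixel-level definition
of the workflow it reproduces; `areaMode = "whole_spot"` selects the other
reading. The two differ only when prey spots extend beyond the anchors.

## Spot segmentation

Both channels run through the same chain, with per-channel parameters
(`SegmentationParams`):

1. Gaussian blur, `gaussSigma` (anchor 1 px, prey 1.5 px -- the prey channel
   has lower contrast and gets slightly stronger smoothing);
2. white top-hat with a disk structuring element, `tophatRadius` (8 px):
   removes structures larger than a spot, flattening the strong, smoothly
   varying cellular background;
3. local mean threshold: a pixel is foreground iff it exceeds the mean of
   the preprocessed image over a disk of `localRadius` (8 px) plus an
   offset. The inequality is strict, so constant regions never segment. By
   default the offset is `offsetNmad` (5) times `stats::mad()` of the
   preprocessed image, a robust noise-scaled choice; a fixed offset can be
   given instead;
4. majority-vote median filtering over a disk (`medianRadius` 1 px) and
   area opening to `[minArea, maxArea]` = [4, 200] px^2; components are
   8-connected.

Every neighborhood operation handles image borders by symmetric reflection,
one convention throughout, which gives two useful invariants: adding a
constant to the input changes no mask pixel (the top-hat removes it), and
scaling the image by $k$ with the offset scaled by $k$ reproduces the
identical mask. Intensity statistics of segmented regions are always
measured on the raw channel, not the preprocessed one.

The concrete parameter values for this workflow were never published; the
defaults above are the package's own engineering choices, validated against
the synthetic generator (below): at peak signal-to-noise ratio 5 the anchor
defaults give recall and precision 1.0 against ground-truth spot centres
(2 px matching radius), and pure-noise fields segment to zero spots. The
`offsetNmad = 5` default was fixed by those two requirements jointly; at
2--3 MAD the correlated post-blur noise produces spurious small components.

## The synthetic-data generator

No raw microscopy data are available for this assay, so the package ships a
generative model (`sceneParams()`, `simulateField()`) that stands in for
them and carries ground truth. It emulates, per field: non-overlapping
elliptical cells (axis ratio 0.85, semi-major axis `cellRadius`, placed by
rejection sampling with a 1.2 `cellRadius` border margin); one or two
anchors per cell as isotropic Gaussian spots of `psfSigma` = 1.5 px
(a diffraction-limited spot at ~100 nm/px; the original workflow does not state
a PSF) offset half a cell radius from the centre; a green channel with
diffuse cell signal, one wide nucleolar blob per cell
(sigma = 0.35 `cellRadius`, offset perpendicular to the anchor axis --
the bright sub-nuclear accumulation typical of Pol I), and, in a
configurable fraction of cells, prey spots centred on the anchors; a
smooth background field (white noise blurred at `backgroundSmoothness`,
scaled to `backgroundMean` with 20% spatial CV) shared by both channels;
and Poisson shot noise followed by additive Gaussian read noise (the
standard CCD/sCMOS approximation; the original workflow states no camera model),
clipped at zero. Amplitudes are integrated photons per component, so
photon accounting is exact: with noise off the channel sums match the
analytic integrals to well under 0.5%.

Default amplitudes (anchor 5000, prey 2000, nucleolus 20000 photons;
background 100, diffuse cell signal 20 photons/px; read noise sd 2) were
chosen once to mimic the qualitative regime the assay describes -- nearly
flawless anchor segmentation, prey spots clearly above background but much
dimmer than the nucleolar pool -- and are not tuned per test. The replicate
design defaults (3 biological replicates, at least 6 fields each) mirror the
assay's stated design. Per-field seeds derive from a documented hash of
(base seed, replicate, field), so every collection is reproducible
bit-for-bit.

What the generator does *not* emulate: 3D stacks, photobleaching,
cell-cycle morphology, optical aberrations, or condition-dependent
background. Passing tests therefore demonstrate correctness of the
*analysis chain* under a controlled model, not robustness to every artefact
of real microscopy.

### The analytic score oracle

`expectedScore()` returns the noise-free expectation of the score measured
over the true anchor footprints: disks of radius `ceiling(2 psfSigma)`
around each anchor. It integrates the generative model over the footprint
-- background mean, diffuse cell signal, the nucleolar tail at the fixed
anchor--nucleolus distance, and the recruited prey spot's photon fraction
inside the disk, averaged over the uniform sub-pixel spot placement.
`trueMaskScore()` is its empirical counterpart on a simulated field, and
the two agree within Monte-Carlo error (the mean over 200 noise
realizations falls within 3 standard errors). Note the oracle's convention:
the measured region is the *full* anchor mask, so with no prey and a flat
background $b$ the expected score is $b$. A segmentation-based score only
approaches this value when every cell is recruited (prey spots then cover
the anchors); that is exactly the condition under which the end-to-end
recovery test compares the two (agreement within 15% at recruited
fraction 1; the residual bias is the part of the anchor footprint that the
prey segmentation does not cover).

For the null calibration of the replicate-level Welch t-test (1000
simulated 3-vs-3 comparisons from identical generator parameters), the
replicate scores are measured with `trueMaskScore()` on small fields rather
than through full segmentation: the quantity under test is the calibration
of the test on replicate scores, and the segmentation stage contributes
nothing to that question at 6000 simulated fields' cost. The observed
fraction of p < 0.05 falls in [0.03, 0.07].

## Nuclear vs non-nuclear localization

Because the spindle pole body spans the nuclear envelope, an anchored prey
can sit on either side of it; in cells with two platforms the nucleus lies
between them. The package reproduces the profile-based call: select cells
with two anchors (`pairAnchors()`: mutually nearest anchors with separation
in 1--4 um, the typical spindle-pole-body range), extract
bilinear-interpolated intensity profiles at ~1 px spacing along the line
joining the two brightest anchor pixels (`lineProfile()`; the station count
is `round(distance) + 1`, so reversing the endpoints exactly reverses the
profile), and classify (`classifyLocalization()`): the green peak must lie
strictly between the two red peaks, at least `margin` (0.15) of the
inter-peak distance away from each, with prominence above 3 MAD of the
green profile -- otherwise the call is non-nuclear or ambiguous. The
original analysis classified plotted profiles by eye; the margin and
prominence rule is this package's explicit, testable operationalization.
Profiles are extracted after subtracting each channel's field median (the
background-subtraction method was unstated; the median is robust to the
sparse bright structures). On 200 synthetic two-anchor cells with known
prey placement the classifier is >= 95% correct.

## Complex-level dynamics

Time courses of the two Pol I complexes are normalized to their highest
measurement (max exactly 1), and assembly/disassembly rates are forward
differences between consecutive measurements -- the literal reading of
"between two consecutive measurements" in the original description -- reported at interval
midpoints. The rates telescope exactly: $\sum_k r_k \Delta t_k = v_n - v_1$.

The descriptive fits mirror the shapes the original analysis reports, without model
selection: Pol I--Rrn3 decays as $v(t) = c + a e^{-t/\tau}$, the homodimer
rises as a 4-parameter logistic. Fitting is Levenberg--Marquardt
(`minpack.lm::nlsLM`) with data-driven initialization (log-linear
regression for $\tau$, logit-linear for the steepness); constant series are
flagged degenerate instead of fitted; non-convergence is reported with the
best iterate. Noiseless recovery is within 1%; with 5% multiplicative noise
the median $\tau$ error over 50 seeds stays within 20%.

The three response stages are labelled per interval by a rule: if both
complexes' |rates| fall below `slowThreshold` (0.2) of the overall maximum
|rate| the interval is *consolidation*; otherwise the complex with the
larger |rate| labels it (ties go to the first complex). The source draws
stage boundaries visually; this rule is the package's explicit
operationalization, recorded as such in output provenance. The default
synthetic scenario -- decay $0.4 + 0.6 e^{-t/10\,\mathrm{min}}$ (a ~30%
drop in the first 15 min and 60% total reduction) against a logistic rise
with $t_{50} = 25$ min and steepness 0.2/min, sampled at 0, 5, 10, 15, 20,
25, 35, 50, 65, 90, 120 min -- reproduces the expected order: fast Rrn3
adjustment (0--15 min), fast dimer adjustment (15--35 min), consolidation
thereafter.

## ChIP-qPCR occupancy

Standard curves are ordinary least-squares lines of mean Ct versus log10
relative quantity over four serial 10-fold dilutions; efficiency is
$10^{-1/\mathrm{slope}} - 1$ (perfect doubling: slope $-\log_2 10 \approx
-3.3219$, efficiency 1). Quantification inverts the curve. The occupancy
chain per condition and biological replicate is: technical triplicates
averaged on the Ct scale (geometric mean on the quantity scale, the common
qPCR convention; unstated in the original protocol), then IP/input, then division by
the non-transcribed chromosome VII control region, then division by the
same control-normalized quantity at the 5S reference gene, then fold change
versus a reference condition. Since every step is a ratio the composition
is order-independent, the result is invariant to adding a constant to all
Cts, and at efficiency exactly 1 the whole chain reduces to
$2^{\Delta\Delta C_t}$ arithmetic -- both properties are asserted against
closed-form oracles. Whether the 5S amplicon is itself control-normalized
before the final ratio is ambiguous in the original protocol description; the ratios make it
immaterial.

## Pipeline, sizes and reproducibility

`runPipeline()` chains all stages on a YAML-configured synthetic data set:
TIFF pairs (16-bit, quantized at a stated gain from the internal float
photon scale) plus manifest and ground truth, manifest validation (all
violations reported, not just the first), segmentation, scoring,
localization, dynamics and ChIP, with a provenance header (config hash,
seed, package version) on every CSV and no timestamps in data files, so
identical configurations reproduce byte-identical outputs. Stage failures
abort naming the stage and leave a `FAILED` marker beside the partial
outputs.

Simulation sizes used in the shipped tests were chosen to keep the full
suite comfortably interactive while leaving estimator noise well below the
tolerances asserted: 192x192 px fields with 6--10 cells for segmentation
and recovery runs (3 replicates x 10 fields per condition), 64x64 px
fields for the 1000-pair null calibration, 200 cells for the localization
benchmark, 50 seeds for noisy kinetic recovery. Larger scenes only shrink
the Monte-Carlo error around the same expectations.

## Known limitations

- The segmentation defaults are engineering choices; real data would need
  the same per-channel adjustment the original workflow applied.
- The analytic score oracle assumes the generator's fixed in-cell geometry
  (anchor offset, nucleolus distance); changing those constants requires
  re-deriving no formulas but does change the oracle's nucleolar term.
- Welch t-tests on n = 3 replicates have limited power; the package
  reports p-values but leaves multiple-testing control to the caller.
- No watershed splitting of touching spots, no sub-pixel localization, no
  distance-based colocalization metrics: the score is the assay's overlap
  statistic, nothing more.
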