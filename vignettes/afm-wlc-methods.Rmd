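---
title: "Models and methods: worm-like-chain analysis of AFM DNA images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: worm-like-chain analysis of AFM DNA images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(afmwlc)
```

This vignette is the package's account of the science behind each stage:
the models, the parameters that matter, the numerical choices, and what
the synthetic-data tests do and do not demonstrate about real images.

## The 2D worm-like chain and its discrete sampler

DNA deposited on mica under conditions that allow surface equilibration
adopts conformations drawn from the worm-like chain ensemble confined to
two dimensions. In 2D the tangent direction performs Brownian motion in
arc length: the net bending angle over a contour separation $L$ is
Gaussian with variance $L/L_p$, giving the tangent–tangent correlation

$$\langle \cos\theta(L) \rangle = e^{-L/2L_p}.$$

`sample_wlc_2d()` realizes this exactly in discrete form: turning angles
between consecutive segments of fixed length $s$ are i.i.d.
$\mathcal N(0,\, s/L_p)$. The generator's own segment directions are
therefore *exact* tangents, and the discrete laws
$\operatorname{var}\theta(ks)=ks/L_p$ and
$\langle\cos\theta(ks)\rangle=e^{-ks/2L_p}$ hold with no discretization
error — which is why the generator serves as the oracle for every
downstream estimator. The internal segment length is 2 nm, far below the
8 nm analysis step, so resampling error at the analysis scale is
negligible. The precondition $s \le L_p/4$ keeps the Gaussian-increment
approximation faithful if a user requests coarser chains.

### Closed (circular) chains

Circular molecules are sampled in two conditioning steps:

1. **Angle bridge.** Raw turning angles are shifted by a constant so they
   sum to $2\pi$ — exact Gaussian conditioning on the heading-closure
   constraint.
2. **Position closure by Newton projection.** The end-gap of an
   angle-bridged ring is $O(\sqrt{C\,L_p})$, roughly 200 nm for a
   $C=856$ nm, $L_p=56$ nm plasmid, so it cannot be "absorbed" naively:
   distributing it uniformly over vertices (with segment renormalization)
   measurably corrupts the local statistics — in development we measured
   the turning-angle s.d. inflated by 22 %, i.e. an apparent $L_p$ of
   38 nm instead of 56 nm. Instead the turning angles are projected onto
   the two position-closure constraints by Newton iteration *in the
   Mahalanobis metric of the bridged prior*. This is exact Gaussian
   conditioning under linearized constraints: only headings change (every
   segment keeps its exact length), and the correction is spread according
   to the prior covariance. After the fix the sampled turning-angle s.d.
   is 0.186 rad against the unconditioned 0.189 rad — conditioning
   slightly *reduces* variance, as it must.

Chains that self-intersect, or whose distant strands pass closer than a
clearance (default 12 nm), are rejected and resampled. The clearance
emulates the experimental practice of analyzing only individually
resolvable, non-overlapping molecules; 12 nm is chosen so that two strands
never merge at the half-height segmentation threshold given the rendered
ridge width (half-width at half maximum $\approx 3.3$ nm). Simple closed
polygons have turning angles summing to $\pm 2\pi$ automatically, so that
invariant is inherited rather than imposed.

## Rendering: from polygon to height map

`render_afm()` draws each strand as a Gaussian ridge of transverse width
$\sigma_r$ and pre-blur peak $h$, takes the pointwise maximum over the
path (computed from exact point-to-segment distances), convolves with an
isotropic Gaussian of width $\sigma_t$ standing in for finite tip
sharpness, optionally adds free-protein background dots, and adds i.i.d.
Gaussian pixel noise. A straight ridge then images as a Gaussian
cross-section of width $\sqrt{\sigma_r^2+\sigma_t^2}$ and peak
$h\,\sigma_r/\sqrt{\sigma_r^2+\sigma_t^2}$ — the closed form the render
tests check, and the relation `preblur_ridge_height()` inverts so a
condition can be specified by its *observed* height.

Defaults (all configurable): 2 nm/px on 512×512 images, $\sigma_r = 2$ nm,
$\sigma_t = 2$ nm, noise s.d. 0.05 nm, bare-DNA imaged height 0.6 nm,
protein-coated filament 1.0 nm, compacted particles 1.5 nm. The imaging
parameters are this package's own stated choices of a realistic operating
point — tapping-mode images of DNA on mica resolve the duplex as a
5–7 nm-wide, sub-nanometer ridge — not values taken from any instrument.

## Tracing

`segment_molecules()` thresholds at half the single-strand height (Otsu
fallback), labels 8-connected components (EBImage), discards
border-touching or too-short components, and classes each one from its
pruned Zhang–Suen skeleton: 0 endpoints → circular, 2 → linear, branched →
reject. Compact (collapsed) particles are recognized by being
simultaneously *tall* — plateau mean height above 1.2 nm, where the
plateau excludes pixels below 60 % of the region peak so the blurred skirt
does not dilute the statistic — and *short* (skeletal length below
100 nm). Height alone cannot separate a 1.5 nm collapsed rod from a
doubled interwound body; the length condition does.

`trace_backbone()` orders the skeleton (shortest path between endpoints
via the pixel graph; greedy walk around cycles), then refines each point
to the ridge crest by fitting a parabola to the height profile along the
local normal — the subpixel "brightest point". On noiseless straight rods
the refined points deviate from the true line by well under 0.2 px RMS.
A 3-point moving average smooths residual pixel jitter. Two end
corrections matter for length accuracy: skeletons of Gaussian-capped
ridges stop short of the true ends, so each open end is extended along
the local tangent to the half-maximum point and pulled back by the
transverse half-width at half maximum (the half-max contour of a Gaussian
cap sits exactly one HWHM beyond the true endpoint). Finally the path is
resampled at a uniform 8 nm arc step — half the apparent cross-sectional
diameter — with the true endpoint retained so no length is discarded.

Traced contours still come out about 2–3 % short of generator truth: an
8-nm chord of a $L_p = 56$ nm path is ~1.5 % shorter than its arc, and tip
blur plus smoothing genuinely shorten the imaged centerline. The same
convention affects any experiment traced this way, which is why the
contour-recovery acceptance band is 3 % on the ensemble mean.

## Persistence-length estimation

`tangent_correlation()` pools $\cos\theta$ over all position pairs across
molecules (each pair weighted equally), with wrap-around pairs for closed
traces and between-molecule jackknife standard errors.
`fit_persistence_length()` then performs weighted nonlinear least squares
(minpack.lm), with two corrections that development showed are not
optional at these scales:

* **Chord dead-zone.** Trace tangents are chords — averages of the
  underlying heading over one 8 nm step — so the net angle between chords
  at separation $L$ has variance $(L - L_0)/L_p$ with $L_0 \approx
  \text{step}/3$ for pure chord averaging and somewhat larger once tip
  blur smooths the path. The short-separation bins carry most of the fit
  weight, so ignoring $L_0$ inflates $L_p$ by ~17 % even on resampled
  ground truth. $L_0$ is fitted as a bounded nuisance parameter for curves
  measured from chords; analytic curves and native-resolution generator
  traces carry `tangent_chord_nm = 0` and invert exactly (the noiseless
  oracle: fitting $e^{-L/112}$ returns $L_p = 56$ to $10^{-6}$ relative).

* **Ring closure.** A closed molecule's tangent must wind by $2\pi$
  around the loop and its fluctuations are conditioned by closure, so for
  all-circular ensembles the fitted form is
  $\cos(2\pi L/C)\, e^{-(L-L_0)\gamma(L/C)/2L_p}$ with $C$ the measured
  ring contour. $\gamma(x)$ is the exact variance factor of the heading
  increment for the conditioned Gaussian model (sum bridge plus the two
  linearized position-closure functionals), computed once by covariance
  algebra on a fine discretization and memoized; it is position
  independent by ring symmetry. The pure angle-bridge factor $(1 - L/C)$
  under-counts the conditioning and biases $L_p$ high by ~16 %; fitting
  the bare open-chain form to rings biases low by ~7 %.

With both corrections, end-to-end recovery (simulate → render → trace →
fit, 30 closed 856 nm molecules per experiment) gives $L_p$ = 55.2 ±
2.9 nm over eight independent master seeds against a generated 56 nm.
The default fit window is (8 nm, 2× a log-linear prefit of $L_p$); the
long-separation bins beyond $\sim 2L_p$ are sparse and noisy.

Uncertainty is reported two ways: the curvature standard error of the fit,
and `bootstrap_lp()`, which resamples molecules with replacement — the
appropriate unit, since conformations are independent between molecules
but strongly dependent along one contour.

## Bending angles and heights

`bending_angle_distribution()` histograms the signed tangent-angle change
at a fixed contour separation (default 10 nm, about one protein footprint),
resampling the trace when the separation is not a grid multiple — angles
are never interpolated directly. Its oracle is the generator:
mean-square angle $= L/L_p$ at native resolution. Sharp kinks would appear
as outlier mass near $\pm\pi/2$ absent from the WLC ensemble; the test
suite checks both directions with a constructed kinked fixture.

`height_profile()` samples transverse profiles at random arc positions
(10 nm excluded at open ends to avoid end-cap bias), subtracts the local
background (median of the profile tails), and estimates the apex by a
log-quadratic fit through profile samples aligned to pixel centers along
the normal's dominant axis. The alignment matters: bilinear interpolation
between pixel rows flattens a ridge whose crest falls mid-pixel, biasing
a naive apex ~5 % low, while pixel-aligned samples of a Gaussian
cross-section invert exactly (measured 0.599 nm on a 0.6 nm rod).

## Topology and linking-number bookkeeping

`classify_topology()` distinguishes linear molecules, open circles,
plectonemes and compact particles using skeleton topology plus a
doubled-height test (median ridge height above 1.6× the single-strand
calibration — two stacked duplexes image roughly twice as high).
`measure_superhelical_axis()` thresholds the interwound body well above
the single-strand height, skeletonizes it, orders the skeleton and
measures the path *smoothed over 30 nm* — the medial axis of the
interwound band weaves at the strand-winding scale, inflating the raw
skeletal length by ~8–12 % — plus one transverse half-width per endpoint
for cap erosion (path ends re-anchored so smoothing cannot pull them in).
Against construction truth (axis ratio 0.42 of an 860 nm contour,
i.e. 361.2 nm) the measurement is accurate to ~±1.5 %.

`unwinding_model()` is pure bookkeeping, no mechanics: each bound protein
dimer unwinds the duplex by a chosen angle over its 9 bp footprint. For a
covalently closed chain the linking number is fixed, so the twist change
converts entirely to writhe ($W_r = -\Delta T_w$; unwinding gives positive
writhe — a previously relaxed circle interwinds), while a nicked or linear
chain relaxes the twist freely. White's relation $\Delta L_k = \Delta T_w
+ W_r$ holds identically in every state the package constructs. The
per-dimer unwinding angle and the rise change per covered base pair are
deliberately free parameters — they are not identifiable from images —
but the arithmetic shows their consequences: at full occupancy of a
1000 bp chain, a rise change of 0.02 nm per covered base pair yields a
5.9 % contour extension, the magnitude seen when a nucleoprotein filament
lengthens upon rearrangement.

## What the synthetic tests do and do not show

The generator emulates: 2D-equilibrated WLC statistics at calibrated
$L_p$; Gaussian ridge rendering with tip blur; additive instrument noise;
free protein in the background; interwound and collapsed morphologies with
known ground truth. It does **not** emulate: tip-shape artifacts beyond
isotropic blur (no deconvolution is attempted), scan-line drift or
flattening residues, kinetically trapped (non-equilibrated) conformations,
molecule–molecule overlap, sequence-dependent bending, or the internal
structure of collapsed particles. Passing the recovery tests therefore
shows the *estimators* are unbiased under the stated imaging model at
realistic noise; it does not certify accuracy on images whose artifacts
violate that model.

## Problem sizes and numerical choices

The test suite and acceptance runs use the study-scale ensembles: 30
circular molecules for persistence-length recovery, 40 linear molecules
for contour recovery, 1000 native-resolution chains for the WLC-law
oracles, and 40 labeled molecules (10 per class) for the topology suite.
Fits bound $L_p \in [0.1, 10^6]$ nm and $L_0 \in [0, 2\,\text{step}]$,
start from a log-linear prefit, and fail loudly on non-convergence or
bound-hitting rather than returning a value. Ties in skeleton ordering
break lexicographically by (row, column); circular traces start at the
smallest pixel and run counter-clockwise; all coordinates are nm with
pixel $(r, c)$ centered at $((c-0.5)\,\mathrm{px}, (r-0.5)\,\mathrm{px})$
(1-based). Degenerate inputs — empty images, all-background frames,
one-endpoint skeletons, separations exceeding a trace — raise descriptive
errors; an all-background image segments to an empty list rather than an
error. TIFF output is normalized to $[0,1]$ with the scale recorded in the
YAML sidecar because 32-bit float TIFF writing clamps outside that range;
the round-trip is exact.

## Known limitations

* The ring-closure factor $\gamma$ comes from the linearized conditional
  Gaussian model; at $L_p/C \approx 0.065$ the linearization is good but
  not exact, and simplicity/clearance rejection conditions the ensemble
  further (a ~2–4 % apparent stiffening). These effects are inside the
  stated 10 % recovery band but are not zero.
* Contour lengths measured on 8-nm traces are systematically ~2 %
  short of the underlying fine-scale arc length (chord and blur
  convention), as in any experiment traced the same way.
* Plectoneme DNA contour cannot be measured from the projected image;
  only the superhelical axis is measured, and the axis/contour ratio
  requires the contour from ground truth or a separate relaxed-circle
  measurement.
* The compact-class rule is calibrated for the rendered morphologies;
  real collapsed particles with unusual geometry may need the two
  thresholds (1.2 nm plateau, 100 nm skeletal length) adjusted.
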