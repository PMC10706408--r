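---
title: "cellkin: models, pipeline design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellkin: models, pipeline design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellkin)
```

`cellkin` quantifies the kinetics of DNA-repair proteins at
micro-irradiation-induced lesions from time-lapse fluorescence
microscopy: recruitment and removal of proteins that accumulate at
damage foci, local depletion ("holes") of proteins excluded from the
site, and exchange rates measured by fluorescence recovery after
photobleaching (FRAP). This vignette explains the models, the design
choices behind the processing pipeline, and the numerical details a
user should know before trusting the fitted numbers.

## The kinetic models

### Recruitment: a consecutive reaction chain

Recruitment to a lesion is modeled as a linear chain of first-order
reactions
$S_0 \xrightarrow{k_1} S_1 \to \dots \xrightarrow{k_m} S_m
\xrightarrow{k_r} \text{removed}$, with $m \le 3$ steps, all
unoccupied mass starting in $S_0$. The observed focus signal is
proportional to the occupancy of the final bound state $S_m$. Because
repair proteins frequently do not dissociate completely within the
imaging window, the signal is a mixture of a *removable* pool (removal
rate $k_r$) and a *non-removable* pool (removal rate 0):

$$y(t) = B + A\left[f_{rem}\,S_m(t;k_1..k_m,k_r) +
(1-f_{rem})\,S_m(t;k_1..k_m,0)\right].$$

`crc_model()` evaluates $S_m$ with the Bateman closed form for a linear
chain,
$S_m(t) = \left(\prod_i k_i\right)\sum_j e^{-r_j t}\big/\prod_{l\ne j}(r_l - r_j)$
with rate vector $r = (k_1..k_m, k_r)$. The closed form has removable
singularities at coincident rates; any two rates closer than a relative
$10^{-9}$ are symmetrically split by that same relative amount before
evaluation. This keeps the model continuous in its parameters (the test
suite checks $|y_{k_2=k_1(1+10^{-6})} - y_{k_2=k_1(1+10^{-5})}| <
10^{-4}$) without special-casing repeated-root formulas. The closed
form is validated against numerical integration of the chain rate
equations (deSolve, `lsoda` at `rtol` $10^{-11}$) to below $10^{-6}$
maximum absolute error over 100 random log-uniform parameter draws —
that integration is an *independent oracle* and is never used by the
fitting path.

Parameters and units: rates $k_i, k_r$ in 1/s (typical nuclear repair
proteins: $10^{-3}$–$1$ /s), $f_{rem} \in [0,1]$, amplitude $A$ and
baseline $B$ in the measured intensity units. Depletion curves use the
simpler `exp_decay_model()`, $y = C + A e^{-kt}$.

### FRAP: exponential exchange and diffusion-limited recovery

Post-bleach recovery is fitted with `frap1`/`frap2`:
$F(t) = F_\infty - B_1 e^{-k_1 t} - B_2 e^{-k_2 t}$, where the fit is
parameterized as $(F_0, B_1, B_2, k_1, k_2)$ with
$F_\infty := F_0 + B_1 + B_2$ so the amplitude constraint holds by
construction rather than by penalty. Derived quantities:

* **half-time of recovery** — the smallest $t$ with
  $F(t) = (F_0+F_\infty)/2$; analytic $\ln 2/k$ for the single
  exponential, bisection on the fitted curve otherwise (bracket
  $[0, 100/\min k]$, iterated to $10^{-12}$ relative width so the
  midpoint condition is met to $\sim 10^{-9}$ of the recovery
  amplitude);
* **mobile fraction** — $M = (F_\infty - F_0)/(F_{pre} - F_0)$ with
  $F_{pre}$ the pre-bleach reference (1 on normalized curves).

When the protein does not bind the damage site, recovery of a uniformly
bleached disk is diffusion-limited and fitted with
$F(t) = F_0 + (M - F_0)\,e^{-2\tau/t}\left[I_0(2\tau/t) +
I_1(2\tau/t)\right]$, the classical uniform-disk solution with modified
Bessel functions ($t=0$ is evaluated as its limit $F_0$; the scaled
`besselI(..., expon.scaled = TRUE)` avoids overflow at small $t$). The
bleach-spot radius $w$ (µm) is an acquisition parameter, not a fitted
one; the effective diffusion coefficient is $D_{eff} = w^2/(4\tau)$.
For a bound protein this is an *effective* coefficient — binding
residence inflates $\tau$ and deflates $D_{eff}$ relative to free
diffusion.

### Fitting

`fit_model()` minimizes the residual sum of squares with bounded
Levenberg–Marquardt (minpack.lm `nls.lm`, `maxiter` 500, `ftol = ptol =`
$10^{-12}$), from user-supplied initial values — the initials only
nudge the optimizer; no global search is attempted. Non-finite model
output during the search is replaced by a large penalty residual and
flags the result as non-converged. $R^2 = 1 - SS_{res}/SS_{tot}$ is
reported alongside the residual sum of squares; on noiseless self-fits
the suite requires $R^2 = 1$ to machine precision. Custom models are
expression strings over `t` and named parameters, parsed against a
whitelist (`+ - * / ^`, `exp log sqrt abs min max`) with unknown
identifiers rejected at parse time; `^` keeps R's right-associativity.
A plain-text model library (`inst/extdata/crc_models.txt`) ships the
chain equations written out explicitly.

## The measurement pipeline

### Segmentation

Global thresholds come from `otsu_multilevel()` (1–4 thresholds
maximizing between-class variance) or `kmeans_thresholds()` (weighted
1-D Lloyd on the histogram, initialized at evenly spaced quantiles).
Histograms use 256 unit-width bins for 8-bit data and 1024 min–max
scaled bins otherwise; thresholds are reported as bin upper edges, and
ties are broken toward the lexicographically smallest threshold vector.
For 1–2 thresholds the optimum is found by exhaustive search; for 3–4
by dynamic programming over cumulative histogram moments — both exact,
and checked against brute force in the tests. One consequence of the
tie-break worth knowing: on a cleanly bimodal histogram the
between-class variance is flat across the empty gap, so the reported
threshold hugs the upper edge of the *lower* mode.

Particles are 8-connected components above a class level, holes are
4-connected below-class components strictly inside an enclosing mask
(components touching the mask boundary are not holes). Connected-
component labeling is delegated to EBImage's `bwlabel` (4-connected),
with 8-connectivity obtained by merging labels that touch diagonally.

A single global multi-level Otsu cannot isolate a diffraction-limited
focus: a ~30-pixel spot inside a ~5000-pixel nucleus carries too little
histogram mass to earn its own threshold, so the two-threshold optimum
splits background/nucleus rather than nucleus/focus.
`adaptive_focus_labels()` therefore mirrors what practitioners do when
they "tailor the settings to the foci": per frame, one Otsu threshold
separates nucleus from background, and focus pixels are those exceeding
the nucleus population median by $z$ robust standard deviations
(default $z = 5$; scale = 1.4826·MAD, floored at 0.1% of the median so
noise-free synthetic frames behave). Median/MAD ignore the boundary
intensity ramp that Gaussian smoothing paints around the nucleus, and
both cuts rescale under multiplicative intensity decay, so the
segmentation is stable across acquisition photobleaching.

### Tracking

Tracking is deliberately simple: the workflow is "click one object and
follow it", not multi-object tracking. From the seed frame, linking
proceeds greedily in both directions to the nearest same-kind centroid,
gated at `max_displacement_px` (default 20 px); ties prefer the larger,
then lower-id component. When no acceptable candidate exists the track
*coasts*, holding the last placement and flagging the frame — the right
behavior for damage foci that transiently drop below threshold (and for
frames before the focus exists at all). Reversing a movie and the seed
reproduces the reversed track.

### Layered ROI photometry and photobleaching compensation

Measurement always happens on the raw channel (filters exist to help
segmentation, not to alter photometry), with multi-plane stacks reduced
by maximum projection by default. A circle's pixel set is "center
within radius"; layered circles add concentric shells of width
`layer_width_px` (default: half the inner radius — wide enough to
average the free pool, narrow enough to stay inside the nucleus).

The compensated focus total from a two-layer ROI is

$$\text{corrected}(t) = \frac{(\bar I_0(t) - \bar I_1(t))\,
A_0(t)}{\bar I_1(t)/\bar I_1(t_0)},$$

with $\bar I_0, \bar I_1$ the inner/shell means and $A_0$ the inner
area. The difference removes the free-pool pedestal under the focus;
the division by the shell's own normalized intensity removes the global
multiplicative decay from imaging and micro-irradiation bleaching. The
plain difference alone is *not* bleaching-invariant — it still scales
with the frame-wide decay factor — which is why the shell doubles as
the bleaching reference; with no bleaching the divisor is 1 and the
quantity reduces to the scaled mean difference. On synthetic movies the
corrected series is invariant to the bleaching rate to well below 2%
and proportional (r > 0.999) to the generating recruitment curve. The
approximation to watch: the shell must sample free pool only, so foci
whose tails leak far into the shell (inner radius below ~2σ of the
focus) bias the correction.

### Curve aggregation

Event-locked ensembles follow a fixed order: **crop** at the event
(re-zeroing time), then **normalize** each curve to [0, 1], then
**average**. Cropping first matters — normalizing before cropping lets
the pre-event plateau set the scale, so curves with different plateaus
stop being comparable after the event (a test demonstrates the two
orders disagree). Depletion curves are normalized by the same min/max
rule with no flipping; the decay model handles direction. Averaging
aligns curves to the grid of the shortest curve restricted to the
common time support, linearly interpolating the others, and reports the
pointwise mean and sample standard deviation (n−1).

## The synthetic generator

Every demo input is generated in-package, seeded, and paired with
ground truth. Three scene families are rendered:

* a field of non-overlapping elliptical nuclei (the demo preset places
  11 of them in a 512×512, two-channel frame with per-nucleus intensity
  jitter and Gaussian noise, scene seed 1, amounting to the kind of
  field of view the tool is pointed at first);
* recruitment movies: one centered nucleus, a Gaussian focus (σ 2.5 px)
  whose amplitude follows the chain model after the irradiation frame,
  a co-localized multiplicative depletion hole in channel 1 (σ 4 px,
  maximum depth 0.85, approached at 0.01/s — deep enough that a single
  global threshold shows the hole, as depletion phenotypes do), global
  per-frame bleaching $e^{-\beta t}$, optional drift, then noise. The
  reference conditions are a two-step chain $k = (0.1, 0.02)$ /s,
  $k_r = 0.005$ /s, $f_{rem} = 0.7$, 125 frames at 5 s, β = 0.02/frame,
  Gaussian noise at 2% of the focus amplitude;
* FRAP experiments, as a rendered single-plane movie or directly as a
  curve: plateau 1, bleach at 3600 s, then either a double-exponential
  recovery constructed so the mobile fraction is 0.955 and the
  half-time is 25.68 s (with $k_2 = k_1/10$, $B_2 = 0.25(F_\infty-F_0)$,
  $k_1$ solved numerically), or a uniform-disk diffusion recovery with
  $\tau_D = 16.89$ s and $w = 1$ µm, i.e. $D_{eff} = 0.0148$ µm²/s.
  These presets encode the reference exchange kinetics as generating
  truth, making parameter recovery the natural acceptance surface.

What the generator does *not* emulate: photophysics (blinking,
bleaching heterogeneity between fluorophores), 3-D point-spread
rendering, nuclear texture, cell movement or division, detector gain
artifacts. Passing tests therefore demonstrate correctness of the
measurement and fitting machinery under controlled conditions, not
robustness to every pathology of real movies; on real data the
segmentation settings (filter σ, z-cut, ROI radius) remain the user's
responsibility.

## Problem sizes and runtime

The test and acceptance workloads are sized for a desk run: 128×128
recruitment movies with 125 frames, a 512×512 demo field, 701-point
FRAP curves, 100-draw oracle comparisons, and a 10-cell end-to-end
recovery study (segment → track → measure → compensate → crop →
normalize → average → fit) that recovers the generating chain rates
within a few percent. The full suite runs in roughly a minute on one
CPU.

## Storage formats

Stacks are written as uncompressed multi-page TIFF in (T, C, Z)
odometer order (T slowest); all calibration, thresholds, ROIs, tracks,
event markers and the recorded command protocol live in a JSON sidecar
`<image>.celltool.json` merged field-wise on every write. The R `tiff`
writer cannot emit IEEE-float TIFFs, so float32 stacks are stored
bit-exactly by reinterpreting each value's IEEE-754 bit pattern as a
32-bit integer sample, recorded in the sidecar and decoded on read;
float TIFFs produced by other tools are read natively. Construction of
a float32 stack snaps values to float32-representable numbers, so a
write–read round trip is bit-exact by construction. Curves and
component/measurement tables export as tab-delimited text with event
markers in comment headers.

## Known limitations

* Greedy nearest-centroid linking has no global assignment step; two
  objects passing within the displacement gate of each other can swap
  identities.
* The shell-based bleaching factor assumes the free pool is spatially
  uniform around the focus and temporally constant up to bleaching;
  strong local gradients (e.g. nucleoli under the shell) bias it.
* Multi-level Otsu is a global method; no local-adaptive segmentation
  is provided.
* Uncertainty on fitted parameters is reported only through the
  residual sum of squares and $R^2$; there are no bootstrap intervals
  or model-selection criteria.
* Only TIFF input is supported; proprietary microscope formats must be
  converted upstream.
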