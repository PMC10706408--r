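# cellkin

Headless quantification of DNA-repair protein kinetics from time-lapse
fluorescence microscopy.

Live-cell imaging of micro-irradiated nuclei produces two recurring
measurement problems: (i) following the accumulation (or local
depletion) of a fluorescently tagged repair protein at a damage focus
over tens of minutes, against photobleaching from the acquisition
itself; and (ii) quantifying the exchange of a bound protein by
fluorescence recovery after photobleaching (FRAP). `cellkin` is a
scriptable R toolkit covering the full path from multi-page TIFF stacks
to fitted kinetic parameters: segmentation (multi-level Otsu, histogram
k-means, adaptive focus detection), click-free object and hole tracking,
layered concentric-shell ROI photometry with photobleaching
compensation, folder-wide curve aggregation, and nonlinear model
fitting. A seeded synthetic-movie generator with analytic ground truth
makes every stage testable without any external data.

## Models

**Recruitment (consecutive reaction chain).** Accumulation at a lesion is
modeled as a linear chain of first-order steps
S₀ →(k₁) S₁ → … →(kₘ) Sₘ →(kᵣ) removed, m ≤ 3, with the observed signal

  y(t) = B + A·[ f_rem·Sₘ(t; k₁..kₘ, kᵣ) + (1 − f_rem)·Sₘ(t; k₁..kₘ, 0) ],

where Sₘ is the occupancy of the final bound state (Bateman closed
form) and f_rem the removable fraction of the bound pool.

**Depletion.** Local exclusion from the damage site is fitted with a
negative exponential decay y = C + A·e^(−kt).

**FRAP.** Post-bleach recovery is fitted with single or double
exponentials, F(t) = F∞ − B₁e^(−k₁t) − B₂e^(−k₂t) (B₁+B₂ = F∞−F₀);
derived quantities are the half-time of recovery (bisection on the
fitted curve) and the mobile fraction M = (F∞−F₀)/(F_pre−F₀). For
diffusion-dominated recovery of a uniformly bleached disk,
F(t) = F₀ + (M−F₀)·e^(−2τ/t)[I₀(2τ/t) + I₁(2τ/t)], yielding an
effective diffusion coefficient D_eff = w²/(4τ) for bleach radius w.

**Photobleaching compensation.** A layered ("stack") circular ROI places
an inner disk on the focus (bound + free signal) and a concentric shell
just outside it (free signal only). The compensated focus total is the
difference of the layer means scaled by the inner area and divided by
the shell's own normalized intensity decay — the shell simultaneously
subtracts the free-pool pedestal and cancels global acquisition/
micro-irradiation bleaching.

## Worked example: FRAP exchange kinetics

```r
library(cellkin)

ref <- simulate_frap_experiment(scene_config("bard1_reference"))
cv  <- crop_after_event(ref$curve, "bleach")     # isolate the recovery
fit <- fit_model("frap2", cv,
                 initials = c(F0 = 0.3, B1 = 0.4, B2 = 0.3,
                              k1 = 0.06, k2 = 0.002))
print(fit)
#> Kinetic model fit: frap2
#> Coefficients:
#>         F0         B1         B2         k1         k2
#> 0.20000000 0.57300000 0.19100000 0.03921810 0.00392181
#> RSS 0, R-squared 1.000000, converged in 7 iterations

d <- frap_derive(fit, F_pre = 1)
#> half-time of recovery: 25.68 s
#> mobile fraction: 0.955
```

The reference curve drops from a normalized pre-bleach plateau of 1 to
F₀ = 0.2 at the bleach and recovers over 1400 s; the fitted half-time
(25.68 s, 25–50× slower than a freely diffusing protein) and mobile
fraction (0.955) characterize a protein almost fully exchanging, but
slowly — the signature of a chromatin-bound pool.

Segmenting the demo field of view:

```r
fld  <- simulate_field(scene_config("fig2_field"))
filt <- apply_filter(fld$stack, 0, filter_spec("gaussian", sigma = 2))
tset <- otsu_multilevel(get_frame(filt, 0, 0), 1, dtype = fld$stack$dtype)
#> <ThresholdSet otsu: 80.7666 (2 classes)>
comps <- detect_particles(apply_thresholds(filt, 0, tset), 1, min_area_px = 500)
nrow(comps)
#> [1] 11
```

The same steps are available from the shell via the installed
`exec/cellkin` script (`simulate`, `segment`, `track`, `measure`,
`extract`, `fit`, `replay`); every command appends its step to a JSON
session sidecar next to the TIFF, and `replay` re-executes a recorded
protocol on the same or new data.

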