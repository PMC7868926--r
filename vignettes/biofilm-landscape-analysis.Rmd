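---
title: "Methods: quantifying biofilm landscape morphogenesis along a hydraulic gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying biofilm landscape morphogenesis along a hydraulic gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and its representation

Optical coherence tomography of a flume-grown phototrophic biofilm yields a
digital elevation model (DEM): a raster whose pixel value is the biofilm
thickness above the substrate. The instrument conventions this package
assumes are a 40 µm lateral pixel, a 2.18 µm height quantum (thickness is
stored as a 16-bit gray level in quantum units), and a usable imaging depth
of about 1.2 mm. Heights are carried internally in mm as floating point;
rows run across the flume, columns downstream, and pixel centers sit at
`(i − 0.5)` pixel widths. Pixels at or above the depth ceiling are kept as
valid heights but flagged in a clipping mask, because structures taller
than the ceiling are silently truncated — a known source of volume
underestimation in the tall-cluster (slow-flow) region that no analysis
step can undo.

A `dem_series` bundles repeat scans of the same position. The scans are
declared co-registered rather than being aligned computationally: automated
OCT re-scans fixed stage positions, and any registration step would absorb
exactly the downstream displacement signal the temporal analysis is
designed to measure. An optional integer-shift cross-correlation
pre-alignment exists for instruments without a fixed stage but is off by
default.

# Landscape metrics

All Figure-style landscape metrics are computed per moving window (24 mm
edge, spanning the full cross-section, default stride 2 mm) so they can be
regressed against the bed shear stress interpolated at the window center
from a tabulated hydraulic profile. The profile is an input — typically a
CFD export or measurement — never computed here; only analytic open-channel
helpers (hydraulic-radius Reynolds number, plane-laminar shear estimate)
are provided as sanity checks, with the hydraulic-radius multiplier
configurable (1 or 4) because both Reynolds conventions circulate.

Choices that needed making:

* **Detection threshold** `h_min = 0.010` mm (≈5 height quanta): above
  quantization noise, below the smallest colonies that must still count as
  covered (<0.1 mm). All coverage/thickness statistics condition on it.
* **Porosity** is defined on the surface envelope: `1 − V/(A·h₉₉)`, the
  void fraction of the box bounded by the 99th-percentile covered height.
  A volumetric biomass porosity cannot be computed from a surface DEM;
  the envelope definition is isolated in one function (`porosity()`) so a
  different convention can be swapped in. The 99th percentile rather than
  the maximum makes the envelope robust to single clipped spikes. An
  uncovered region has porosity 1 by convention, a space-filling slab 0.
* **Textural correlation** uses a symmetric gray-level co-occurrence
  matrix with 64 levels quantized over `[0, max]` of each window and the
  four unit offsets {(0,1), (1,0), (1,1), (1,−1)}, averaged. These are
  standard Haralick settings; both are configurable. A constant window has
  zero variance and returns `NA` ("undefined"), and such windows are
  excluded from downstream regression rather than imputed.

The window stride (2 mm) is much smaller than the window edge, which
produces smooth curves but spatially overlapping, autocorrelated rows; the
consequence for inference is handled in the breakpoint section.

# Segmentation into clusters, base and troughs

A pixel is classified relative to the moving-average thickness `h̄` of its
24 mm neighborhood (the only length scale the landscape analysis already
uses): cluster if `h ≥ 2·h̄`, trough if `h ≤ h̄/2`, base otherwise; pixels
below `h_min` are *bare*. Two interpretation decisions are deliberate:

* "At least two times lower than the local average" is read symmetrically
  as `h ≤ h̄/2` — the only self-consistent reading of a multiplicative
  threshold.
* The local average includes zero-height pixels (it is the landscape's
  average thickness, not the covered area's); a covered-only variant is a
  flag. Near grid edges the averaging window is truncated and normalized
  by the in-grid pixel count, so a uniform slab is classified base
  everywhere including its edges. The window is forced to an odd pixel
  count so it is exactly centered.
* Bare substrate is kept out of the trough class so trough fractions are
  not inflated by uncolonized plexiglass, but the merged fraction is also
  reported, since published trough fractions may merge them.

Because both thresholds are relative, the segmentation is invariant to a
global rescaling of heights (with `h_min` rescaled likewise) — a property
the tests check. Cluster objects are 8-connected components (diagonal
contact joins; the labeling is checked against a flood-fill oracle) with
components below 0.01 mm² discarded as speckle, below the <0.1 mm colony
scale. Per-cluster morphology (volume, extents along and across the flow,
vertical aspect = max height / equivalent diameter) comes straight from the
component pixels; note that the cluster volume sums only pixels above the
relative threshold, so it modestly undercounts the Gaussian-skirt volume of
a bump — the recovery tests quantify this (<5 % under the planted-scene
conditions used there).

# Temporal dynamics

Subtracting consecutive DEMs splits volume change into local accumulation
(`V⁺`) and local loss (`V⁻`, "negative growth" — detachment or downstream
displacement). The identity `V⁺ − V⁻ = ΔV` is kept exact by default: a
configurable flicker threshold that zeroes sub-quantum |Δh| exists
(`min_delta`) but defaults to 0, because the conservation identity is the
invariant every downstream interpretation rests on, and quantization
flicker contributes symmetrically to both sums. The displaced fraction
divides `V⁻` by the biovolume of the later day; the denominator convention
(later/earlier/mean) is explicit because "fraction of total biovolume" is
ambiguous in prose.

A rigid translation of a cluster with no overlap between its old and new
footprints gives `V⁻ = V⁺ = V(cluster)` with `ΔV ≈ 0` — the canonical
displacement signature, planted and verified by the generator's event log.

# Breakpoint regression

Each metric `y` is regressed on bed shear stress τ with a single-breakpoint
broken line `y = β₀ + β₁τ + β₂(τ−ψ)₊`. The breakpoint ψ is estimated by
exhaustive grid search over interior τ-quantiles (5th–95th percentile, 100
candidates, each requiring two distinct τ on both sides), taking the
candidate minimizing the OLS residual sum of squares. Grid search was
chosen over iterative refitting because it is deterministic, cannot stall
in a local optimum, and is directly checkable against a brute-force
split-point fit; internally the hinge column is residualized against the
linear fit so each candidate costs one dot product, which is what makes the
Monte-Carlo calibration below cheap. One breakpoint only: the scientific
question is a single morphotype transition, and multi-break model selection
is out of scope.

Significance uses a parametric bootstrap under the linear null (linear fit
plus resampled residuals, segmented refit per replicate) of the F-type
improvement statistic `F = ((RSS_lin − RSS_seg)/2)/(RSS_seg/(n−4))`. The p
value is the plain exceedance proportion. Because overlapping windows
violate the independence this test assumes, inference runs on windows
thinned to a stride of one window edge, while ψ itself is estimated from
all windows. Exactly linear data leave ψ unidentified; the fit carries an
explicit flag instead of a fabricated estimate. A consensus range across
replicate flumes is reported only when the break is significant in every
replicate.

Calibration, recomputed by the test suite and acceptance script under
fixed study-like conditions (τ spanning 0.04–0.13 Pa, ψ = 0.08 Pa, n = 50
windows, noise at 5 % of the response range): mean recovered ψ within
0.005 Pa of truth over 500 replicates, and type-I error 0.047 at nominal
α = 0.05 over 1000 linear-null simulations (199 bootstrap replicates
each). These problem sizes keep the whole calibration under ten seconds
while holding Monte-Carlo error on the type-I rate near ±0.014.

# Oxygen microprofiles

Profiles are depth-indexed concentration series (µmol/L) re-zeroed to the
biofilm surface; when no surface position is recorded it is estimated as
the depth of steepest concentration change in the dark profile, where
respiration sharpens the gradient, and the estimation is logged. Local
gradients are OLS slopes over the 0.05–0.15 mm depth window — more robust
to sensor noise than a two-point difference, which remains available. The
light:dark gradient ratio |slope_light|/|slope_dark| is scale-invariant and
undefined (NA) at zero dark gradient.

The Brown–Forsythe statistic is implemented from its definition (absolute
deviations from group medians, F-distributed ratio) and cross-checked in
the tests against both a hand-computed oracle and `car::leveneTest`;
Welch's test wraps `stats::t.test`. Depth-binned comparisons pool readings
in 100 µm bins and emit both raw p values and Benjamini–Hochberg q values —
published analyses often report raw p across bins, so both are kept. Bins
with fewer than two readings on a side are skipped with a note, never
silently dropped. Pooling is at the reading level within bins; since
profile-level pooling is an equally defensible convention, the profile
table keeps its ids so users can aggregate either way.

# The synthetic generator

The generator produces ground-truthed stand-ins for the flume data; all
package validation runs against it, so its scope defines what the tests
can and cannot show.

**Landscape.** Two morphotypes are blended by a logistic weight in local
shear stress (transition at 0.08 Pa, width 0.004 Pa — sharp enough that
the below-transition region stays morphologically flat). The slow-flow
side is a set of anisotropic Gaussian caps (lognormal amplitudes capped at
1.5 mm, slight streamwise elongation) over sparse <0.1 mm colonies;
Gaussian caps were chosen for testability — the analytic volume
`2π σₓ σᵧ A` is the oracle for every volume-recovery test — not for visual
realism. Cluster centers are placed by dart throwing with a minimum
separation and an edge margin of four radii, so every planted bump lies
fully inside the grid and its analytic volume is a valid truth value. The
fast-flow side is a thresholded, smoothed Gaussian random field (circular
FFT convolution; the periodic boundary is immaterial at the correlation
lengths used) clamped at its 98th percentile — coalescing plateau-like
patches — scaled to a target mean thickness that rises linearly with shear
*above* the transition only (`carpet_tau_slope`). That asymmetry encodes
the emulated study condition that biomass accrual responds positively to
shear above the threshold but not below, and keeps the carpet thin
relative to cluster peaks, so maximum thickness stays higher on the
slow-flow side. The measurement model applies, in order, additive sensor
noise, truncation at zero, depth clipping at 1.2 mm, and height
quantization; noiseless/unquantized variants exist for exact-recovery
tests. The threshold-rule ground-truth labels are computed through
`stats::filter` moving averages — a separate code path from the analysis
module's integral-image implementation — so rule application can be
checked end to end.

**Time series.** Cluster amplitudes and the carpet grow exponentially
(doubling every 3 days), reaching the planted values on the final day; at
each 3-day interval every slow-flow cluster independently sloughs off or
is displaced downstream by a fixed pixel shift, with all events recorded.
Under the 1.2 mm clip, tall-cluster growth saturates while the carpet keeps
accruing — which is why the fast-flow accrual exceeds the slow-flow one by
a large factor in the generated study, an effect the real instrument's
depth limit would also produce.

**Oxygen.** Closed-form steady-state diffusion–reaction profiles with
zero-order reaction, fixed surface concentration C₀ = 300 µmol/L, and a
no-flux base over L = 0.5 mm: dark `C(z) = C₀ − (R/D)(Lz − z²/2)`
(so `C''·dz⁻² = +R/D`, verified to 1e−8 in the tests), light with net
production replacing consumption. Default dark reaction strengths
(R/D = 2080 and 976 µmol L⁻¹ mm⁻²) put the base concentrations at 40
(slow-flow) and 178 µmol/L (fast-flow); light production defaults to
P = R, so light:dark gradient ratios average 1 — balanced net fluxes. A
single quadratic closed form cannot simultaneously match those dark minima
and independently chosen light maxima; the defaults prioritize the dark
profiles and the flux balance, which are the quantities the analysis
chain consumes. Per-profile lognormal jitter of R/D is wider in the
slow-flow set (σ_log 0.30 vs 0.10), producing the
heterogeneity-of-micro-niches contrast the variance tests detect; strongly
respiring profiles can hit zero oxygen at depth and are truncated there
with a warning and a truth flag (anoxia, not an error). Wall/core variants
add an offset decaying with lateral distance from the cluster wall
(Δ = 60 µmol/L at the wall, decay length 0.3 mm) that ramps in over the
first 0.1 mm of depth — planted advective replenishment through trough-
facing walls; their reaction jitter is tighter (σ_log 0.05) because those
profiles transect the same cluster population.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mechanistic growth coupled to nutrient fields,
EPS mechanics, irregular (non-Gaussian) cluster shapes, migratory ripples,
sub-surface voids, spatially correlated sensor noise, and registration
error between repeat scans. Results on real DEMs inherit none of the
generator's guarantees beyond the purely algorithmic ones (oracle
equivalences, conservation identities, estimator calibration).

# Numerical and degenerate-input conventions

* Moving averages use an exact summed-area table with edge truncation;
  the reference path in the generator uses `stats::filter`. Both force odd
  window sizes.
* GLCM quantization maps `[0, max]` to 1…n levels with the top edge
  closed; an all-zero or constant region returns the undefined marker.
* Grid-search ties in the breakpoint RSS resolve to the first (smallest)
  candidate; the equivariance property ψ(a·τ+b) = a·ψ(τ)+b holds for
  a > 0 because quantile candidates transform affinely.
* Welch's test on two equal constant samples returns t = 0, p = 1; the
  Brown–Forsythe denominator at exact degeneracy returns W = 0, p = 1.
* DEM round trips are exact for quantized heights and within half a
  quantum otherwise; gray levels above the 16-bit range saturate with a
  warning.
* All generator randomness is Mersenne-Twister with inversion normal
  sampling under an explicit seed; identical seeds reproduce DEMs
  bit-identically.

# Problem sizes

The test suite validates on grids up to 625 × 1250 pixels (25 × 50 mm) and
runs in well under a minute; the analysis drivers and the acceptance
script use the full 0.025 × 0.4 m flume extent (625 × 10 000 pixels, six
days) and complete in about a minute on one CPU. The Monte-Carlo
calibration sizes (500 recovery replicates, 1000 nulls × 199 bootstrap
replicates) were chosen to bound the simulation standard error on the
type-I rate below 0.007 while staying fast, and are stated here as the
package's own convention.

# Known limitations

* The porosity and GLCM parameter conventions are provisional stand-ins
  for instrument-community conventions; both are isolated and
  configurable.
* Cluster volumes from relative-threshold segmentation systematically
  exclude bump skirts; comparisons across conditions are unaffected, but
  absolute volumes are conservative.
* The bootstrap-F breakpoint test is a pragmatic substitute for an
  analytic changepoint test; its calibration is verified by simulation
  only under the study-like conditions above.
* Depth clipping biases volume, thickness and accrual low wherever
  structures exceed ~1.2 mm — predominantly the slow-flow region at late
  time points; the clipping-fraction diagnostic should be reported
  alongside any affected metric.
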