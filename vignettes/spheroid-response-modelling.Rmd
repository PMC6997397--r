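---
title: "Modelling and quantifying tumour-spheroid response to radiation and hyperthermia"
author: "spheroTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying tumour-spheroid response to radiation and hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroTx)
```

# The problem

Three-dimensional tumour spheroids are a standard in-vitro model for solid
tumours: a multicellular aggregate develops an outer proliferating rim, a
quiescent interior and - once diffusion limits are reached - a necrotic core.
When spheroids are treated with ionising radiation (RT), hyperthermia (HT) or
both (RTHT), their growth response is followed for weeks by two-channel
time-lapse imaging: a phase-contrast-like structural channel for the contour
and a propidium-iodide (PI) fluorescence channel that marks dead cells.

`spheroTx` provides the full quantification chain for such experiments:

1. **dose models** - thermal dose (CEM43), a combined clonogenic-survival
   model, biologically equivalent dose (BEQD) and isoeffect solving;
2. **image quantification** - spheroid segmentation, the 36-diameter
   morphometric convention, mean PI intensity and radial PI profiles;
3. **growth curves** - daily-grid pooling across repeat experiments, peak-PI
   analysis, growth delay, regime classification and group comparison;
4. **synthetic data** - a deterministic compartmental simulator plus a frame
   renderer that emulates the treatment-specific cell-death dynamics, so the
   whole chain can be validated against known ground truth.

# Thermal dose

Any time-temperature exposure is converted to cumulative equivalent minutes
at 43 °C with the per-degree compounding rule

$$CEM_{43} = \sum_i t_i \, R^{(43 - T_i)},$$

with the classic breakpoint convention $R = 0.5$ above 43 °C and $R = 0.25$
at or below it. Both factors are arguments of `computeCEM43()`, because
cell-line-specific variants of the per-degree factor are in use; the
defaults are the standard convention. Temperatures are restricted to
20-50 °C, the range over which the thermal-dose concept is considered valid.
The measure is exactly additive over segment concatenation, which the test
suite exercises as a property.

# The combined survival model

Clonogenic survival after $D$ Gy radiation and $H$ CEM43 heat is modelled as

$$S(D, H) = \exp\!\big[-(a H + b H^2) \;-\; \alpha_0 (1 + c H) D \;-\;
\beta D^2\big].$$

This family was chosen as the *minimal* parametric form that captures the
three phenomena the assay must represent: linear-quadratic (LQ) radiation
kill ($\alpha_0, \beta$), thermal-only kill with upward curvature
($a, b$), and heat-induced radiosensitization as a linear inflation of the
radiation $\alpha$ ($c$). It is a declared stand-in: cell-line-specific
combined survival models exist whose internal form and fitted coefficients
are not reproduced here, and this family makes no claim to equal them. No
thermotolerance/saturation term is included - reported growth-delay plateaus
at intermediate thermal doses hint at one, but it is not quantified well
enough to parameterize.

Key consequences of the form:

* $S(0,0) = 1$ and $S$ is monotone non-increasing in each dose;
* the *biological effect* $E = -\ln S$ is additive across the thermal and
  radiation terms, which makes isoeffect matching a 1-D root-find;
* $\ln S$ is **linear** in $(a, b, \alpha_0, g, \beta)$ with
  $g = \alpha_0 c$, so fitting is exact weighted linear least squares - no
  iterative optimizer, no starting values, fully deterministic.
  `fitSurvivalParams()` weights records by colony counts (the inverse
  Poisson variance of $\ln S$), applies a +0.5 continuity correction to
  zero-colony records, and recovers $c = g/\alpha_0$ with a delta-method
  standard error.

**BEQD.** The biologically equivalent dose of a treatment is the pure-RT
dose with the same effect, i.e. the positive root of
$\alpha_0 x + \beta x^2 = E$; `beqd()` uses the closed-form quadratic root
(falling back to $E/\alpha_0$ when $\beta = 0$) so that pure radiation
treatments map to their own dose exactly. `isoeffectCombinations()` inverts
the model in $H$ on a radiation-dose grid by monotone root finding
(bracket 0 to $10^5$ CEM43, refined by bisection to $10^{-9}$ in effect
units); grid doses whose radiation-only effect already exceeds the target
are omitted with a notice. Effects are always evaluated on the log scale
internally, so extreme dose combinations cannot underflow.

Default parameters (`survivalParams()`) emulate a sensitive colorectal-line
phenotype in which 10 Gy and roughly 240 CEM43 each correspond to a
surviving fraction near $10^{-4}$ - the isoeffect level at which single and
combined treatments are typically compared.

# Image quantification

**Segmentation** (`segmentSpheroid()`) is classical: Gaussian smoothing
(sigma 2 px), Otsu thresholding, morphological closing (5 px disc), hole
filling and retention of the largest connected component. A trained
neural-network contouring model would be an alternative; the downstream
metrics only require a consistent contour, and here ground truth comes from
the synthetic renderer, so a deterministic classical pipeline is preferable.
Shed-cell debris (the corona of dead cells around a regrowing spheroid) is
excluded by the largest-component rule; `mergeCorona = TRUE` merges nearby
components instead, to study the corona's contribution. When more than one
component is present (disintegration), the largest is measured and a
`fragmented` flag is emitted.

**Diameters** (`measureDiameters()`) follow the 36-diameter convention: one
diameter every 5 degrees over 180 degrees through the centre of mass of the
segmented area, measured outermost-crossing to outermost-crossing so that
interior holes cannot shorten a diameter. Rays are sampled at 0.25 px steps;
the reported distance is to the centre of the outermost foreground pixel
crossed, projected on the ray, which keeps the estimate within ~1.5 px of a
brute-force pixel-enumeration oracle at every angle. Coordinates are
(row, col) from the top-left; angles are counter-clockwise from the +column
axis.

**Mean PI** (`meanFluorescence()`) defaults to the whole-image mean - the
acquisition-faithful convention - with a mask-restricted mode provided
because whole-image values depend on the field of view. Either way PI
intensities are only comparable between treatments imaged under identical
settings; they are not calibrated viability.

**Radial profiles** (`radialProfile()`) take line profiles every 5 degrees
(72 angles over 360°) through the centre of mass of the Gaussian-filtered PI
channel, sample them at unit-pixel steps with bilinear interpolation, align
them at the centre and average pointwise up to the shortest profile. The
filter sigma defaults to 2 px (the filter scale is a convention, not a
measurement; any small sigma gives equivalent between-treatment contrasts).

# Growth curves and regimes

Scans arrive at irregular times, several spheroids per repeat experiment.
`assembleGrowthCurve()` linearly interpolates each repeat onto the fixed
daily grid 0-21 days and pools across repeats with mean ± SEM. Two rules
matter: **no extrapolation** beyond a repeat's first or last scan (those
grid days are missing for that repeat, not clamped), and SEM is only defined
with at least two repeats; at least three repeats are required for the
publication-grade flag.

`peakPI()` reports the maximum of the pooled PI curve in a window defaulting
to days 0-7 (the first week post treatment). Observed HT peaks typically
fall on days 3-6, but the window - not the observation - defines the
statistic, and the window is an argument. `regressEffect()` relates peak PI
to biological effect by OLS with $R^2 = 1 - SS_{res}/SS_{tot}$ (defined as 0
for a constant response).

`classifyRegime()` encodes the qualitative post-treatment regimes as
explicit rules on the daily curve: *transient swelling then shrinkage*
(a value above day 0 followed by a ≥15 % drop - the HT signature of
structural loosening followed by shedding), *shrinkage then regrowth*
(minimum below day 0 followed by ≥3 consecutive rising days), *monotone
shrinkage*, *growth control* (final ≤ day 0, no regrowth) and *control-like
growth*. The 15 % drop, the 3-day rise and a 3 % relative noise tolerance
are exposed arguments; the defaults were chosen once to separate the four
canonical scenarios cleanly at the simulator's default conditions and are
not tuned per dataset. `compareGroups()` is a two-sided unpaired Welch
t-test - the unequal-variance form is the safer default when only
"unpaired t-test" is specified. `growthDelay()` returns the difference in
(interpolated) threshold-crossing times, with `Inf` encoding growth control.

# The synthetic-data generator

## Population model

`simulateSpheroid()` advances compartments P (proliferating rim), Q
(quiescent), C (necrotic core), Dm (radiation-doomed but metabolically
active), Aht/Art (dead-but-attached, by death origin) and a cumulative shed
pool, in 4-hour steps over 21 days - the imaging cadence. It is a
deliberately minimal compartment model: no agent-based geometry, no
reaction-diffusion oxygen field. Compartment boundaries are geometric depths
(rim thickness, necrosis-onset depth) because the data the generator must
emulate constrain geometry, not oxygen kinetics. The spheroid radius follows
from total attached cells and packing density,
$N = \tfrac{4}{3}\pi r^3 \rho$.

Treatment enters once, at $t = 0$ (the recorded day-0 state is the
pre-treatment configuration, matching how a day-0 scan is acquired):

* **heat** kills the fraction $1 - S_{HT}(H)$ of P, Q and C *alike* - heat
  kill is independent of position and proliferation status - and loosens
  packing: density is multiplied by $1 - \ell\,(1 - S_{HT})$, recovering
  linearly over 4 days. Scaling the loosening by the killed fraction (rather
  than applying a fixed factor whenever heat was delivered) keeps a
  null-effect exposure exactly equivalent to no treatment and makes the
  swelling dose-dependent, as observed.
* **radiation** dooms the fraction $1 - S_{RT}$ of surviving P (with
  heat-sensitized $\alpha$). Doomed cells stop proliferating and die with
  exponential timing (mean `mitoticDeathLagDays`, default 2.5 d) - the
  mitosis-linked delayed-death mechanism.
* **shedding** moves dead-attached cells into the corona pool at
  modality-specific rates after modality-specific onset delays (defaults:
  HT 1.2/d after 2 d; RT 0.15/d after 0.5 d). The onset delay is a kinetic
  refinement of a pure exponential rate: without it, the observed multi-day
  diameter increase after heating cannot coexist with near-complete shedding
  within about four days on a daily measurement grid.
* **reoxygenation** boosts the proliferation rate (default +30 %) in
  proportion to the deficit of the necrotic core relative to a size-matched
  untreated spheroid. This implements the core-reduction explanation of
  post-HT growth acceleration; selective killing of slow-growing
  subpopulations is an alternative explanation the model does not implement,
  and the boost can be disabled (`reoxygenationBoost = 0`) to represent
  agnosticism.

The simulation is fully deterministic; all stochasticity lives in the
renderer and the dataset generators, each drawing from sub-streams of one
global seed. Cell counts are conserved exactly - the pooled total changes
only by births - and the suite checks this bookkeeping at every step.

Default conditions: 300 µm initial diameter at a packing density giving
~4800 cells (the small-spheroid condition; 550 µm for the large condition),
rim depth 75 µm, necrosis-onset depth 275 µm (so a 550 µm spheroid is
hypoxic but not yet necrotic at treatment), proliferation 0.30/d. Under
these values an untreated control grows from 300 to about 1000 µm in 21
days, in the range typical for colorectal-line spheroids.

## Renderer

`renderFrame()` draws the structural channel as a soft-edged textured disc
of the state's radius plus a faint annulus whose brightness scales with the
shed-cell fraction (the corona), and the PI channel from the dead-attached
fractions with linear radial ramps: centre-weighted for heat-origin death
and the necrotic core, edge-weighted for radiation-origin death - the
qualitative spatial PI patterns of the two modalities, without any claim of
quantitative radiometric fidelity. Additive Gaussian noise is seeded per
frame. The corona's phase intensity is kept below the Otsu threshold so the
segmentation contract (corona excluded from the main mask) holds by
construction; ground-truth masks and diameters are emitted alongside every
frame.

What the generator does *not* emulate: optical depth attenuation and
focal-plane effects, PI diffusion kinetics, microenvironment-dependent PI
brightness, irregular spheroid shapes, and well-wall artefacts. Passing
round-trip tests therefore demonstrates that the measurement chain is
internally consistent and unbiased on idealized images - not that it is
robust to every artefact of real microscopy.

## Dataset generators

`generateClonogenicDataset()` draws colony counts by binomial thinning of
the plated cells with probability (plating efficiency × survival) - exactly
mean-preserving and indistinguishable from the Poisson colony model at low
survival. `generateViabilityDataset()` reports the metabolically active pool
(P + Q + Dm) relative to control with mean-one lognormal noise of stated CV;
doomed cells count as active because viability assays shortly after
irradiation read out metabolism, not clonogenic potential.

# Numerical choices

* Isoeffect root-finding: monotone 1-D bracket [0, 1e5] CEM43, uniroot plus
  bisection refinement to 1e-9 in effect units; ties at the boundary return
  H = 0 exactly.
* Fitting: weighted `lm` on the effect scale; rank-deficient designs (e.g.
  all records at one dose point) raise an explicit degenerate-design error
  rather than returning arbitrary coefficients. Point estimates are clamped
  at 0 in the returned parameter object (the raw unclamped estimates and
  standard errors are also returned).
* Diameters: 0.25 px ray step, distances to outermost crossed pixel centres;
  a ring-shaped mask whose centroid falls outside the foreground triggers a
  warning but is still measured.
* Interpolation: `approx(..., rule = 1)` - missing outside a repeat's scan
  range by design.
* TIFF I/O stores float intensities divided by a power-of-two headroom
  scale (default 4), since TIFF float storage is only defined on [0, 1];
  the reader re-applies the scale losslessly.
* Regime rules evaluate differences against a relative tolerance (3 % of
  the day-0 diameter) so that sub-pixel measurement noise cannot flip a
  label.

# Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data generated at
test time: oracle comparisons on 300-400 px masks; 50 rendered frames at
2 µm/px for segmentation quality; full 22-day round trips for the four
canonical scenarios at the reference resolution of 1 µm/px; and regime
classification for 4 scenarios × 20 seeds at a 4 µm/px preview resolution.
These sizes were chosen as the smallest that still exercise every code path
at the reference conditions.

# Known limitations

* The survival family has no thermotolerance saturation and models a single
  fraction at a fixed heating temperature; sequencing and the RT-HT gap are
  metadata only.
* The compartment model is one-way (P → Q → C): quiescent cells do not
  re-enter the cycle; post-treatment acceleration is carried entirely by the
  reoxygenation boost.
* Whole-image PI means are field-of-view dependent; both PI modes are
  relative measures, never absolute viability.
* Segmentation assumes one dominant body brighter (or darker, by
  configuration) than background; during disintegration only the largest
  fragment is tracked.
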