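---
title: "A layered heat-balance model of fasting polar bear energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered heat-balance model of fasting polar bear energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polarfast` predicts the energetics of adult polar bears fasting onshore
during the ice-free season from physical first principles. This vignette
is the package's account of the science: the model and its assumptions,
the parameters that matter, the numerical choices, the design decisions
that were genuinely open, and what the tests do and do not demonstrate.

## The steady-state premise

The central assumption is thermal steady state: in every hour, the bear's
metabolic heat production `Q_gen` equals its net losses,

```
Q_gen - Q_resp - Q_evap  =  Q_fur  =  Q_rad + Q_conv - Q_sol,
```

where `Q_resp` is respiratory loss, `Q_evap` cutaneous evaporation,
`Q_fur` the heat conducted through the coat, `Q_rad` and `Q_conv` the
radiative and convective exchange at the fur surface, and `Q_sol` the
absorbed solar load. Rather than prescribing a metabolic rate and
tracking a transient body temperature, the model solves for the rate
that keeps the core at its set point. Heat storage is represented only
through the bounded core-temperature swing of the thermoregulation
cascade (36–39 °C), so sub-hourly transients are deliberately outside
the model.

## Microclimate

Daily forcing (extremes of temperature, wind, relative humidity, cloud,
plus a snow flag) becomes hourly drivers:

* **Sinusoids.** Each variable follows two half-cosine branches anchored
  at sunrise (minimum temperature and wind, maximum humidity and cloud)
  and one hour after solar noon (the opposite extremes). The curve passes
  exactly through both anchors and is continuous across midnight. Time is
  local solar time throughout; at Churchill's latitude a sunrise always
  exists in the modeled season, and a 05:00/13:00 fallback guards the
  polar cases.
* **Solar.** Clear-sky global irradiance uses Spencer declination and
  eccentricity, the Kasten–Young airmass, a Hottel-type beam
  transmittance `0.7^(m^0.678)` and the Liu–Jordan diffuse fraction. The
  unit tests compare it against the Haurwitz closed form — a genuinely
  different empirical model — at the equator equinox (5% agreement) and
  check that the annual noon maximum falls at the summer solstice. Cloud
  attenuates the flux linearly, reaching a configurable maximum fraction
  `a_max = 0.65` at full overcast; the linear form is a model choice, not
  a measured law, and is exposed in `cloud_adjust_solar()`.
* **Longwave sky.** The effective sky radiant temperature blends the
  Swinbank clear-sky emission `L = 5.31e-13 T_air^6` with cloud emission
  at air temperature, weighted by fractional cloud. An Idso-type variant
  (vapour-pressure based, using relative humidity) is available through
  `method = "idso"`. Which exact correlation constants the original
  modelling software of this problem used is not recoverable, so the
  package fixes the correlation family and verifies against the
  published Swinbank form directly.
* **Ground.** A 10-node substrate column, geometrically spaced to 2 m
  depth, advances with a backward-Euler finite-volume scheme (six
  10-minute substeps per hour — unconditionally stable and conservative:
  each step's stored-heat change equals the boundary flux). The surface
  node is forced by absorbed solar, longwave exchange with the sky
  temperature and a Jürges-type convective coefficient `5.7 + 3.8 u`.
  Snow (October–December by calendar rule) switches to snow conductivity
  and albedo and caps the surface at 0 °C. The integrator is verified
  against an independent Crank–Nicolson solution on the same grid.

## Body composition and geometry

Structural mass — the non-catabolizable skeleton-determined mass — comes
from a monotone Hyman spline through the six published (length, mass)
anchors. The anchors from both sexes lie on one smooth curve (within 1%
of `15.0 L^3` kg), so the package pools them rather than keeping
sex-specific splines; a power law fitted to the same anchors extends the
curve smoothly to the 1.8–2.5 m validation sweep, and a user-supplied
function can replace it. Storage mass (total minus structural) splits
into fat and lean pools with a per-sex fat fraction fitted once to the
published composition table (≈0.627 female, ≈0.440 male — the tabled
ratios are near-constant within sex). Energy stores are exactly linear:
`E = 39.3 F + 18.0 × 0.22 × L` MJ (fat at 39.3 MJ/kg; lean mass is 22%
protein at 18.0 MJ/kg).

Geometry follows the photo-scaling recipe: part dimensions in photo
units are scaled by straight-line length over the head+neck+torso photo
sum (11.5 units, so a 2.30 m bear scales by 20), twice the fur depth is
subtracted for skin diameters, mass is apportioned by part volume, and a
single multiplicative factor on all radii brings whole-body flesh+fat
density to 1000 kg/m³ — exactly, since volumes are quadratic in radius
at fixed length; the iteration cap in `build_geometry()` only guards
round-off. Because the published work does not print its proportion
table, the default table here was calibrated once against the live-bear
allometric equations (`0.09 M^0.67` and `0.11 M^0.67` m² for skin and
fur): the shipped table holds the maximum deviation to ~5% across
1.8–2.5 m, comfortably inside the published <6%/<7% bounds, with the
torso circumference near the axillary-girth curve. The truncated-cone
head uses a muzzle/base taper of 0.6 (no value is published). The
"reference" fur-depth set (10/40/50/35 mm) used for geometric validation
sits between the summer (10/20/20/20) and winter (15/45/60/35) coats.

Subcutaneous fat is 75% of body fat at 901 kg/m³, distributed over all
parts except the head in proportion to volume, with each annulus
thickness solved in closed form; infeasible allocations fail loudly,
naming the part. End areas follow the joining rules: the torso keeps its
end disks minus the joined neck and leg areas, the neck and legs are
lateral-only, the head keeps its muzzle end.

## The heat-balance solver

Per part, given a trial skin temperature, everything else follows in
closed form: generation from the core-to-skin resistance (solid
generating cylinder, `ΔT = q/(4πkL)`, plus the fat annulus
`ln(r_s/r_f)/(2πk_fat L)`), fur-surface temperature from the fur annulus
(effective conductivity `0.0628 (1 + 0.07 min(u, 7))` W/m·°C folding
conduction and radiative transport within the coat), convection from the
Hilpert cylinder-in-crossflow power law with a free-convection floor,
radiation exchanged at the temperature 85% of the way along the
(logarithmic-in-radius) skin-to-surface profile against a 50% sky / 50%
ground view split, solar absorption over half the fur lateral area (the
sunlit-silhouette approximation) at reflectivity 0.61, and cutaneous
evaporation from a small fixed wetted fraction (0.5%) via the Lewis
analogy. The solver brackets skin temperature and runs Brent's method to
1e-7 °C; trial points far outside the physical range are clamped in the
air-property and radiation kelvin terms so the residual stays finite —
the clamps are unreachable at any solution. The subcutaneous-fat
conductivity (0.20 W/m·°C, blubber-typical) is a parameter of
`bear_params()`; the vasomotor flesh conductivity is the thermoregulated
quantity.

Respiratory loss closes the loop at the whole-animal level: ventilation
is oxygen demand (20.1 kJ/L O₂, 20.95% O₂ air) over extraction
efficiency, and the loss is the sensible plus latent cost of saturating
that air at core temperature. Because the loss depends on summed
generation, the whole-animal solve iterates the respiratory fraction to
joint consistency (a contraction that converges in a few rounds).

Verification is two-route: the production solver (scalar root-find with
closed-form chaining) is compared against a nested-bisection brute force
over (skin, fur-surface) temperature pairs on the same flux equations —
20 randomized part/environment configurations agree within 0.1% — and
the fat-annulus conduction matches its closed form to 1e-6 relative.

## Thermoregulation

Outside the ±5% band around the target rate `2.66 M^0.78` W (the
55 kcal/d/kg^0.78 field equation in watts), options engage in the fixed
order: posture (curling removes the legs from exchange and generation)
or shade (binary, full shade, only when the scenario provides it), then
vasomotion in 0.2 W/m·°C steps within 0.4–2.8, core temperature in
0.5 °C steps within 36–39, and panting as oxygen extraction in 2.5%
steps down to 5%; sweating never engages. Increment sizes are config
constants (`thermo_config()`); the published account fixes the bounds
and the order but not the step sizes.

Three refinements make the discrete cascade behave like the continuous
physiology it stands for:

* a continuous control that steps across the band is bisected within
  that step, so the bear lands in band instead of oscillating;
* a binary toggle that would jump the band (curling when already near
  the lower edge) is held back and the finer controls do the work; it is
  applied only if the side's continuous options exhaust first — this is
  what lets a November bear stay curled and vasodilate rather than
  uncurl into a too-cold state;
* a step that moves the rate *away* from the target (vasodilation when
  the environment is hotter than the skin, which conducts heat inward)
  is reverted and locked for the hour.

Each hour starts from the previous hour's state and relaxes one step at
a time toward neutral while that keeps the rate in band (re-solving from
neutral every hour is available via `carry_state = FALSE`; the original
software's behaviour between hours is not documented, so both modes
exist and the carried mode is the default). When every option is spent
the hour records the closest achievable rate with the `unresolvable`
flag — never silently.

Panting carries no metabolic surcharge by default, mirroring the source
analysis in which panting is energetically free; a configurable
surcharge (e.g. +25% while panting) exists for sensitivity work.

## Fasting

The fast advances in 4-day intervals (the shortest the original forcing
pipeline allowed; configurable). The first day of each interval is the
representative day — "the day being modeled" is not pinned down further
in the source, so this is a documented default — and its 24 regulated
hours give the daily demand, multiplied by the interval length and drawn
from the stores. Fat supplies fraction *f* of the energy (Sim1 94.66%,
Sim2 90.85%, Sim3 88.56% — Sim2 is exactly the fraction at which fat and
lean losses are equal kilograms given the two energy densities; the
other two fractions are literature-derived constants taken as given) and
lean mass the rest at 3.96 MJ/kg; when a pool runs dry the other covers
the shortfall at its own density. Composition, geometry and the
mass-dependent target rate are rebuilt every interval. The winter coat
replaces the summer coat on October 1 by default, aligned with the snow
rule. Starvation is `E = 0`; a mid-interval death is dated by how many
whole days that interval's daily demand could still be paid. The running
average daily weight loss is frozen at the last interval in which both
pools held mass, for comparability with field studies that report
mass-specific loss. Energy and mass bookkeeping is exact by
construction and asserted to 1e-6 relative over a full fast in the
tests.

The minimum energy density for survival sweeps initial size from 1.1×
structural mass upward in 0.1× steps until the first survivor, then fits
an ordinary least-squares line of survived fraction against initial
energy density (total stores over lean body mass) and reports the
density at which the line reaches 1. Least squares is a choice — the
source names only a "best-fit line". Degenerate sweeps return a flagged
bound instead of an extrapolation.

## Synthetic climate

Because the archival Churchill forcing is not redistributable, the
package generates a structurally equivalent series: seasonal sinusoids
for the daily extremes (July maxima near +18 °C, January near −22 °C,
warmest day 205), a shared daily anomaly (s.d. 3 °C) applied to both
extremes so `t_max ≥ t_min` holds by construction, monthly-constant wind
(6 m/s) and humidity, daily cloud spanning 30–100%, snow October
through December, and an optional uniform offset for the +3 °C warmed
scenario. The generator is seeded and deterministic, and its output
round-trips through the package's climate CSV dialect.

What the synthetic forcing does *not* emulate: real day-to-day weather
autocorrelation, wind–temperature covariance, within-month humidity
structure, and precipitation. Passing tests on this forcing demonstrate
the model's internal physics and the *directions* of its responses
(condition ordering of survival, warming easing the cold late fast while
raising warm-season panting); they do not reproduce the published
percentages, which depend on the actual archive. On this forcing the
model's behaviour is nonetheless quantitatively close to the published
account: the average 2.30 m male finishes the historical 120-day fast
with ~41% of stores remaining and ~1.0 kg/d average loss, the poorest
males starve around day 107, and 2.00 m poor females finish with ~6%
remaining.

## Numerical choices and problem sizes

Solver tolerances: 1e-7 °C on skin temperature (steady-state residuals
land near 1e-5 W against the 1e-4·max(1, Q_gen) invariant), 1e-6 on the
respiratory fraction, 40 bisections for within-step cascade refinement.
Ground column: 10 nodes to 2 m (ratio 1.6), hourly steps with six
substeps. The test suite runs one 120-day and four 180-day fasts plus a
three-condition 120-day trio for the ordering properties — sizes chosen
so the full suite completes in under two minutes on one CPU while still
exercising every seasonal regime; the 18-bear population runner
(`run_fast_population()`) scales linearly at roughly 15 s per bear-
season. All solvers are deterministic; randomness exists only in the
seeded climate generator.

## Known limitations

* Steady state per hour: no sub-hourly heat storage beyond the bounded
  core swing, no conduction to the ground through footpads, no wind
  direction.
* Swimming, denning, reproduction and movement energetics are out of
  scope; so is converting minimum energy density into population
  mortality percentages, which requires an external population energy-
  density distribution.
* The cylinder-in-crossflow correlation, 50/50 view factors, linear
  cloud attenuation and sunlit-silhouette solar interception are
  standard simplifications, each exposed as configuration rather than
  hard-coded.
* The default proportion table is calibrated to whole-bear areas; per-
  part dimensions are plausible but not validated individually.
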