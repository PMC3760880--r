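# polarfast

Mechanistic heat-balance and fasting energetics for polar bears
(*Ursus maritimus*).

Polar bears of the western Hudson Bay population are forced ashore when
the sea ice melts and then fast for months on stored body reserves. As
break-up comes earlier and freeze-up later, the central management
question is energetic: which bears carry enough stored energy to survive
an extended ice-free season, and how much of the demand is set by the
physical environment rather than by body size alone? `polarfast`
addresses that question with a first-principles model instead of a
regression: every hour, the metabolic rate is whatever heat production
balances the bear's losses to its microclimate.

## The model

The package chains four components:

1. **Microclimate.** Daily extremes of temperature, wind, humidity and
   cloud are interpolated onto hourly sinusoids anchored at sunrise
   (minimum temperature, maximum humidity) and one hour after solar noon
   (the opposite extremes). Clear-sky solar irradiance comes from solar
   geometry with a simple transmittance model and is attenuated linearly
   by cloud; longwave sky temperature blends the Swinbank clear-sky
   correlation with cloud emission near air temperature; ground surface
   temperature comes from a 10-node, one-dimensional substrate
   heat-conduction column forced by the surface energy balance (snow-
   covered from October through December).

2. **Morphometry.** The bear is a set of photo-proportioned parts — a
   truncated-cone head and cylindrical neck, torso and legs — scaled to
   straight-line body length. Total mass splits into structural mass
   (from the published length anchors, roughly 15·L³ kg) and storage
   mass, which divides into fat and lean pools by sex. Radii are
   adjusted to a whole-body flesh+fat density of ~1000 kg/m³; 75% of
   body fat forms a subcutaneous annulus on every part except the head.

3. **Heat balance.** Per part, the steady state solves

   Q_gen − Q_resp − Q_evap = Q_fur = Q_rad + Q_conv − Q_sol

   for the generation rate Q_gen that holds the core at 37 °C:
   conduction from a generating flesh cylinder through the fat annulus
   and a fur layer whose conductivity (0.0628 W/m·°C still air) grows 7%
   per m/s of wind; convection from a cylinder in crossflow; thermal
   radiation exchanged at the fur temperature 85% of the way from skin
   to surface; absorbed solar load at coat reflectivity 0.61; and a
   respiratory loss set by oxygen demand and extraction efficiency.

4. **Thermoregulation and fasting.** If the solved rate leaves ±5% of
   the fasting target rate 2.66·M^0.78 W, options engage in a fixed
   order — posture/shade first, then vasomotion (flesh conductivity
   0.4–2.8 W/m·°C), bounded core-temperature change (36–39 °C), and
   finally panting (oxygen extraction 20% → 5%); sweating is disabled.
   The fast proceeds in 4-day intervals: the daily demand is drawn from
   the energy stores with fat supplying 94.66 / 90.85 / 88.56% of energy
   (scenarios Sim1–Sim3), composition and geometry are rebuilt, and a
   bear starves when its stores reach zero. A size sweep locates the
   minimum energy density (MJ per kg of lean body mass) needed to
   survive a given fast.

## Worked example

```r
library(polarfast)

# geometric validation against live-bear allometry
glance(validate_allometry())
#>   n_lengths max_abs_skin_dev_pct max_abs_fur_dev_pct skin_in_bounds fur_in_bounds
#> 1         8                 5.23                4.87 TRUE           TRUE

# a 120-day fast for an average-condition 2.30 m male on synthetic
# Churchill-like forcing
cl   <- generate_climate(climate_profile(seed = 1), 2000)
bear <- init_composition(2.30, 2.25, "male")     # 409 kg, 4430 MJ stores
fast <- run_fast(bear, cl, fast_scenario("2000-07-29", 120, sim = 2))
fast
#> <bear_fast> 2.30 m male, 409.5 kg start; survived 120 days with 41.1% energy remaining
#>   avg daily weight loss 1.01 kg/d; panting 13.2% of hours
```

The maximum deviations of the modeled fur and skin areas from the
live-bear predictive equations (0.11·M^0.67 and 0.09·M^0.67 m²) are
4.9% and 5.2% across 1.8–2.5 m average-condition bears. The simulated
average male survives the historical 120-day fast losing about 1 kg/day
— the field-study range for this population — with panting needed only
in the warm opening weeks of the fast; poor-condition males starve
before day 120 while poor-condition females scrape through, matching
the ordering reported from the population. `tidy(fast)` returns the
per-interval composition trajectory and `autoplot(fast)` draws it.

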