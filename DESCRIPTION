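Package: polarfast
Title: Mechanistic Heat-Balance and Fasting Energetics for Polar Bears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the energetics of adult polar bears (Ursus maritimus)
    fasting onshore during the ice-free season. An hourly microclimate model
    (sinusoidal interpolation of daily extremes, clear-sky solar geometry with
    cloud attenuation, longwave sky temperature from air-temperature
    correlations, and a one-dimensional substrate heat-conduction column)
    drives a layered steady-state heat-balance solver for a bear built from
    photo-scaled cylindrical body parts with flesh, subcutaneous fat and fur
    layers. A hierarchical thermoregulation cascade (posture, shade,
    vasomotion, bounded core-temperature change, panting) holds the solved
    metabolic rate within a band around a fasting target rate. A fasting
    pipeline partitions the resulting energetic demand into fat and lean
    losses over multi-day intervals, tracks body composition and survival,
    and estimates the minimum energy density needed to survive a fast under
    current and uniformly warmed climates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
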