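Package: onager
Title: Space-Use Analysis of Hourly GPS Telemetry: Displacement, Habitat
    Selection and Recursion Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the space-use patterns of GPS-collared large
    herbivores in heterogeneous landscapes, built around hourly relocation
    series. Implements hourly displacement profiles, simplified movement-based
    kernel utilization distributions with isopleth home ranges, use-versus-
    availability habitat selection coefficients on raster habitat layers,
    water-point visit detection with an empirically derived visit radius,
    per-location residence/recursion/visit metrics with censoring-aware
    Kaplan-Meier summaries, a periodic Poisson model scan for 24-hour
    periodicity in recursion times, random-intercept model selection for
    visit rate versus home range size, and clustering of main recursion
    sites. A synthetic landscape and trajectory generator with the same
    statistical structure makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    survival,
    igraph
Suggests:
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
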