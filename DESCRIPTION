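Package: seedrain
Title: Data-Driven Simulation of Seed Dispersal by Migratory Herbivores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates propagule dispersal by migrating animals from GPS
    tracking data. Couples optimal-transport migratory connectivity between
    seasonal ranges (an exact solution of the Monge-Kantorovich transportation
    problem on an equal-area hexagonal grid), an empirical random trajectory
    generator that reproduces the step-length and turning-angle geometry of
    observed tracks between fixed endpoints, and a gut-retention
    foraging/excretion model producing spatial seed-rain and seed-fate maps.
    Includes a synthetic-island generator for self-contained experiments,
    utilization-distribution estimation, and Kolmogorov-Smirnov validation
    against observed dung-pile records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    mgcv,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
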