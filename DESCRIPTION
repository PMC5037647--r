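Package: feedlife
Title: Lifetime Energy Budget Simulation of Resource Acquisition and
    Allocation in Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the lifetime energy budget of an individual dairy cow
    at a daily time step, dissociating genetically-driven resource
    acquisition (dry-matter intake and its conversion to metabolizable
    energy) from resource allocation (priority partitioning of energy
    among growth, gestation, lactation and somatic functions).  Allocation
    follows a four-compartment priority system integrated with a
    fixed-step fourth-order Runge-Kutta scheme, punctuated by discrete
    reproductive events (conception, parturition, drying-off, culling,
    death) with seeded stochastic conception.  Includes lactation-level
    and lifetime feed-efficiency metrics, a 3^4 complete factorial
    sensitivity experiment over four genetic-scaling parameters with
    replicates, and ANOVA variance-decomposition sensitivity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
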