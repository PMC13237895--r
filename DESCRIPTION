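Package: lhsdrive
Title: Engine-Drivetrain Evaluation of Learning Health Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, simulation and evaluation tools for the engine-drivetrain
    model of a Learning Health System (LHS), in which a Clinical and
    Translational Science Award (CTSA) hub acts as the translational engine and
    community empowerment acts as the variable transmission coupling four
    learning cycles (clinical care, education, research, governance). Provides
    the Community Transmission Index (CTI) instrument with multi-rater scoring,
    maturity bands and weighted-kappa reliability; the mechanistic transmission,
    friction and spillover-coupling model mapping CTI to cycle velocities;
    translational efficiency indices (gain, bottleneck, global) and the LHS
    typology; an economic layer (innovation throughput, revenue, cost, return
    on investment); seeded deterministic and Monte Carlo simulation protocols;
    and Results-style statistical reporting (correlations, Kruskal-Wallis group
    comparisons, multivariate ROI regression).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
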