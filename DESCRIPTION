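Package: evotitrate
Title: Eco-Evolutionary Tumor Dynamics, Optimal Dose Titration and Virtual
    Trials for Abiraterone Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models metastatic castrate-resistant prostate cancer as a
    three-species Lotka-Volterra competition game between androgen-dependent,
    testosterone-producing and androgen-independent tumor cells, with the
    abiraterone dose acting on carrying capacities. Provides equilibrium
    enumeration and stability analysis over constant doses, a Forward-Backward
    Sweep solver for the reach-the-equilibrium optimal control problem, six
    clinically feasible closed-loop dosing protocols (maximum tolerated dose,
    adaptive therapy and dose titration variants), seeded virtual-patient
    cohort generation, and Kaplan-Meier survival reporting. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
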