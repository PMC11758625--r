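Package: ketodose
Title: Pharmacokinetic Modelling and Dose Optimisation for Oral 3-Hydroxybutyrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-compartment pharmacokinetic model for orally ingested
    3-hydroxybutyrate (3-HB) with saturable (Michaelis-Menten) and
    non-saturable gastrointestinal absorption, constant endogenous
    production, and linear elimination. Provides forward simulation,
    simultaneous nonlinear least-squares estimation across dose arms with
    AIC-based comparison of absorption-pathway variants, calibration of
    absorption parameters from printed Cmax/Tmax summaries, and search for
    the minimum oral dose reaching a target peak serum concentration.
    Companion tools analyse 2x2 crossover efficacy trials (change scores,
    POMS2 total mood disturbance, linear mixed model with sequence, period
    and treatment effects, baseline tests) and generate synthetic serum
    concentration profiles and crossover datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    lme4,
    lhs,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
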