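Package: ageflux
Title: Demand-Gated, Age-Structured Simulation of RNA and Protein Level
    Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time, age-structured simulation of biomolecule
    (mRNA, protein) abundance in single cells, in which production occurs
    in fixed-size pulses gated by a demand for biomolecule activity:
    cohorts age with per-age survival coefficients, contribute activity
    through per-age activity coefficients, and a pulse fires whenever
    total activity falls below demand.  Includes a two-unit
    transcription-translation coupling and n-unit chains/webs, exact
    cycle (wavelength/amplitude) detection for the deterministic
    dynamics, a staggered-labelling design that recovers the RNA age
    distribution by differencing labelled totals, exhaustive grid-search
    least-squares estimation of lifespans, survival rates, pulse levels
    and demands from time-series abundance data, and generators for
    synthetic observation series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
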