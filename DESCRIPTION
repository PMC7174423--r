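Package: ragweedburden
Title: Health Burden of Ragweed Pollen in Europe and Its Reduction by
    Biological Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation chain from airborne common-ragweed (Ambrosia
    artemisiifolia) pollen measurements and allergy sensitisation studies to
    patient numbers and annual economic costs across Europe, and projection
    of how establishment of the biocontrol leaf beetle Ophraella communa
    changes both. Provides point-to-grid inverse-distance interpolation and
    Jenks natural-breaks classification; sensitisation mapping with
    clinical-relevance correction and a pollen-exposure threshold; a
    community-level log-log through-origin exposure-response fit yielding a
    patient elasticity; purchasing-power-parity weighted cost aggregation;
    growing-degree-day voltinism mapping with a generation-dependent
    pollen-reduction policy; an allometric raceme estimator with a
    random-intercept hurdle model for the field exclusion experiment; and
    seeded synthetic-data generators so the whole pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), lme4, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
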