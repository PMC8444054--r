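Package: phnsim
Title: System Dynamics Modelling of Regional Mental Health Services and
    Suicide Prevention Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stock-and-flow system dynamics model of a regional mental
    health service catchment (population dynamics, psychological distress,
    service pathways with capacity constraints and waiting-time-driven
    disengagement, and suicidal behaviour), together with the analysis
    machinery built on it: business-as-usual projection, a catalogue of 13
    suicide prevention and mental health services interventions, exhaustive
    search over 4- and 5-intervention combinations per catchment and at
    state level, quantification of the benefit of regional versus
    centralised planning, derivative-free (Powell-type) calibration against
    yearly observed series under a mean-absolute-percent-error objective,
    and Latin hypercube sensitivity analysis of intervention effect
    assumptions. A synthetic ten-catchment state generator emulating
    realistic regional heterogeneity makes every analysis runnable and
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
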