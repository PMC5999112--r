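Package: mothnav
Title: Moth-Inspired Navigation in Turbulent Odor Plumes from a Pulsating Source
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of odor-source localization in a windy
    environment, inspired by male moths tracking pulsed pheromone plumes. A
    Lagrangian Gaussian-puff model disperses discrete odor parcels released
    at a constant pulsing rate into a stochastic wind (mean flow, turbulent
    fluctuations, gusts, and slow meandering). A threshold-sensor navigator
    performs optomotor anemotaxis: it times upwind surges and counter-turn
    (casting) legs by the instantaneously measured puff crossing time. A
    Monte-Carlo harness estimates success probabilities and flight metrics
    across turbulence intensities, meander and gust settings, and compares
    the crossing-time strategy against a fixed internal-counter baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
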