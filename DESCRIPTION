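Package: flockdual
Title: Apparent Interaction Rules from Co-Moving Individuals at Fixed Mutual Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates pairs and triplets of individuals that travel on a
    shared correlated-random trajectory while holding fixed mutual target
    positions under temporally autocorrelated positional noise, and provides
    the analysis suite that infers their apparent interaction rules from the
    recorded tracks: polar force maps of turning and tangential acceleration,
    attraction-versus-alignment turning maps, directional correlation delays
    (leadership), and multi-neighbour response combination. Demonstrates the
    duality between imposed mutual positions and the interaction rules an
    observer would infer from trajectory data alone.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
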