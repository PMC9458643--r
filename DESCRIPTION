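Package: larvappi
Title: Prepulse Inhibition in the Drosophila Larva Startle Circuit
Version: 0.1.0
Authors@R:
    person("Taro", "Ishikawa", email = "t.ishikawa@example.org",
           role = c("aut", "cre"))
Description: Simulates the seven-node firing-rate model of the Drosophila
    larva startle-response circuit (chordotonal input, Basin projection
    neurons, feedforward inhibitory local interneurons and handle neurons)
    and the behavioural read-out built on it. Provides fourth-order
    Runge-Kutta integration of the rectified rate dynamics, threshold-based
    classification of hunch, bend and no-reaction outcomes with bout
    extraction and a minimum-duration cut-off, behavioural landscapes over
    the chordotonal input-weight plane, prepulse-inhibition change and
    residual-activity (persistence) maps, lead-interval sweeps, in silico
    neuron silencing, and maximum-rate manipulations modelling enhanced
    neurotransmitter release. Results are returned as tibbles with ggplot2
    autoplot methods; experiments are scriptable through a configuration
    interface and a command-line entry point.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
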