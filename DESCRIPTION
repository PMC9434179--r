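Package: reversim
Title: Wright-Fisher Simulation of Reversion and Compensation of Costly
    Resistance Mutations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of what happens after a
    costly resistance (or other adaptive) mutation has fixed in a haploid
    microbial population and the selecting environment is removed. The package
    models the race between direct reversion to the wild type and the
    fixation of partially or fully compensating mutations, including the
    soft-sweep regime where the reversal mutation arises on both the
    uncompensated and compensated genetic backgrounds. It provides the
    stochastic engine (per-generation mutation kernel and fitness-weighted
    multinomial reproduction), a deterministic/analytic approximation for the
    probability that a reversal establishes before compensation fixes, an
    exact Markov-chain oracle for tiny instances, experiment-scale clone
    sampling, and replicate-grid drivers with summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
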