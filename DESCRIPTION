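Package: rwddm
Title: Rescorla-Wagner Drift-Diffusion Model of Conditioning and Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for the Rescorla-Wagner
    Drift-Diffusion Model (RWDDM) of classical conditioning and interval
    timing. The model couples a noisy linear accumulator with an adaptive
    drift (a timing drift-diffusion process) to a time-scaled
    Rescorla-Wagner associative learning rule, with optional Pearce-Hall
    learning-rate adaptation. Provides the timer, stimulus-representation
    and learning primitives, a protocol engine with preset conditioning
    designs (acquisition/extinction, ISI effect, fixed and variable
    interval schedules, mixed FI, latent inhibition, blocking with
    unequal durations, conditioned inhibition, compound peak procedure,
    temporal averaging), and analysis routines for averaged response
    curves, timescale-invariance checks and peak statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
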