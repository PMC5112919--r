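Package: microdosim
Title: Stochastic Microdosimetry of the Natural Radiation Background for Bacterial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level Monte Carlo simulator quantifying how often natural
    background radiation (terrestrial gamma rays, potassium-40 beta decay in
    the growth medium, cosmic-ray neutrons and muons) deposits energy in
    individual bacterial cells grown in microplate wells. A macroscopic stage
    transports primaries through a 96-well plate model and records the
    charged secondaries entering or created in a sensitive well into a phase
    space file; a microscopic stage replays those particles through a
    periodic 200 micrometre domain packed with capsule-shaped cells using
    chord-based condensed-history transport with energy-loss straggling.
    Hit lists are reduced to per-cell per-day hit frequencies, per-nanogray
    interaction rates and energy-deposit statistics, and compared against
    spontaneous mutation rates in long-term evolution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
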