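Package: ethoseq
Title: Behavioral Sequence Analysis for Dyadic Agonistic Encounters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethology of timed behavioral event logs
    from dyadic (and single-animal) encounters: ethogram management with
    category structure, time budgets, bout durations and occurrence rates,
    first-order behavioral transition matrices with structural-zero diagonals,
    quasi-independence log-linear models fitted by iterative proportional
    scaling with likelihood-ratio G tests and Freeman-Tukey cell deviates,
    cross-cohort log-linear comparisons, kinematic diagram export in DOT
    format, nonparametric ontogeny statistics (Kruskal-Wallis with Dunn's
    post-hoc, Tukey-type comparisons of arcsine-transformed proportions,
    dominance and escalation tests), and an age-parameterized semi-Markov
    simulator of dyadic encounter sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
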