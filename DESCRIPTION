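Package: spdeconv
Title: Deconvolution of RNA Structure Ensembles from Chemical Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects a parsimonious set of co-existing RNA secondary
    structures and estimates their relative abundances from chemical
    structure-profiling (SHAPE/DMS) sequencing data. Reads are binned into
    modification patterns (reverse-transcriptase truncations or mutational
    profiles), a generative model turns candidate structures into
    pattern-probability columns of a design matrix, and non-negative least
    squares recovers sparse structure abundances. Includes closed-form
    reactivity and noise estimators, candidate pre-filtering, ensemble
    post-processing (pairing probabilities, base-pairing Shannon entropy,
    motif-based cluster trajectories, structure-function linear fits), and
    a seeded read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
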