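Package: fluortree
Title: De Novo Design of Fluorescent Molecules by Monte Carlo Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates candidate fluorescent molecules by Monte Carlo tree
    search over SMILES tokens, guided by an autoregressive language-model
    prior and parallelized with virtual loss. Candidates are scored by a
    four-component photophysical reward built from absorption and
    fluorescence wavelengths and their oscillator strengths, evaluated
    either by a deterministic structural surrogate or through a
    quantum-chemistry adapter (TD-DFT input-deck writer and output-log
    parser). Includes the structural descriptors (aromatic ring count,
    conjugation length), the post-run photophysical filter, correlation
    tables, and run summaries used to screen fluorophore candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'analysis.R'
    'cli.R'
    'fluortree-package.R'
    'mcts.R'
    'tokenizer.R'
    'molecule.R'
    'oracle.R'
    'plots.R'
    'prior.R'
    'qc_io.R'
    'reward.R'
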