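Package: codonchannel
Title: Markov Chain-Like Classical and Quantum Models of the Codon
    Substitution Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the DNA-to-protein transmission of genetic information as
    a noisy communication channel over the 64 codons. Implements the
    classical Markov-chain codon channel, an amplitude-level (Markovian-like
    quantum) chain in which stage transition amplitudes rather than
    probabilities compose, its operator-sum (Kraus) representation and
    Lindblad first-order limit, hybrid quantum-classical chains, and the
    nucleotide-level 4-ary symmetric and Kimura two-parameter reference
    processes. Channel capacity in bits per residue is computed by
    Blahut-Arimoto mutual-information maximization and by the
    Holevo-Schumacher-Westmoreland formula over amino-acid input ensembles,
    with sweep and crossing-threshold utilities for studying capacity as a
    function of the single-base error probability, the number of stages, and
    the number of generations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
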