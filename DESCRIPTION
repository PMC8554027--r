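Package: pmedit
Title: Homologous-Arm and Primer Design for Suicide-Plasmid Point Mutation Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch design of the two homologous arms and seven primers required to
    introduce a single genomic point mutation (substitution, insertion or deletion)
    into a bacterial chromosome by suicide-plasmid counter-selection editing with
    overlap-based vector assembly. For every requested edit the package validates
    the input against the target genome, derives the optional design regions,
    constructs the three 20-bp assembly overhangs, optimizes all seven primers
    under nearest-neighbor melting-temperature and GC constraints, evaluates
    off-target homology of the arms, and verifies the design by simulating the
    assembly and both single-crossover events in silico. Includes a seeded
    synthetic fixture generator and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
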