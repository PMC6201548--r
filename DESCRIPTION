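Package: karyoforge
Title: Reference-Assisted Chromosome Assembly Simulation and Avian Karyotype-Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying avian karyotype evolution with fragmented
    genome assemblies. Simulates ancestral multichromosomal genomes carrying
    conserved non-coding element (CNE) and multi-species homologous synteny
    block (msHSB) tracks, plants inversions, fusions and fissions with a
    CNE-poor breakpoint bias, and fragments the derived karyotype into
    scaffolds with chimeric joins, spanning read-pair coverage, an in-silico
    PCR oracle and BAC/FISH observations. Rebuilds chromosomes via a
    simplified reference-assisted assembly (syntenic-fragment merging,
    PCR-calibrated coverage thresholds for chimera splitting, predicted
    chromosome fragment chaining, FISH anchoring, AGP export), classifies
    evolutionary breakpoint regions (fusion, fission, intrachromosomal),
    and quantifies CNE-density contrasts between breakpoint classes, msHSBs
    and the genome-wide background with rank-based tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
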