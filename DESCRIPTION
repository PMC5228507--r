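Package: crisprscout
Title: Reference-Guided CRISPR Spacer Detection and Virus-Host Mapping from
    Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR spacers directly in unassembled metagenomic reads
    by approximate matching of known direct-repeat sequences under a
    Levenshtein edit budget, extracts the inter-repeat spacers, collapses them
    into non-redundant clusters at a 90% identity threshold, aligns them to a
    viral genome library to infer a bipartite virus-host interaction network,
    and compares virus and host oligonucleotide (dimer/trimer) usage with a
    squared-difference distance. Includes a fully reproducible synthetic
    metagenome generator (planted repeat-spacer-repeat arrays with bounded
    repeat mutations and spacers excised from simulated viral genomes) so the
    whole pipeline can be exercised and scored against ground truth offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
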