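Package: domainhood
Title: Domain-Centric Annotation and Neighborhood Analysis of Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates viral (or any) nucleotide genomes with protein domains by
    six-frame translation and profile-HMM search (HMMER3) over whole frames,
    overlapping amino-acid windows, or annotated genes; rescales per-domain
    E-values for the windowed search space; resolves redundant overlapping hits
    with clan-aware de-overlap rules; and reconstructs "domain neighborhoods",
    the ordered domains flanking a domain of interest with signed ordered-domain
    distances. Neighborhoods are turned into clan-keyed inverse-square-distance
    feature matrices for hierarchical clustering and comparison against
    taxonomy via the adjusted Rand index. Includes a synthetic-genome generator
    with planted domain architectures so the full pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
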