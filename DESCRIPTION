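Package: ssrdb
Title: Audited Management, Merging and Comparison of SSR DNA Fingerprint Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and curating plant SSR (microsatellite) DNA
    fingerprint databases. Implements a three-tier audited fingerprint store
    (experimental, sample and local databases) with locking and provenance
    tracing; hierarchical weighted consensus merging of replicate genotyping
    experiments (experiment, DNA, experimenter, sample, variety layers);
    offset-tolerant pairwise fingerprint comparison with the five standard
    comparison scopes and report filtering; replicate-audit quality control
    including a noise-tolerance scan; genetic analysis (allele frequency
    tables, twelve genetic distance measures, UPGMA and neighbour-joining
    trees with Newick export); readers and writers for GeneMapper-style
    genotype tables, sample information tables and 96-well plate layouts; and
    a seeded synthetic-data generator so every pipeline stage can be
    exercised end to end. All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
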