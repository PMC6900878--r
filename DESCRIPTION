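Package: synsig
Title: Signatures and Hotspot Detection for Cancer-Associated Synonymous
    Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotation and analysis of somatic synonymous single-nucleotide
    variants in coding sequences: codon- and context-level annotation
    (substitution pattern, CpG dinucleotide context, six sequence-context
    subtypes, optimal-codon transitions), substitution-spectrum and
    amino-acid-level summaries per cancer type, hotspot detection at
    amino-acid resolution using a per-gene, per-cancer-type, per-subtype
    Poisson background with Fisher's combined probability test and
    Benjamini-Hochberg false-discovery-rate control, and comparative
    analyses (conservation scores, amino-acid distributions, protein-domain
    overlap) between hotspot, non-hotspot and neutral mutation sets.
    Includes seeded generators for synthetic tumor and neutral cohorts with
    planted hotspots so that every stage of the pipeline can be exercised
    and validated end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
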