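Package: smrecruit
Title: Comparative Analysis of Enzyme Recruitment from Primary into
    Secondary Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the enzyme repertoires of bacterial primary
    metabolism (genomes free of biosynthetic gene clusters) and secondary
    metabolism (enzymes encoded in biosynthetic gene clusters, BGCs) on the
    basis of Enzyme Commission (EC) numbers. Computes normalized EC-frequency
    spectra at every level of the EC hierarchy, overrepresentation ratios and
    shared/exclusive function sets, filters homology hit tables by E-value and
    protein-length criteria, classifies secondary-metabolism functions by the
    functional makeup of their primary-metabolism homologs (monofunctional,
    multifunctional, or fully changed), derives rates of functional
    conservation and directed functional-change networks exportable to
    Cytoscape formats, and annotates the genomic neighborhoods of putative
    primary-metabolism homologs with pathway summaries and per-cluster HTML
    reports. Includes a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
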