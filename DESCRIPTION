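Package: norgscan
Title: Detection and Comparative Analysis of Nuclear Copies of Organellar DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects nuclear copies of mitochondrial and plastid DNA (NUMTs
    and NUPTs) in genome assemblies with a self-contained seed-and-extend
    local aligner using Karlin-Altschul E-value statistics, deduplicates
    overlapping hits into counted segments by interval union, and summarises
    per-genome content (counts, total length, per-Mb densities). Provides the
    comparative statistical layer used in desiccation-tolerance studies of
    endosymbiotic DNA transfer: lineage averaging over paired designs, exact
    two-tailed Wilcoxon signed-rank tests, phylogenetic generalized least
    squares with maximum-likelihood Pagel's lambda against assembly-level
    codes, and Spearman correlation with genome size. A synthetic-data module
    generates nuclear genomes with planted organellar insertions at controlled
    length and identity, contaminant contigs, pure-birth trees, traits under
    lambda-scaled Brownian motion, and paired designs, giving ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
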