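Package: panelscreen
Title: Large-Deletion Detection and Recessive Variant Prioritization for
    Targeted Capture Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-diagnostics toolkit for targeted-capture sequencing of
    recessive-disease gene panels (the Fanconi anemia genes being the
    motivating panel). Detects large (multi-exon down to single-exon)
    deletions from read depth via windowed log2 ratios against a pooled
    median reference, including mosaic deletions diluted by normal cells,
    and estimates the mosaic cell fraction. Formalizes the recessive variant
    filtering funnel (on-target, nonsynonymous/splice, population frequency,
    disease genes, pathogenic clue) and a recessive prioritization of
    biallelic findings that integrates point variants with deletion calls.
    Includes a minimal transcript-aware consequence annotator with HGVS c.
    positions (intronic offsets included), pseudogene-region allele-fraction
    flagging, and a fully deterministic synthetic capture-cohort simulator
    with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    patchwork,
    yaml,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
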