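Package: hapblend
Title: Hybrid Assembly Blending and Haplotype Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Blends a contiguous but error-prone long-read (TGS) genome
    assembly with accurate, fragmented, haplotype-resolved co-barcoded (SLR)
    assemblies. Whole-assembly alignments are screened with a collinear
    chaining dynamic program over alignment blocks, small-scale errors in the
    long-read contigs are corrected by replacing sub-threshold substitution
    and indel events extracted from cs difference strings, and the resulting
    haplotype assemblies are evaluated with trio-based hapmer statistics
    (haplotyping precision/recall/F1, k-mer consensus quality, completeness,
    phase blocks) and a switch-error minimizing dynamic program over phased
    variants. Includes a ground-truthed synthetic diploid fixture generator
    and a built-in anchor-plus-banded-alignment engine so the whole pipeline
    runs without external binaries.
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
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
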