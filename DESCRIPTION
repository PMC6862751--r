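Package: islandswap
Title: Simulation and Analysis of CRISPR Dual-Cut CpG Island Replacement Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse amplicon sequencing of CRISPR/Cas9
    dual-cut replacement of a CpG island with in vitro methylated DNA. Provides
    a surrogate locus model with allele-defining SNVs and PAM mutations, a
    truth-labelled read simulator for short-read, long-read and bisulfite
    branches (including editing outcomes, junction indels, inversions, wholesale
    deletions and 6-thioguanine selection), a banded affine-gap global aligner
    with orientation selection, UMI clustering and majority consensus calling,
    perfect-match allele and methylation callers, junction indel profiling, and
    the comparison statistics used to summarise editing outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
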