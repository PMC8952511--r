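Package: sdpnet
Title: Specificity Determining Position Networks for Protein Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects specificity determining positions (SDPs) in protein
    superfamily alignments by combining cluster-determining-position (CDP)
    detection with column-column mutual information (MI) networks. Provides
    alignment scrutiny filters that remove truncated, misaligned, repeated and
    shuffled sequences; profile-based subfamily clustering under a 100%
    precision-and-recall rule; permutation z-scores for column-to-partition and
    column-to-column MI; selection of the Specificity Determining Network (SDN)
    by maximising the Specific Network Score (SNS) over MI thresholds; a
    1000-random-network significance test; and a synthetic superfamily
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
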