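Package: kaspqc
Title: Cluster Calling and Typing-Quality Grading for KASP Genotyping Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated evaluation of endpoint fluorescence data from KASP
    (kompetitive allele-specific PCR) genotyping plates. Wells of each SNP
    marker are partitioned into no-template controls, heterozygous, untyped
    and homozygous classes by rule-based region extraction, clustered with a
    deterministically initialized K-means, summarized into 24
    position-and-morphology eigenvalues, and assigned a 0-3 typing-quality
    grade through a rule-based decision tree over per-primer amplification
    efficiency, specificity and combination competitiveness. Includes a
    synthetic plate simulator with known class structure, typing-map plots
    and a command-line driver for batch screening of markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
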