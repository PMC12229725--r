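Package: vcnref
Title: Measurement Tools for Lentiviral Vector Copy Number Reference Materials
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for characterizing lentiviral vector copy
    number (VCN) reference materials across laboratories. Converts digital PCR
    partition counts into copy concentrations and VCN estimates under the
    Poisson occupancy model, fits qPCR standard curves with amplification
    efficiency QC, pools per-laboratory estimates into consensus values with
    dark uncertainty by the DerSimonian-Laird random-effects procedure,
    assesses reference-material homogeneity and stability, harmonizes
    lentiviral integration-site reports across laboratory conventions under
    the 5-bp target-site-duplication model, and classifies molecular-combing
    probe-length signals into wild-type and integration-bearing classes.
    Includes seeded synthetic-data generators emulating every input the
    pipeline consumes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    BiocGenerics,
    metafor,
    mclust,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
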