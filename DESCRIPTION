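Package: ctdnamon
Title: Circulating Tumor DNA Therapy Monitoring from Duplicate cfDNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monitors response to neoadjuvant radio(chemo)therapy in locally
    advanced rectal cancer from ultradeep targeted sequencing of plasma
    cell-free DNA. Detects candidate somatic mutations supported in duplicate
    cfDNA libraries and absent from matched leukocyte (buffycoat) DNA,
    validates them against a cohort-wide buffycoat background using a
    95th-percentile variant-allele-frequency filter, converts plasma cfDNA
    mass into genome equivalents and a biological limit of detection,
    classifies per-patient ctDNA dynamics between timepoints, and tests
    association with pathological response by Fisher's exact test. Includes a
    truth-labelled synthetic cohort generator emulating tumor, clonal
    hematopoiesis and germline variants with binomial sequencing noise, so
    the full pipeline is testable without patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
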