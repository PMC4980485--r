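Package: clonaldrift
Title: Clonal Remodelling of Tumours Under Neoadjuvant Endocrine Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers treatment-induced remodelling of tumour subclonal
    architecture from paired pre- and post-treatment sequencing read counts.
    Provides somatic variant filtering (binomial log-likelihood ratio and
    copy-number-neutral masking), purity estimation and correction of variant
    allele fractions, multi-sample binomial mixture clustering of variant
    allele fractions into subclones, clonal evolution tree enumeration under
    the sum rule with collision-tumour detection, per-variant temporal
    classification by Fisher's exact test, and a clonal instability index
    with a four-way tumour-pattern classification. Includes a synthetic-data
    generator that plants known clonal phylogenies, per-sample clone
    fractions, tumour purities and binomial read counts for end-to-end
    validation.
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
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
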