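Package: allelopool
Title: Allele Frequency Estimation from Pooled DNA on SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates population B-allele frequencies of pooled DNA
    samples genotyped on SNP arrays, by piecewise-linear interpolation of
    the pool's allelic intensity ratio (theta) against the mean theta of
    the AA, AB and BB genotype clusters fitted from individually
    genotyped reference samples. Includes a genotype-cluster calling
    surrogate with GenCall-like confidence scores, the quality-control
    cascade used for degraded-sample genotyping (classification,
    call-rate, heterozygote excess/deficit and minor-allele-frequency
    filters), replicate repeatability metrics, reference-panel subset
    resampling to assess how many individually genotyped reference
    samples are needed, and a synthetic-data generator that emulates
    array intensities, pooled designs and DNA-degradation effects so the
    whole pipeline can be exercised without proprietary data.
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
    readr,
    stringr,
    ggplot2,
    generics,
    mclust,
    lme4,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
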