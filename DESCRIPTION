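Package: daeimpute
Title: Reference-Free Genotype Imputation with Sparse Denoising Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free, unphased genotype imputation built on sparse
    denoising autoencoders. Splits a chromosome into approximately
    independent genomic segments at recombination hotspots via windowed
    linkage-disequilibrium box counts, encodes bi-allelic genotypes as
    allele-presence bit pairs, trains one fully connected autoencoder per
    segment under a penalized focal loss with an escalating masking
    curriculum and simulated-offspring augmentation, selects hyperparameters
    with a gradient-boosted meta-model over segment features, and evaluates
    imputation accuracy (dosage r-squared, concordance, macro F1) stratified
    by minor-allele-frequency bin. Includes a synthetic haplotype-panel
    generator with controllable LD-block and hotspot structure so the whole
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
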