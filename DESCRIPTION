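Package: dhdrift
Title: Drift and Selection During Doubled-Haploid Production from Landraces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the loss of genetic diversity when doubled-haploid (DH)
    line libraries are produced from open-pollinated landrace populations, and
    separates neutral drift from selection. Implements genotype-panel quality
    control (heterozygote masking in DH lines, monomorphic and missingness
    filters, exact Hardy-Weinberg mid-p tests), per-site nucleotide diversity
    and joint site frequency spectra, two allele-frequency outlier tests built
    on a three-stage binomial sampling model (a grid maximum-likelihood
    ancestral-frequency test with central confidence intervals, and a
    beta-binomial joint-probability test), haplotype-window diversity with
    major-haplotype fate classification, heterozygosity enrichment of outliers,
    and GERP-based genetic load comparisons under additive and recessive
    models. A synthetic-data generator emulates the three-stage sampling
    scheme (landrace genotyping, DH pool survival with optional recessive
    viability selection, DH genotyping) so every stage of the pipeline can be
    exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
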