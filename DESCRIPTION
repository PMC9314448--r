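Package: ultrasel
Title: Estimation of Ultraselection from Rare-Variant Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of "ultraselection" -- purifying
    selection strong enough to deplete even rare single-nucleotide variants
    in deeply sequenced population panels -- for arbitrary sets of genomic
    sites. A neighbor-dependent (heptamer-context), covariate-adjusted and
    regionally rescaled neutral mutation model predicts per-site, per-allele
    probabilities of observing a rare variant; the fractional depletion
    lambda_s of rare variants in a target region relative to that expectation
    is estimated by maximum likelihood, with closed-form standard errors and
    a likelihood-ratio test. Under mutation-selection balance, large values
    of lambda_s are converted to heterozygous selection coefficients
    (s_het). Includes simulators (exact Bernoulli model and an equilibrium
    Poisson sampler over a distribution of fitness effects), decomposition
    of the fitness-effect distribution of "missing" variants, and a
    genome-wide accounting of expected strongly deleterious mutations per
    zygote.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
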