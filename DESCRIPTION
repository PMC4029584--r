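Package: haplocn
Title: Haplotype-Specific Copy Number Inference from SNP Array Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers copy-number variants and the haplotype each variant
    resides on from biallelic SNP-array allele intensity summaries. A hidden
    Markov model over six allelic states per haplotype (normal, gain, loss of
    either allele) is decoded per sample by the Viterbi algorithm. Transition
    probabilities come from a dynamically merged localized-haplotype-cluster
    tree estimated from cohort genotypes; emissions are eleven bivariate
    normal genotype-group models extended from the AA/AB/BB seed clusters.
    Outputs are CNV segments, phased copy-number haplotypes and fractional
    allele-specific copy numbers. Includes a synthetic diploid cohort
    simulator with known CNV haplotypes and a four-level accuracy evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
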