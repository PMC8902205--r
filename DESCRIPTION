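Package: haplotrait
Title: Candidate-Gene SNP Diversity, EM Haplotype Phasing, and Trait Association for Livestock Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete statistical pipeline for small candidate-gene SNP
    association studies in livestock: per-locus genotype and allele
    frequencies, Nei gene diversity, effective allele number, polymorphism
    information content, Hardy-Weinberg chi-square testing,
    expectation-maximization haplotype-frequency estimation from unphased
    diploid genotypes, pairwise linkage disequilibrium (D, D', r-squared),
    frequency-based haplotype filtering, maximum-posterior diplotype
    assignment, and fixed-effects linear-model association of genotype and
    diplotype classes with quantitative traits using least-squares means
    and Bonferroni-corrected pairwise comparisons. Includes a synthetic-herd
    generator that draws diplotypes from a configurable haplotype pool and
    simulates additive trait effects, so the whole pipeline is testable
    without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
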