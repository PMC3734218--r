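Package: bnassoc
Title: Frequentist and Bayesian-Network Relevance Analysis of Case-Control SNP Panels
Version: 0.1.0
Authors@R:
    person("bnassoc", "developers", email = "bnassoc@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of candidate-gene case-control SNP studies:
    genotype QC (call rate, monomorphism, Hardy-Weinberg equilibrium in
    controls), gender-adjusted logistic odds ratios under multiple genetic
    codings, Benjamini-Hochberg FDR, a Purcell-Sham style genetic power
    calculator, EM haplotype-frequency estimation with pairwise linkage
    disequilibrium and haplotype odds ratios, Kaplan-Meier survival by
    genotype with the Mantel-Cox logrank test, and a Bayesian-network
    multilevel relevance layer: BDeu-scored structure posteriors (exact
    enumeration or structure MCMC), Markov-blanket relevance posteriors
    (strong relevance, direct edge, pure interaction, association,
    transitive relevance), pairwise interaction/redundancy ratios, and
    structure-conditional Bayesian odds ratios summarised as highest
    posterior density segments with probability weights. Includes a
    synthetic-cohort generator emulating the statistical structure such
    studies assume (LD blocks with tagSNPs, planted direct and epistatic
    effects, disease subtypes, censored survival).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
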