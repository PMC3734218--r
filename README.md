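# bnassoc

Frequentist and Bayesian-network relevance analysis of case-control SNP
panels.

`bnassoc` is built for candidate-gene association studies of the classic
design: a few hundred cases and controls, tens of SNPs in a handful of
genes, a gender covariate, disease-subtype labels, and censored survival
for the cases. It runs the whole analysis twice, from two statistical
viewpoints:

1. **Frequentist**: SNP QC (call rate, monomorphism, control-group
   Hardy-Weinberg equilibrium), gender-adjusted logistic odds ratios
   under genotype / dominant / recessive / allelic codings,
   Benjamini-Hochberg FDR across each sweep, EM haplotype-frequency
   estimation with pairwise LD (D', r²) and haplotype odds ratios,
   Kaplan-Meier survival by genotype with the Mantel-Cox logrank test,
   and a Purcell-Sham style genetic power calculator.
2. **Bayesian-network multilevel relevance**: a posterior over dependency
   structures (DAGs) scored with the BDeu marginal likelihood — by exact
   enumeration on small panels, by structure MCMC on full panels — turned
   into per-variable posteriors of *strong relevance* (Markov-blanket
   membership), *direct edge*, *pure interaction* (spouse: effect only
   jointly through a common child), *association* and *transitive
   (mediated) relevance*; pairwise interaction/redundancy ratios; and
   structure-conditional Bayesian odds ratios summarised as 95% HPD
   segments with probability weights (disjoint when the posterior is
   multimodal).

For a target T and DAG posterior P(G | D), the central quantity is

    p_strong(X) = sum over G of  P(G | D) * 1[ X in MB_G(T) ]

with MB the Markov blanket (parents, children, children's other
parents), and the structure-conditional odds ratio of genotype g vs
reference 0

    OR_G(g) = odds(P_G(T = case | X = g)) / odds(P_G(T = case | X = 0)),

other blanket members marginalised over their empirical joint
distribution; the posterior over OR values across structure groups is
summarised by HPD segments carrying the groups' probability weights.

Because raw genotypes for studies of this design are typically not
deposited, the package ships a first-class synthetic-cohort generator
(`simulate_cohort()`) emulating their statistical structure — LD blocks
with tagSNPs, planted direct effects (ORs 1.4-2.0), margin-null
epistatic (spouse) motifs, subtype-specific effects, ~85% censored
survival — so every stage is testable end to end.

## Worked example

```r
library(bnassoc)

# a study-shaped synthetic cohort: 543 cases / 529 controls, 64 SNPs
co <- simulate_cohort(default_sim_spec(543, 529, seed = 3))
qc <- apply_qc(co)

# planted direct effect on snp08 (true OR_het 1.5, OR_hom 2.0)
genotype_logistic(qc$cohort, "snp08", coding = "genotype")
#>   snp_id subgroup   coding               contrast   or_hat   ci_low  ci_high           p n_used note
#> 1  snp08  overall genotype       het vs major hom 1.246381 0.960886 1.616706 0.08497518   1072
#> 2  snp08  overall genotype minor hom vs major hom 1.368595 0.851719 2.199130 0.19411437   1072

# worked 2x2 numbers: haplotype and allelic odds ratios from counts
or_2x2(543, 543, 442, 616)$or_hat            # 1.387  (allelic 50% vs 41.8%)
haplotype_case_control_or(248, 1086, 302, 1058)$or_hat   # 0.7405

# power of a recessive test, GRR 2, MAF 0.4, at the FDR-adjusted alpha
genetic_power(0.4, 2, "recessive", 390, 390, alpha = 1.21e-3,
              prevalence = 5e-4)             # 0.7532168

# Bayesian-network relevance on a small panel (exact enumeration over
# all DAGs; snp20 is the planted epistasis-mediating child SNP, snp25
# one of its spouse parents)
panel <- var_panel(qc$cohort, c("snp08", "snp20", "snp25"))
post  <- enumerate_posterior(panel)
relevance_posteriors(post)
#>   variable     p_strong       p_edge p_pure_interaction p_association  p_transitive
#> 1   gender 1.957816e-01 1.957816e-01       3.182703e-08   0.197982183  2.200551e-03
#> 2    snp08 3.470564e-03 3.470528e-03       3.628133e-08   0.004013262  5.426980e-04
#> 3    snp20 1.000000e+00 1.000000e+00       1.547622e-19   1.000000000  1.165734e-14
#> 4    snp25 1.174585e-05 8.715346e-08       1.165870e-05   1.000000000  9.999883e-01

# structure-conditional OR with HPD segments
orp <- structure_or_posterior(panel, post, "snp20", "hom")
hpd_segments(orp)
#>        low     high prob_weight
#> 1 3.064177 6.755257           1
```

Reading the relevance block: snp20 (the mediating child) is certainly
strongly relevant with a direct edge; snp25 is associated with certainty
but its association is entirely *transitive* (mediated through snp20) —
the pattern the multilevel taxonomy exists to surface; snp08's planted
direct effect (true OR_hom 2.0) is too weak at this particular seed to
dominate the structure posterior, matching its nominal-only frequentist
p above. All output is what the code printed at seed 3; the 2x2, power
and percent-censored values are reproduced exactly in
`tests/testthat/test-acceptance.R`.

The full pipeline (QC -> association + FDR -> haplotypes -> survival ->
BN relevance -> effect size), with per-stage TSV/JSON artifacts and a
deterministic manifest:

```r
run_pipeline(default_run_config("out_dir", seed = 1))
```

or from the shell via the bundled CLI:

```sh
Rscript -e 'bnassoc::bnassoc_cli()' run --seed 1 --out out_dir
```

## Layout

- `R/` — cohort container and I/O, QC, association statistics,
  haplotype EM/LD, survival, BDeu scoring + enumeration + structure
  MCMC, relevance taxonomy, Bayesian effect size, pipeline and CLI.
- `tests/testthat/` — unit, property and acceptance suites; all
  fixtures generated in code.
- `vignettes/bnassoc-methods.Rmd` — the model, parameter choices with
  defaults and rationale, what the synthetic generator does and does not
  emulate, numerical conventions, known limitations.
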