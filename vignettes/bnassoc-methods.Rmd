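---
title: "Methods: frequentist association and Bayesian-network relevance for case-control SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequentist association and Bayesian-network relevance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`bnassoc` analyses candidate-gene case-control SNP studies: a few hundred
cases and controls typed at tens of SNPs grouped into genes, with a
gender covariate, optional disease-subtype labels for the cases, and
optional censored survival. All stages consume one container,
`cohort_data`: a subject table, a SNP annotation table, and a genotype
matrix coded 0/1/2 as copies of the minor allele (`NA` = failed call).

Two conventions matter and are deliberate:

* **Genotype code 0 is the major homozygote** and is the reference
  category of every contrast (het-vs-ref, hom-vs-ref, carrier-vs-ref,
  hom-vs-carrier), matching the usual wild/carrier/mutant table layout.
* **The minor allele is defined among controls only**, with ties broken
  lexicographically. Defining it on the pooled sample would let strong
  case enrichment flip the coding of a SNP between analyses.

Missing data are handled complete-case per statistic: each analysis
drops exactly the subjects missing a variable it uses. No imputation.

## Quality control

`apply_qc()` removes SNPs failing (i) call rate below 0.90, (ii)
monomorphism, (iii) Hardy-Weinberg equilibrium **among controls** at the
chi-square goodness-of-fit test (`hwe_chisq`, 1 df; default alpha 0.05).
HWE is tested in controls only: testing in cases (or pooled) would let a
true association masquerade as a typing failure. A monomorphic SNP is
reported as monomorphic, not as an HWE failure — the test is undefined
there.

# Frequentist stage

Per SNP and coding, `genotype_logistic()` fits a maximum-likelihood
logistic regression of status on the coded genotype plus gender, and
reports OR = exp(beta) with Wald 95% CIs and Wald p-values (the CI/p
pairs printed by the standard software this mirrors are Wald).
The allelic coding instead uses the 2N-chromosome 2x2 table through
`or_2x2()` (OR = ad/bc, Woolf CI, log-OR z test, Haldane +0.5 correction
flagged when a cell is empty) because alleles, not subjects, are the
sampling units there. Subgroup analyses keep all controls and the named
case subtype.

`bh_fdr()` is the Benjamini-Hochberg step-up rule; the family is one
(subgroup x coding) sweep across SNPs and the family size `m` is recorded
in the result, since a printed threshold is only interpretable together
with its family.

## Genetic power calculator

`genetic_power()` re-implements the Purcell-Sham construction: expected
case and control genotype frequencies under HWE at the risk-allele
frequency, penetrances scaled to a stated prevalence, and power equal to
the noncentral-chi-square tail of the coded contingency test, with the
noncentrality parameter set to the Pearson statistic of the expected
table. Dominant/recessive collapse to 1 df; the genotype test keeps 2 df;
allelic/additive use the 2N allele table.

**Documented reference configuration.** The worked example this package
reproduces — MAF 0.4, recessive genotype relative risk 2, B-cell-ALL-sized
sample, alpha 1.21e-3, power 0.75 — is obtained with the recessive 1-df
collapse, 390 cases, **390 controls** (the calculator's web-form default
control:case ratio of 1), and rare-disease prevalence 5e-4:

```{r}
genetic_power(0.4, 2, "recessive", 390, 390, alpha = 1.21e-3,
              prevalence = 5e-4)   # 0.7532
```

Using the study's actual 529 controls gives 0.85 under the same test and
0.77 under the 2-df genotype test; no configuration with 529 controls
yields 0.75. Prevalence matters only in the third decimal below 1e-2.

# Survival stage

`km_curve()` is the product-limit estimator with Greenwood standard
errors; ties follow the standard convention that deaths precede
censorings at equal times (the data source is silent on ties). The
"percent" column of the case-processing summary is the **censored
fraction** (censored/total) — verified against the printed worked values
(269/303 = 88.8%, 437/511 = 85.5%) — and is reported alongside the
restricted mean survival (area under S(t) to the largest observed time),
which differs from it in general. `logrank()` is the Mantel-Cox
observed-minus-expected statistic with hypergeometric variance, df =
groups - 1. The `survival` package is used in the test suite as an
independent oracle only; the estimators here are the package's own.

# Bayesian-network relevance stage

## Scoring and structure posteriors

Variables are discrete (status 2, gender 2, SNPs 3 levels). Families are
scored with the BDeu marginal likelihood (Dirichlet hyperparameters
`ess/(q r)`); the network score is decomposable, and Markov-equivalent
structures score equally (property-tested). Defaults: `ess = 1` (the
prior strength is not dictated by anything in the problem; 1 is the
common weakly-informative choice), uniform prior over DAGs under a
fan-in cap of 4 (needed for tractability on 64-SNP panels).

Two posterior engines share one output type:

* `enumerate_posterior()` — exact enumeration of all DAGs (vectorised
  acyclicity elimination over the candidate parent-set product), for
  panels of up to ~5 variables. It is the oracle everything else is
  validated against.
* `mcmc_posterior()` — structure MCMC with add/delete/reverse-edge
  Metropolis-Hastings proposals (the add/delete proposal asymmetry is
  Hastings-corrected), memoised family rescoring, multiple chains pooled
  by visit frequency, and a between-chain total-variation check on
  blanket-membership posteriors that attaches a non-mixing warning.
  Structure MCMC was chosen over order MCMC for simplicity; correctness
  is anchored by the enumeration oracle, not by the sampler.

Gender is always a panel variable — it competes with the SNPs for
relevance rather than being conditioned away at this stage.

## Relevance taxonomy

For a structure posterior and target T, `relevance_posteriors()` reports
per variable: strong relevance (Markov-blanket membership), direct edge
(adjacency), pure interaction (blanket membership without adjacency — a
spouse, carrying effect only jointly through a common child), association,
and transitive relevance (association minus strong relevance — mediated
dependence). **Association** is operationalised as marginal d-connection
(the common-ancestor criterion) *union* blanket membership: a pure spouse
is d-separated from T given the empty set, yet the taxonomy treats every
strongly relevant variable as associated, so the transitive remainder
stays nonnegative. This union is what makes mediated SNPs show
association ~ transitive ~ high with strong relevance ~ 0, the pattern
the method is designed to surface.

`pair_ratio()` implements interaction/redundancy with a single statistic:
P(both in blanket) / (P(a in blanket) P(b in blanket)); above 1 + tau is
labelled interaction, below 1 - tau redundancy (tau = 0.05). No separate
formulas exist in the source material for the two labels; one ratio with
a neutrality band is the natural reading.

## Structure-conditional odds ratios

`structure_or_posterior()` computes, per structure group (structures
sharing the target's family and its children's families), the target's
conditional case probability from the group's Bayesian-network
parameters, marginalising the other blanket members over their empirical
joint distribution (a standardised OR — the conditioning convention is
not dictated by the source and is documented here as a choice), and forms
the OR of the het- or hom-contrast against the major-homozygote
reference. Structures that exclude the SNP from the blanket contribute
OR = 1 exactly.

Within a group, the OR distribution is obtained by **sampling the family
parameters from their Dirichlet posteriors** (default 200 seeded draws).
A pure posterior-mean version (`n_param_samples = 0`) is available, but a
point-valued per-group OR would make every credible segment zero-width:
coverage of a planted OR would be impossible and the printed-style
intervals (e.g. 1.44-1.53 at 100% weight) have parameter-level width.
Multimodality remains attributable to structure groups alone.

`hpd_segments()` merges structure groups whose posterior-mean ORs
coincide within 0.01 on the log scale, drops groups below 2% mass, and
summarises each remaining group by the shortest interval containing 95%
of its own mass, weighted by the group's share — so a multimodal OR
posterior yields disjoint segments with probability weights, and a
concentrated one yields a single interval whose coverage of a planted OR
is ~95% (verified at n = 2000/2000 over 100 seeds).

`joint_effect()` keeps posterior-**mean** parametric averaging (as the
joint-effect tables it mirrors state) and reports dominant-coded 2x2
model-averaged case probabilities and joint ORs against the
double-reference cell, which is exactly 1.

# Synthetic cohorts: what they emulate and what they do not

No genotype data for the motivating study are deposited, so every
downstream stage is exercised on `simulate_cohort()` output. The stated
world of the bundled emulation (`default_sim_spec()`):

* 543 cases / 529 controls, 64 polymorphic SNPs in 15 genes; gender
  57/43 in both groups.
* One 7-SNP LD block with a tagSNP structure (haplotypes 0000000/0.70,
  1111111/0.25, 0000011/0.05 — one SNP's minor allele tags the other
  six), one 4-SNP block with four common haplotypes.
* Planted direct effects with genotype ORs in the 1.4-2.0 range
  (logistic disease model; the intercept is a nuisance under
  outcome-stratified rejection sampling and defaults to 0).
* Case subtypes B/T/HD at 0.711/0.144/0.145 with a subtype-specific
  effect (ORs 1.6/2.4) visible only in the smallest (HD-like) subgroup.
* One pure-interaction (spouse) motif, below.
* Exponential survival with genotype hazard ratio 2 for carriers of one
  SNP, uniform 2-20y administrative censoring, baseline hazard solved by
  `calibrate_baseline_hazard()` for ~85-87% censoring.

**Pure interaction is planted as a collider motif, not a penetrance
term.** A margin-null 3x3 penetrance table on the disease odds (also
provided, `make_pure_interaction_table()`, with *exactly* constant
margins by the additive centred-dosage construction) makes both SNPs
*parents* of the target — direct edges, the opposite of pure interaction
in the blanket taxonomy. The motif the taxonomy calls pure interaction
requires a common *child*: `spouse_motifs` redraws a child SNP
conditionally on case status and the spouse genotypes, with an LD-like
main dependence on each spouse (`ld = 1`), a direct case-control
component (`direct = 0.5`, making the child itself an edge variable, as
in the motivating finding), and an interaction term (`strength = 3` on
the odds of the extreme cell). The spouses' joint distribution with the
target is untouched, so they are *exactly* marginally independent of
status — their relevance can only be pure-interactional.

Magnitudes were chosen once, before any acceptance measurement, to match
the reported effect sizes of the motivating study (detected direct ORs
~1.9-2.0; a strongly relevant mediating SNP; interaction posteriors of
~0.7 at ~600-1100 subjects) and were not revisited.

What a green test does **not** establish: the generator has no
population stratification, no genotyping-batch structure, no
recombination map (blocks are drawn as independent haplotype pairs), no
ascertainment model, and subtype weights multiply rather than define
distinct aetiologies. Posteriors on real cohorts will be less clean.

## Known limitations worth stating

* **Pure-interaction posteriors are conservative.** A collider family
  over 3-level genotypes pays a steep BDeu dimensionality price (a
  3-parent child family has 36 free parameters), so the posterior often
  retains only one spouse at a time at n ~ 1000 even when both
  dependencies are individually strong; the members are still never
  mistaken for direct edges. This mirrors the motivating study's own
  remark that larger samples are needed to characterise interactions.
* Weak margin-null epistasis (penetrance-table strength 1.5) is jointly
  *testable* by a 9-cell chi-square at n = 2000 but sits below the BDeu
  Occam penalty at n = 5000; the planted-epistasis recovery tests
  therefore use strength 2.5.
* The MCMC sampler is serial R; 64-variable full panels mix slowly. The
  pipeline's bundled configuration preselects the top-12 SNPs by marginal
  chi-square before the BN stage and uses reduced chain settings so the
  end-to-end run is minutes, not hours; `snp_preselect = 0` restores the
  full panel.
* Enumeration is limited to ~5 variables by the candidate product; the
  size error directs callers to MCMC.

# Numerical and degenerate-input choices

* Logistic separation/non-convergence is flagged (`note =
  "separation"`), never fatal; empty genotype cells mark the contrast
  inestimable.
* EM haplotype frequencies: product-of-allele-frequency start, optional
  seeded Dirichlet restarts, convergence on log-likelihood gain < 1e-8,
  monotonicity asserted every iteration; k <= 6 keeps the haplotype space
  exhaustive. Printed-style integer haplotype counts are EM-expected
  counts rounded, with the fractional counts reported alongside.
* LD: D' = |D|/Dmax with the frequency-dependent bound; monomorphic
  input is an error, not a zero.
* `or_2x2` applies Haldane +0.5 on any zero cell and flags it.
* OR posteriors over exact-enumeration structure posteriors evaluate
  only the structure groups jointly covering 99.9% of the in-blanket
  mass (the long tail of sub-0.1% groups can never reach a reporting
  floor); atom weights are renormalised, so the distortion is bounded
  by 0.001.
* All seeded code paths restore the caller's RNG state
  (`.rng_local`), so library calls do not perturb user simulations;
  derived seeds stay below 2^31.
* Pipeline artifacts contain no wall-clock content (timings go to
  `run.log`), so two identically-seeded runs are byte-identical.
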