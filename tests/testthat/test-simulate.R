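test_that("unlinked SNPs follow HWE at the stated MAF (large-n law check)", {
  snps <- data.frame(snp_id = "s1", gene = NA, maf = 0.4)
  spec <- sim_spec(50000, 50000, snps, seed = 1)
  co <- simulate_cohort(spec)
  g <- co$genotypes[, 1]
  expect_equal(mean(g) / 2, 0.4, tolerance = 0.005 / 0.4)
  freqs <- tabulate(g + 1L, 3) / length(g)
  expect_true(all(abs(freqs - c(0.36, 0.48, 0.16)) < 0.005))
})

test_that("the null model carries no case-control signal", {
  snps <- data.frame(snp_id = c("s1", "s2"), gene = NA, maf = c(0.3, 0.2))
  hits <- vapply(1:12, function(s) {
    co <- simulate_cohort(sim_spec(400, 400, snps, seed = s))
    r <- genotype_logistic(co, "s1", "dominant")
    r$ci_low <= 1 && 1 <= r$ci_high
  }, TRUE)
  expect_gte(mean(hits), 0.75)   # 95% CI covers OR = 1
})

test_that("a planted OR_hom of 2 is recovered inside its own CI (coverage)", {
  cover <- vapply(1:100, function(s) {
    co <- planted_cohort(s)
    r <- genotype_logistic(co, "s1", "genotype")
    r$ci_low[2] <= 2 && 2 <= r$ci_high[2]
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("identical specs give bit-identical cohorts", {
  spec <- default_sim_spec(80, 80, seed = 9)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
})

test_that("simulation specs survive the JSON round trip", {
  spec <- default_sim_spec(60, 60, seed = 4)
  spec$effects$interaction_pairs <- list(
    list(a = "snp30", b = "snp35",
         table = make_pure_interaction_table(2, 0.3, 0.3, 0.4)))
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_spec(spec, f)
  back <- read_sim_spec(f)
  expect_identical(simulate_cohort(back)$genotypes,
                   simulate_cohort(spec)$genotypes)
})

test_that("pure-interaction penetrance tables have exactly constant margins", {
  for (maf in c(0.2, 0.35, 0.5)) {
    tab <- make_pure_interaction_table(2, maf_a = maf, maf_b = 0.3, p0 = 0.4)
    ga <- dbinom(0:2, 2, maf); gb <- dbinom(0:2, 2, 0.3)
    expect_equal(as.vector(tab %*% gb), rep(0.4, 3), tolerance = 1e-12)
    expect_equal(as.vector(t(tab) %*% ga), rep(0.4, 3), tolerance = 1e-12)
  }
  # strength -> 1 limit: uniform table
  tab1 <- make_pure_interaction_table(1 + 1e-9, 0.5, 0.5)
  expect_equal(max(abs(tab1 - 0.5)), 0, tolerance = 1e-8)
  # infeasible strength
  expect_error(make_pure_interaction_table(50, 0.5, 0.5, p0 = 0.2),
               "parameter error")
  expect_error(make_pure_interaction_table(0.8), "strength")
})

test_that("the planted pair is jointly detectable at n = 2000 while margins stay flat", {
  # analytic margins are exact; joint 9-cell association power by Monte Carlo
  tab <- make_pure_interaction_table(1.5, 0.5, 0.5, p0 = 0.5)
  reps <- 300
  hits <- 0; marg_hits <- 0
  set.seed(77)
  for (r in seq_len(reps)) {
    a <- rbinom(2000, 2, 0.5); b <- rbinom(2000, 2, 0.5)
    y <- rbinom(2000, 1, tab[cbind(a + 1, b + 1)])
    joint <- interaction(a, b)
    p_joint <- suppressWarnings(chisq.test(table(joint, y))$p.value)
    p_marg <- suppressWarnings(chisq.test(table(a, y))$p.value)
    hits <- hits + (p_joint < 0.05)
    marg_hits <- marg_hits + (p_marg < 0.05)
  }
  expect_gt(hits / reps, 0.8)          # joint association is powered
  expect_lt(marg_hits / reps, 0.12)    # margins behave like the null
})

test_that("simulated survival hits the target censoring and hazard ordering", {
  snps <- data.frame(snp_id = "s1", gene = NA, maf = 0.3)
  sv <- list(snp_id = "s1", hazard_mult = c(1, 1, 1),
             baseline_hazard = calibrate_baseline_hazard(0.85),
             follow_up = c(2, 20))
  cens <- vapply(1:10, function(s) {
    spec <- sim_spec(511, 50, snps,
                     effects = sim_effects(survival = sv), seed = s)
    co <- simulate_cohort(spec)
    ev <- co$subjects$surv_event[co$subjects$status == "case"]
    mean(!ev)
  }, 0)
  expect_lt(abs(mean(cens) - 0.85), 0.03)

  # equal hazards: logrank null distribution (mean approximately df = 2)
  chi <- vapply(1:200, function(s) {
    spec <- sim_spec(300, 10, snps,
                     effects = sim_effects(survival = sv), seed = s)
    co <- simulate_cohort(spec)
    cases <- co$subjects$status == "case"
    g <- co$genotypes[cases, 1]
    lr <- logrank(co$subjects$surv_time[cases],
                  co$subjects$surv_event[cases], g)
    lr$chi2 / lr$df
  }, 0)
  expect_equal(mean(chi, na.rm = TRUE), 1, tolerance = 0.2)

  # hazard ratio 2 for carriers: curves stochastically ordered
  sv2 <- list(snp_id = "s1", hazard_mult = c(1, 2, 2),
              baseline_hazard = calibrate_baseline_hazard(0.8),
              follow_up = c(2, 20))
  ordered <- vapply(1:40, function(s) {
    spec <- sim_spec(500, 10, snps,
                     effects = sim_effects(survival = sv2), seed = s)
    co <- simulate_cohort(spec)
    cv <- km_by_genotype(co, "s1", "dominant")
    cv$carrier$rmean < cv$wild$rmean
  }, TRUE)
  expect_gte(mean(ordered), 0.95)
})
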