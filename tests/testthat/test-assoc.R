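test_that("HWE chi-square matches exact proportions and a hand oracle", {
  expect_equal(hwe_chisq(250, 500, 250)$chi2, 0)
  expect_equal(hwe_chisq(250, 500, 250)$p, 1)
  expect_equal(hwe_chisq(360, 480, 160)$chi2, 0, tolerance = 1e-12)
  # hand oracle: counts (300, 200, 100), p-hat = (2*100+200)/1200
  ph <- (2 * 100 + 200) / 1200
  e <- 600 * c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
  chi_oracle <- sum((c(300, 200, 100) - e)^2 / e)
  expect_equal(hwe_chisq(300, 200, 100)$chi2, chi_oracle)
  # monomorphic input is undefined, not an HWE failure
  expect_true(is.na(hwe_chisq(100, 0, 0)$p))
})

test_that("2x2 odds ratios reproduce printed worked examples", {
  # allele-level: 50% vs 41.8% of 2N chromosomes -> OR 1.39
  o <- or_2x2(543, 543, 442, 616)
  expect_equal(round(o$or_hat, 2), 1.39)
  expect_equal(round(o$ci_low, 2), 1.18)
  expect_equal(round(o$ci_high, 2), 1.65)
  # haplotype rows: 248/1086 vs 302/1058 -> 0.74; 181 vs 134 -> 1.38
  expect_equal(round(or_2x2(248, 838, 302, 756)$or_hat, 2), 0.74)
  expect_equal(round(or_2x2(181, 905, 134, 924)$or_hat, 2), 1.38)
  # no association
  expect_equal(or_2x2(30, 60, 10, 20)$or_hat, 1)
  expect_error(or_2x2(-1, 2, 3, 4), "negative")
  expect_true(or_2x2(0, 5, 5, 5)$haldane)
})

test_that("or_2x2 symmetry invariances hold for random tables", {
  set.seed(1)
  for (i in 1:50) {
    x <- rpois(4, 40) + 1
    a <- or_2x2(x[1], x[2], x[3], x[4])
    swapped <- or_2x2(x[3], x[4], x[1], x[2])     # swap rows AND columns
    expect_equal(or_2x2(x[4], x[3], x[2], x[1])$or_hat, a$or_hat)
    expect_equal(swapped$or_hat, 1 / a$or_hat, tolerance = 1e-12)
  }
})

test_that("gender adjustment is null when gender is independent of the SNP", {
  co <- planted_cohort(3)
  adj <- genotype_logistic(co, "s1", "dominant", adjust_gender = TRUE)
  g <- co$genotypes[, 1]
  y <- co$subjects$status == "case"
  crude <- or_2x2(sum(y & g >= 1), sum(y & g == 0),
                  sum(!y & g >= 1), sum(!y & g == 0))
  expect_equal(adj$or_hat, crude$or_hat, tolerance = 0.01)
})

test_that("null logistic p-values are uniform (KS over 500 replicates)", {
  set.seed(11)
  ps <- vapply(1:500, function(i) {
    g <- rbinom(600, 2, 0.3)
    y <- rbinom(600, 1, 0.5)
    sex <- sample(c("male", "female"), 600, TRUE)
    co <- toy_cohort(matrix(g, ncol = 1),
                     status = ifelse(y == 1, "case", "control"),
                     gender = sex)
    genotype_logistic(co, "snp1", "dominant")$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a planted log-OR of log 2 is recovered without bias", {
  lo <- vapply(1:200, function(s)
    log(genotype_logistic(planted_cohort(s), "s1", "genotype")$or_hat[2]), 0)
  expect_lt(abs(mean(lo) - log(2)), 0.05)
})

test_that("BH-FDR equals the brute-force scan and handles edge cases", {
  brute <- function(p, q) {
    m <- length(p); ps <- sort(p)
    thr <- 0
    for (k in seq_len(m)) if (ps[k] <= k / m * q) thr <- ps[k]
    thr
  }
  r <- bh_fdr(c(a = 0.001, b = 0.01, c = 0.02, d = 0.9), 0.05)
  expect_equal(r$threshold, brute(c(0.001, 0.01, 0.02, 0.9), 0.05))
  expect_setequal(r$significant, c("a", "b", "c"))

  expect_equal(bh_fdr(rep(0.5, 10), 0.05)$significant, character(0))
  expect_equal(bh_fdr(c(t1 = 0.03), 0.05)$significant, "t1")
  expect_error(bh_fdr(numeric(0)), "empty")

  set.seed(5)
  for (i in 1:1000) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    r <- bh_fdr(p, q)
    expect_equal(r$threshold, brute(p, q))
    expect_true(all(p[names(p) %in% r$significant] <= r$threshold))
  }
})

test_that("the power calculator reproduces its stated configuration", {
  # grr = 1: noncentrality vanishes, power = alpha
  expect_equal(genetic_power(0.3, 1, "recessive", 500, 500, 0.05), 0.05,
               tolerance = 1e-9)
  # enormous samples: power -> 1
  expect_gt(genetic_power(0.4, 2, "recessive", 1e6, 1e6, 1e-3), 0.9999)
  # documented configuration: recessive 1-df collapse, 390 cases with the
  # calculator's default 1:1 control:case ratio, rare prevalence -> 0.75
  expect_equal(round(genetic_power(0.4, 2, "recessive", 390, 390,
                                   1.21e-3, 5e-4), 2), 0.75)
  # monotone in n, grr and alpha
  p1 <- genetic_power(0.3, 1.5, "dominant", 300, 300, 1e-3)
  expect_gte(genetic_power(0.3, 1.5, "dominant", 600, 600, 1e-3), p1)
  expect_gte(genetic_power(0.3, 2.0, "dominant", 300, 300, 1e-3), p1)
  expect_gte(genetic_power(0.3, 1.5, "dominant", 300, 300, 1e-2), p1)
  expect_error(genetic_power(0.3, 3, "recessive", 10, 10, 0.05,
                             prevalence = 0.5), "penetrance")
})

test_that("assoc_sweep stacks per-SNP rows and flags failures", {
  co <- simulate_cohort(default_sim_spec(120, 120, seed = 4))
  res <- assoc_sweep(co, "dominant")
  expect_equal(nrow(res), nrow(co$snps))
  expect_true(all(res$ci_low <= res$or_hat & res$or_hat <= res$ci_high,
                  na.rm = TRUE))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
})
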