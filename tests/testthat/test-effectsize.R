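bit <- function(v) bitwShiftL(1L, v - 1L)

test_that("no-dependency posteriors give a point mass at OR = 1", {
  co <- planted_cohort(1, n_case = 100, n_ctrl = 100, or_het = 1, or_hom = 1)
  panel <- var_panel(co, include_gender = FALSE)
  empty <- manual_posterior(matrix(c(0L, 0L), 1), 1, panel$vars)
  orp <- structure_or_posterior(panel, empty, "s1", "hom")
  expect_equal(orp$values$or, 1)
  expect_equal(orp$values$weight, 1)
  seg <- hpd_segments(orp)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$low, seg$high, seg$prob_weight), c(1, 1, 1))
})

test_that("a concentrated structure posterior recovers the planted OR", {
  co <- planted_cohort(2, n_case = 2500, n_ctrl = 2500)
  panel <- var_panel(co, include_gender = FALSE)
  single <- manual_posterior(matrix(c(bit(2), 0L), 1), 1, panel$vars)
  orp <- structure_or_posterior(panel, single, "s1", "hom", seed = 2)
  # posterior mode (group mean) within 10 percent of 2.0
  mode_or <- orp$values$group_or[which.max(orp$values$weight)]
  expect_lt(abs(log(mode_or) - log(2)), log(1.1) + 0.08)
  # collapses onto the classical logistic estimate (CI overlap)
  fit <- genotype_logistic(co, "s1", "genotype", adjust_gender = FALSE)
  seg <- hpd_segments(orp)
  expect_lt(seg$low[1], fit$ci_high[2])
  expect_gt(seg$high[1], fit$ci_low[2])
  # total HPD mass matches the level under the weighted atoms
  inside <- orp$values$or >= seg$low[1] & orp$values$or <= seg$high[1]
  expect_equal(sum(orp$values$weight[inside]), 0.95, tolerance = 0.015)
})

test_that("structure-group mass splits drive multimodal OR posteriors", {
  co <- planted_cohort(3, n_case = 1200, n_ctrl = 1200)
  panel <- var_panel(co, include_gender = FALSE)
  # 0.75 mass excludes the SNP from the blanket, 0.25 includes it
  two <- manual_posterior(rbind(c(0L, 0L), c(bit(2), 0L)),
                          c(0.75, 0.25), panel$vars)
  orp <- structure_or_posterior(panel, two, "s1", "hom", seed = 5)
  seg <- hpd_segments(orp)
  expect_equal(nrow(seg), 2)
  w1 <- seg$prob_weight[seg$low == 1]
  expect_equal(w1, 0.75, tolerance = 0.02)
  expect_equal(seg$prob_weight[seg$low > 1], 0.25, tolerance = 0.02)
})

test_that("constructed two-component mixtures recover their probability weights", {
  orp <- structure(list(snp_id = "x", contrast = "hom",
                        values = data.frame(
                          or = c(1, 0.44, 0.45, 0.46),
                          weight = c(0.84, 0.05, 0.06, 0.05),
                          group_or = c(1, 0.45, 0.45, 0.45)),
                        target = "t"),
                   class = "or_posterior")
  seg <- hpd_segments(orp)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$prob_weight[seg$low < 1], 0.16, tolerance = 0.02)
  expect_equal(seg$prob_weight[seg$low == 1], 0.84, tolerance = 0.02)
})

test_that("joint effects recover planted epistasis under a forced structure", {
  tab <- make_pure_interaction_table(2.5, 0.4, 0.4, p0 = 0.5)
  snps <- data.frame(snp_id = c("sA", "sB"), gene = NA, maf = c(0.4, 0.4))
  spec <- sim_spec(2500, 2500, snps,
                   effects = sim_effects(interaction_pairs = list(
                     list(a = "sA", b = "sB", table = tab))), seed = 2)
  co <- simulate_cohort(spec)
  panel <- var_panel(co, include_gender = FALSE)
  post <- enumerate_posterior(panel)
  # the pair is detected as joint parents of the target
  expect_gt(sum(post$weight[post$parents[, 1] == bit(2) + bit(3)]), 0.9)
  je <- joint_effect(panel, post, "sA", "sB")
  expect_equal(je$joint_or[1, 1], 1)           # reference cell exactly 1
  expect_true(all(je$p_case > 0 & je$p_case < 1))
  # interacting cells depart from 1 while the single-SNP margins are null
  expect_gt(max(abs(log(je$joint_or))), log(1.3))
  mA <- genotype_logistic(co, "sA", "dominant", adjust_gender = FALSE)
  expect_lt(abs(log(mA$or_hat)), log(1.15))
})

test_that("multiplicative direct effects give multiplicative joint ORs", {
  snps <- data.frame(snp_id = c("sA", "sB"), gene = NA, maf = c(0.3, 0.3))
  spec <- sim_spec(2500, 2500, snps,
                   effects = sim_effects(direct = list(sA = c(1.5, 2.25),
                                                       sB = c(1.6, 2.56))),
                   seed = 4)
  co <- simulate_cohort(spec)
  panel <- var_panel(co, include_gender = FALSE)
  post <- enumerate_posterior(panel)
  je <- joint_effect(panel, post, "sA", "sB")
  prod_marg <- je$joint_or[2, 1] * je$joint_or[1, 2]
  expect_equal(log(je$joint_or[2, 2]), log(prod_marg),
               tolerance = log(1.1) / log(2))
  # null panel: all joint ORs near 1
  spec0 <- sim_spec(1500, 1500, snps, seed = 5)
  co0 <- simulate_cohort(spec0)
  panel0 <- var_panel(co0, include_gender = FALSE)
  je0 <- joint_effect(panel0, enumerate_posterior(panel0), "sA", "sB")
  expect_lt(max(abs(log(je0$joint_or))), log(1.2))
})
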