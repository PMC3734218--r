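bit <- function(v) bitwShiftL(1L, v - 1L)

test_that("markov_blanket reproduces textbook cases", {
  # X -> T, T -> Y, Z -> Y over (T, X, Y, Z): MB(T) = {X, Y, Z}
  parents <- c(bit(2), 0L, bit(1) + bit(4), 0L)
  expect_equal(markov_blanket(parents, 1), c(2, 3, 4))
  # empty graph
  expect_equal(markov_blanket(rep(0L, 4), 1), integer(0))
  # X -> M -> T: mediated, MB(T) = {M}
  parents2 <- c(bit(3), 0L, bit(2), 0L)
  expect_equal(markov_blanket(parents2, 1), 3)
})

test_that("single-structure posteriors classify relevance types exactly", {
  vars <- c("target", "X", "C")
  # X -> T
  p1 <- manual_posterior(matrix(c(bit(2), 0L, 0L), 1), 1, vars)
  r1 <- relevance_posteriors(p1)
  x <- r1[r1$variable == "X", ]
  expect_equal(unlist(x[, -1]), c(p_strong = 1, p_edge = 1,
                                  p_pure_interaction = 0,
                                  p_association = 1, p_transitive = 0))
  # spouse: X -> C <- T
  p2 <- manual_posterior(matrix(c(0L, 0L, bit(1) + bit(2)), 1), 1, vars)
  r2 <- relevance_posteriors(p2)
  x2 <- r2[r2$variable == "X", ]
  expect_equal(unlist(x2[, -1]), c(p_strong = 1, p_edge = 0,
                                   p_pure_interaction = 1,
                                   p_association = 1, p_transitive = 0))
  # mediation: X -> M -> T (vars target, X, M)
  p3 <- manual_posterior(matrix(c(bit(3), 0L, bit(2)), 1), 1,
                         c("target", "X", "M"))
  r3 <- relevance_posteriors(p3)
  expect_equal(r3$p_strong[r3$variable == "X"], 0)
  expect_equal(r3$p_association[r3$variable == "X"], 1)
  expect_equal(r3$p_transitive[r3$variable == "X"], 1)
  expect_equal(r3$p_strong[r3$variable == "M"], 1)
})

test_that("relevance report satisfies its ordering invariants on real posteriors", {
  co <- planted_cohort(19, extra_null = 2)
  post <- enumerate_posterior(var_panel(co))
  rel <- relevance_posteriors(post)
  expect_true(all(rel$p_edge <= rel$p_strong + 1e-12))
  expect_true(all(rel$p_strong <= rel$p_association + 1e-12))
  expect_true(all(rel$p_association <= 1 + 1e-12))
  expect_equal(rel$p_transitive,
               pmax(0, rel$p_association - rel$p_strong), tolerance = 1e-12)
  expect_true(all(abs(rel$p_strong -
                        (rel$p_edge + rel$p_pure_interaction)) < 1e-9))
})

test_that("vectorised classification equals a per-DAG oracle on enumerated panels", {
  co <- planted_cohort(23, n_case = 200, n_ctrl = 200, extra_null = 1)
  panel <- var_panel(co)   # 4 variables
  post <- enumerate_posterior(panel)
  rel <- relevance_posteriors(post)
  V <- length(post$vars)
  acc <- matrix(0, nrow = V, ncol = 3)
  for (i in seq_len(nrow(post$parents))) {
    o <- oracle_classify(post$parents[i, ], 1L)
    acc[o$mb, 1] <- acc[o$mb, 1] + post$weight[i]
    acc[o$adj, 2] <- acc[o$adj, 2] + post$weight[i]
    acc[o$dcon, 3] <- acc[o$dcon, 3] + post$weight[i]
  }
  expect_equal(rel$p_strong, acc[-1, 1], tolerance = 1e-12)
  expect_equal(rel$p_edge, acc[-1, 2], tolerance = 1e-12)
  expect_equal(rel$p_association, acc[-1, 3], tolerance = 1e-12)
})

test_that("pair ratios label interaction, redundancy and independence", {
  vars <- c("target", "a", "b")
  # independent membership: a in MB of half the mass, b in the other axis
  P <- rbind(c(bit(2) + bit(3), 0L, 0L),  # both
             c(bit(2), 0L, 0L),           # a only
             c(bit(3), 0L, 0L),           # b only
             c(0L, 0L, 0L))               # neither
  p_ind <- manual_posterior(P, c(0.25, 0.25, 0.25, 0.25), vars)
  pr <- pair_ratio(p_ind, "a", "b")
  expect_equal(pr$ratio, 1)
  expect_equal(pr$label, "neutral")

  # perfect interchangeability: joint never occurs
  p_red <- manual_posterior(P[2:3, ], c(0.5, 0.5), vars)
  pr2 <- pair_ratio(p_red, "a", "b")
  expect_equal(pr2$p_joint, 0)
  expect_equal(pr2$ratio, 0)
  expect_equal(pr2$label, "redundancy")

  # constructed interaction: p_a = p_b = 0.5, p_joint = 0.4 -> ratio 1.6
  p_int <- manual_posterior(P, c(0.4, 0.1, 0.1, 0.4), vars)
  pr3 <- pair_ratio(p_int, "a", "b")
  expect_equal(pr3$ratio, 1.6)
  expect_equal(pr3$label, "interaction")

  expect_error(pair_ratio(manual_posterior(P[4, , drop = FALSE], 1, vars),
                          "a", "b"), "undefined ratio")
})

test_that("interaction maps restrict to strongly relevant nodes", {
  vars <- c("target", "X", "C")
  P <- matrix(c(0L, 0L, bit(1) + bit(2)), 1)
  post <- manual_posterior(P, 1, vars)
  map <- interaction_map(post, min_strong = 0.5)
  expect_setequal(map$nodes$name, c("target", "X", "C"))
  expect_true(all(c("X", "target") %in% map$edges$from))
  expect_equal(map$edges$weight, c(1, 1))
  # boundary: threshold above every posterior keeps only the target
  map2 <- interaction_map(post, min_strong = 1.1)
  expect_equal(map2$nodes$name, "target")
  expect_equal(nrow(map2$edges), 0)
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(map, f)
  expect_true(any(grepl("->", readLines(f))))
})

test_that("planted spouse motifs surface as the child-mediated map motif", {
  snps <- data.frame(snp_id = c("sA", "sB", "sC"), gene = NA, maf = 0.3)
  found <- vapply(1:10, function(s) {
    spec <- sim_spec(543, 529, snps,
                     effects = sim_effects(spouse_motifs = list(
                       list(child = "sC", parents = c("sA", "sB"),
                            strength = 3))), seed = s)
    co <- simulate_cohort(spec)
    post <- enumerate_posterior(var_panel(co, include_gender = FALSE))
    map <- interaction_map(post, min_strong = 0.5)
    # the child is strongly relevant and linked with the target
    "sC" %in% map$nodes$name &&
      any((map$edges$from == "sC" & map$edges$to == "target") |
            (map$edges$from == "target" & map$edges$to == "sC"))
  }, TRUE)
  expect_gte(mean(found), 0.9)
})
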