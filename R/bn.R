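#' Discrete variable panel for Bayesian-network analysis
#'
#' Extracts the complete-case discrete matrix over the target
#' (case/control status), gender and a set of SNPs. Values are 1-based
#' levels (status: 1 = control, 2 = case; gender: 1 = female, 2 = male;
#' SNPs: genotype code + 1).
#'
#' @param cohort a [cohort_data] object.
#' @param snp_ids SNPs to include (default: all).
#' @param subgroup case subgroup, see [subgroup_cohort()].
#' @param include_gender include gender as a competing variable.
#' @return object of class `var_panel`: list with `data` (n x V integer
#'   matrix), `card` (cardinalities), `vars` (names), `target` (index,
#'   always 1).
#' @export
var_panel <- function(cohort, snp_ids = NULL, subgroup = "overall",
                      include_gender = TRUE) {
  cohort <- subgroup_cohort(cohort, subgroup)
  if (is.null(snp_ids)) snp_ids <- cohort$snps$snp_id
  j <- match(snp_ids, cohort$snps$snp_id)
  if (anyNA(j)) stop("unknown SNP in panel")
  cols <- list(target = as.integer(cohort$subjects$status == "case") + 1L)
  card <- 2L
  if (include_gender) {
    cols$gender <- as.integer(cohort$subjects$gender == "male") + 1L
    card <- c(card, 2L)
  }
  for (i in seq_along(j)) {
    cols[[snp_ids[i]]] <- cohort$genotypes[, j[i]] + 1L
    card <- c(card, 3L)
  }
  dat <- do.call(cbind, cols)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (ncol(dat) > 31L) stop("panels are limited to 31 variables")
  structure(list(data = dat, card = card,
                 vars = colnames(dat), target = 1L),
            class = "var_panel")
}

#' @export
print.var_panel <- function(x, ...) {
  cat(sprintf("var_panel: %d complete-case subjects x %d variables (target '%s')\n",
              nrow(x$data), length(x$vars), x$vars[x$target]))
  invisible(x)
}

# Bit helpers: variable v <-> bit 2^(v-1) of a parent mask.
.bit <- function(v) bitwShiftL(1L, v - 1L)
.in_mask <- function(mask, v) bitwAnd(mask, .bit(v)) != 0L
.mask_vars <- function(mask, V) which(bitwAnd(mask, .bit(seq_len(V))) != 0L)

#' BDeu family log marginal likelihood
#'
#' Closed-form Dirichlet-multinomial log marginal likelihood of one child
#' variable given a parent set, with the Bayesian Dirichlet equivalent
#' uniform hyperparameters `ess / (q r)` (q parent configurations, r child
#' cardinality). Zero data rows score 0. Deterministic; callers cache by
#' (child, parent mask).
#'
#' @param panel a [var_panel].
#' @param child child variable index.
#' @param pmask parent set as a bitmask over variable indices.
#' @param ess equivalent sample size (prior strength), default 1.
#' @return log marginal likelihood (scalar).
#' @export
bdeu_family_score <- function(panel, child, pmask, ess = 1) {
  stopifnot(ess > 0)
  dat <- panel$data
  n <- nrow(dat)
  r <- panel$card[child]
  pa <- .mask_vars(pmask, length(panel$card))
  q <- if (length(pa)) prod(panel$card[pa]) else 1L
  if (n == 0L) return(0)
  if (length(pa)) {
    mult <- cumprod(c(1L, panel$card[pa][-length(pa)]))
    cfg <- as.integer((dat[, pa, drop = FALSE] - 1L) %*% mult) + 1L
  } else cfg <- rep(1L, n)
  cell <- (cfg - 1L) * r + dat[, child]
  counts <- tabulate(cell, nbins = q * r)
  a_jk <- ess / (q * r)
  a_j <- ess / q
  Nj <- .rowsum_groups(counts, q, r)
  sum(lgamma(a_j) - lgamma(a_j + Nj)) +
    sum(lgamma(a_jk + counts) - lgamma(a_jk))
}

# row sums of a q x r count vector laid out cell = (j-1)*r + k
.rowsum_groups <- function(counts, q, r) {
  .colSums(matrix(counts, r, q), r, q)
}

# memoising wrapper around bdeu_family_score
.make_scorer <- function(panel, ess) {
  cache <- new.env(parent = emptyenv())
  function(child, pmask) {
    key <- paste0(child, ":", pmask)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bdeu_family_score(panel, child, pmask, ess)
      cache[[key]] <- val
    }
    val
  }
}

#' Total BDeu score of a DAG
#'
#' Decomposable: the network score is the sum of family scores.
#'
#' @param panel a [var_panel].
#' @param parents integer vector of parent bitmasks, one per variable.
#' @param ess equivalent sample size.
#' @export
bdeu_network_score <- function(panel, parents, ess = 1) {
  sum(vapply(seq_along(parents), function(v)
    bdeu_family_score(panel, v, parents[v], ess), 0))
}

#' Exact posterior over DAG structures by enumeration
#'
#' Enumerates every DAG over the panel's variables subject to a fan-in
#' cap, scores it with the decomposable BDeu marginal likelihood under a
#' uniform structure prior, and normalises. Serves as the exact oracle
#' against which the MCMC sampler is validated; the candidate space grows
#' super-exponentially, so panels are limited to about 5 variables
#' (larger panels raise a size error directing to [mcmc_posterior()]).
#'
#' @param panel a [var_panel].
#' @param ess BDeu equivalent sample size.
#' @param fan_in maximum parents per variable.
#' @param max_combos safety cap on the candidate parent-set product.
#' @return object of class `structure_posterior`: list with `parents`
#'   (n_structures x V bitmask matrix), `weight` (normalised), `vars`,
#'   `card`, `target`, `provenance = "exact"`, `ess`.
#' @export
enumerate_posterior <- function(panel, ess = 1, fan_in = 4,
                                max_combos = 3e6) {
  V <- length(panel$card)
  if (V > 6) stop("size error: panel too large for enumeration; use mcmc_posterior")
  score <- .make_scorer(panel, ess)
  # candidate parent masks per node
  cand <- lapply(seq_len(V), function(v) {
    others <- setdiff(seq_len(V), v)
    masks <- 0L
    for (k in seq_len(min(fan_in, length(others)))) {
      sets <- utils::combn(others, k)
      masks <- c(masks, apply(sets, 2, function(s) sum(.bit(s))))
    }
    as.integer(masks)
  })
  n_comb <- prod(vapply(cand, length, 0))
  if (n_comb > max_combos)
    stop("size error: candidate space too large for enumeration; use mcmc_posterior")
  idx <- as.matrix(expand.grid(lapply(cand, seq_along)))
  P <- matrix(0L, nrow(idx), V)
  for (v in seq_len(V)) P[, v] <- cand[[v]][idx[, v]]
  # vectorised Kahn elimination across all candidate graphs
  rem <- rep.int(as.integer(2^V - 1), nrow(P))
  for (pass in seq_len(V)) {
    for (v in seq_len(V)) {
      removable <- bitwAnd(rem, .bit(v)) != 0L & bitwAnd(P[, v], rem) == 0L
      rem[removable] <- rem[removable] - .bit(v)
    }
  }
  acyclic <- rem == 0L
  P <- P[acyclic, , drop = FALSE]
  idx <- idx[acyclic, , drop = FALSE]
  fam <- lapply(seq_len(V), function(v)
    vapply(cand[[v]], function(m) score(v, m), 0))
  total <- rep(0, nrow(P))
  for (v in seq_len(V)) total <- total + fam[[v]][idx[, v]]
  w <- exp(total - max(total))
  structure(list(parents = P, weight = w / sum(w),
                 vars = panel$vars, card = panel$card,
                 target = panel$target,
                 provenance = "exact", ess = ess,
                 diagnostics = list(n_dags = nrow(P), fan_in = fan_in)),
            class = "structure_posterior")
}

#' @export
print.structure_posterior <- function(x, ...) {
  cat(sprintf("structure_posterior (%s): %d structures over %d variables\n",
              x$provenance, nrow(x$parents), length(x$vars)))
  if (!is.null(x$diagnostics$accept_rate))
    cat(sprintf("  MCMC acceptance rate %.2f over %d chains\n",
                mean(x$diagnostics$accept_rate), x$diagnostics$chains))
  invisible(x)
}

# is there a directed path from `from` to `to`? (parents = bitmask vector)
.has_path <- function(parents, from, to, V) {
  children <- lapply(seq_len(V), function(v)
    which(bitwAnd(parents, .bit(v)) != 0L))
  stack <- from
  seen <- logical(V)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, children[[v]])
  }
  FALSE
}

#' Structure MCMC posterior over DAGs
#'
#' Metropolis-Hastings over DAG space with add / delete / reverse-edge
#' proposals honouring acyclicity and the fan-in cap, a uniform structure
#' prior, and the decomposable BDeu score (only the families a move
#' touches are rescored; scores are memoised). Multiple independent
#' chains are pooled; posterior weights are visit frequencies after
#' burn-in and thinning. A between-chain disagreement check on the
#' Markov-blanket membership posteriors attaches a non-mixing warning to
#' the diagnostics when chains disagree.
#'
#' @param panel a [var_panel].
#' @param ess BDeu equivalent sample size.
#' @param fan_in maximum parents per variable.
#' @param iters iterations per chain (must exceed `burn_in`).
#' @param burn_in discarded initial iterations.
#' @param thin record every `thin`-th structure.
#' @param chains number of independent chains.
#' @param seed integer seed; identical settings give identical output.
#' @param mixing_tol maximum tolerated between-chain total-variation
#'   distance on blanket-membership posteriors before warning.
#' @return a `structure_posterior` with `provenance = "mcmc"`.
#' @export
mcmc_posterior <- function(panel, ess = 1, fan_in = 4, iters = 20000,
                           burn_in = 5000, thin = 10, chains = 2,
                           seed = 1L, mixing_tol = 0.1) {
  stopifnot(iters > burn_in)
  V <- length(panel$card)
  score <- .make_scorer(panel, ess)

  run_chain <- function(chain_seed) .rng_local(chain_seed, {
    parents <- rep(0L, V)
    fam <- vapply(seq_len(V), function(v) score(v, 0L), 0)
    counts <- new.env(parent = emptyenv())
    n_acc <- 0L; n_prop <- 0L
    npairs <- V * (V - 1)
    for (it in seq_len(iters)) {
      i <- sample.int(V, 1L)
      j <- sample.int(V - 1L, 1L); if (j >= i) j <- j + 1L
      has_edge <- .in_mask(parents[j], i)
      move <- NULL
      if (has_edge) {
        move <- if (stats::runif(1) < 0.5) "delete" else "reverse"
      } else move <- "add"
      ok <- TRUE
      new_parents <- parents
      if (move == "add") {
        if (sum(bitwAnd(parents[j], .bit(seq_len(V))) != 0L) >= fan_in ||
            .has_path(parents, j, i, V)) ok <- FALSE
        if (ok) new_parents[j] <- parents[j] + .bit(i)
        lqratio <- log(0.5)      # reverse-move asymmetry: add <-> delete
      } else if (move == "delete") {
        new_parents[j] <- parents[j] - .bit(i)
        lqratio <- log(2)
      } else { # reverse i -> j  becomes  j -> i
        if (sum(bitwAnd(parents[i], .bit(seq_len(V))) != 0L) >= fan_in) {
          ok <- FALSE
        } else {
          tmp <- parents
          tmp[j] <- tmp[j] - .bit(i)
          if (.has_path(tmp, i, j, V)) ok <- FALSE
          if (ok) {
            new_parents <- tmp
            new_parents[i] <- new_parents[i] + .bit(j)
          }
        }
        lqratio <- 0
      }
      n_prop <- n_prop + 1L
      if (ok) {
        touched <- if (move == "reverse") c(i, j) else j
        new_fam <- fam
        for (v in touched) new_fam[v] <- score(v, new_parents[v])
        ldelta <- sum(new_fam[touched]) - sum(fam[touched])
        if (log(stats::runif(1)) < ldelta + lqratio) {
          parents <- new_parents
          fam <- new_fam
          n_acc <- n_acc + 1L
        }
      }
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        key <- paste(parents, collapse = ".")
        prev <- counts[[key]]
        counts[[key]] <- if (is.null(prev)) 1L else prev + 1L
      }
    }
    list(counts = as.list(counts), accept = n_acc / n_prop)
  })

  chain_res <- lapply(seq_len(chains), function(c)
    run_chain(.derive_seed(seed, c)))

  # pool visit counts
  pool <- new.env(parent = emptyenv())
  for (cr in chain_res)
    for (key in names(cr$counts)) {
      prev <- pool[[key]]
      pool[[key]] <- if (is.null(prev)) cr$counts[[key]] else
        prev + cr$counts[[key]]
    }
  keys <- sort(names(pool))
  P <- do.call(rbind, lapply(strsplit(keys, ".", fixed = TRUE), as.integer))
  w <- vapply(keys, function(k) pool[[k]], 0L)
  w <- w / sum(w)

  post <- structure(list(parents = P, weight = unname(w),
                         vars = panel$vars, card = panel$card,
                         target = panel$target,
                         provenance = "mcmc", ess = ess,
                         diagnostics = list(
                           accept_rate = vapply(chain_res, `[[`, 0, "accept"),
                           chains = chains, iters = iters,
                           burn_in = burn_in, thin = thin, seed = seed,
                           fan_in = fan_in)),
                    class = "structure_posterior")
  if (chains >= 2) {
    mb <- lapply(chain_res, function(cr) {
      ks <- names(cr$counts)
      Pm <- do.call(rbind, lapply(strsplit(ks, ".", fixed = TRUE), as.integer))
      wm <- vapply(ks, function(k) cr$counts[[k]], 0L)
      .mb_membership(Pm, wm / sum(wm), panel$target, V)
    })
    tv <- max(abs(mb[[1]] - mb[[2]]))
    post$diagnostics$mb_tv_between_chains <- tv
    if (tv > mixing_tol) {
      post$diagnostics$mixing_warning <- TRUE
      warning(sprintf("chains disagree on blanket posteriors (TV %.3f)", tv))
    }
  }
  post
}

# per-variable Markov-blanket membership posterior from a mask matrix
.mb_membership <- function(P, w, target, V) {
  mb <- .classify_structures(P, target, V)
  as.numeric(t(mb$in_mb) %*% w)
}

# Vectorised per-structure graph classification relative to the target:
# membership masks for parents/children/spouses, adjacency and marginal
# d-connection (common-ancestor criterion).
.classify_structures <- function(P, target, V) {
  n <- nrow(P)
  pa_t <- P[, target]
  ch_mask <- rep(0L, n)
  sp_mask <- rep(0L, n)
  for (v in seq_len(V)) {
    if (v == target) next
    is_child <- bitwAnd(P[, v], .bit(target)) != 0L
    ch_mask <- ch_mask + ifelse(is_child, .bit(v), 0L)
    sp_mask <- bitwOr(sp_mask, ifelse(is_child, P[, v], 0L))
  }
  sp_mask <- bitwAnd(sp_mask, bitwNot(.bit(target)))
  adj <- bitwOr(pa_t, ch_mask)
  mb <- bitwOr(adj, bitwAnd(sp_mask, bitwNot(adj)))
  # ancestor closure (including self) per node, vectorised across rows
  anc <- lapply(seq_len(V), function(v) bitwOr(.bit(v), P[, v]))
  for (pass in seq_len(V)) {
    for (v in seq_len(V)) {
      acc <- anc[[v]]
      for (u in seq_len(V)) {
        if (u == v) next
        has_u <- bitwAnd(P[, v], .bit(u)) != 0L
        acc <- bitwOr(acc, ifelse(has_u, anc[[u]], 0L))
      }
      anc[[v]] <- acc
    }
  }
  # v is marginally d-connected to the target iff their ancestor sets
  # (including themselves) intersect; "association" additionally includes
  # blanket members (a spouse is d-separated given the empty set, yet the
  # taxonomy counts every strongly relevant variable as associated, so
  # that transitive relevance = association - strong relevance is a
  # nonnegative remainder)
  dcon <- matrix(FALSE, n, V)
  in_mb <- in_adj <- in_spouse_only <- matrix(FALSE, n, V)
  for (v in seq_len(V)) {
    if (v == target) next
    in_mb[, v] <- bitwAnd(mb, .bit(v)) != 0L
    in_adj[, v] <- bitwAnd(adj, .bit(v)) != 0L
    in_spouse_only[, v] <- in_mb[, v] & !in_adj[, v]
    dcon[, v] <- bitwAnd(anc[[v]], anc[[target]]) != 0L | in_mb[, v]
  }
  list(in_mb = in_mb, in_adj = in_adj,
       in_spouse_only = in_spouse_only, dcon = dcon,
       pa_t = pa_t, ch_mask = ch_mask)
}
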