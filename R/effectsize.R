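# --- internal: family sufficient statistics and CPT draws ------------------

.family_counts <- function(panel, child, pmask) {
  dat <- panel$data
  r <- panel$card[child]
  V <- length(panel$card)
  pa <- .mask_vars(pmask, V)
  q <- if (length(pa)) prod(panel$card[pa]) else 1L
  mult <- if (length(pa)) cumprod(c(1L, panel$card[pa][-length(pa)])) else
    integer(0)
  cfg <- if (length(pa))
    as.integer((dat[, pa, drop = FALSE] - 1L) %*% mult) + 1L else
      rep(1L, nrow(dat))
  counts <- matrix(tabulate((cfg - 1L) * r + dat[, child], nbins = q * r),
                   r, q)
  list(counts = counts, pa = pa, mult = mult, q = q, r = r)
}

# posterior-mean CPT, or one Dirichlet draw, from precomputed counts
.family_cpt <- function(fc, ess, sample_params = FALSE) {
  a_jk <- ess / (fc$q * fc$r)
  if (sample_params) {
    g <- matrix(stats::rgamma(fc$r * fc$q, shape = fc$counts + a_jk),
                fc$r, fc$q)
    sweep(g, 2, colSums(g), "/")
  } else {
    sweep(fc$counts + a_jk, 2, colSums(fc$counts) + ess / fc$q, "/")
  }
}

# Factory for P(target = case | config of `given`) under one structure:
# precomputes family counts, the blanket grid and the empirical weights
# of the marginalised members once, then evaluates cheaply per CPT draw.
# Returns a function(sample_params) -> vector over the row-major grid of
# given-variable levels (expand.grid order).
.bn_given_factory <- function(panel, parents, given, ess) {
  V <- length(panel$card)
  t <- panel$target
  mb <- markov_blanket(parents, t)
  ch <- which(vapply(seq_len(V), function(v)
    v != t && .in_mask(parents[v], t), TRUE))
  fam_child <- c(t, ch)
  fcs <- lapply(fam_child, function(v) .family_counts(panel, v, parents[v]))

  others <- setdiff(mb, given)
  grid_vars <- c(given, others)
  grid <- as.matrix(expand.grid(lapply(panel$card[grid_vars], seq_len)))
  colnames(grid) <- as.character(grid_vars)
  ng <- nrow(grid)

  if (length(others)) {
    omult <- cumprod(c(1L, panel$card[others][-length(others)]))
    ocfg <- as.integer((panel$data[, others, drop = FALSE] - 1L) %*% omult) + 1L
    ow <- tabulate(ocfg, nbins = prod(panel$card[others]))
    ow <- ow / sum(ow)
    grid_ocfg <- as.integer((grid[, as.character(others), drop = FALSE] - 1L) %*%
                              omult) + 1L
    w_marg <- ow[grid_ocfg]
  } else w_marg <- rep(1, ng)

  # per family and target level, the CPT cell index of every grid row
  cell_idx <- lapply(seq_along(fcs), function(f) lapply(1:2, function(tval) {
    fc <- fcs[[f]]
    child <- fam_child[f]
    cval <- if (child == t) rep(tval, ng) else grid[, as.character(child)]
    cfg <- if (length(fc$pa)) {
      pvals <- sapply(fc$pa, function(pv)
        if (pv == t) rep(tval, ng) else grid[, as.character(pv)])
      if (is.null(dim(pvals))) pvals <- matrix(pvals, ng)
      as.integer((pvals - 1L) %*% fc$mult) + 1L
    } else rep(1L, ng)
    (cfg - 1L) * fc$r + cval      # column-major index into the CPT
  }))

  gcfg <- if (length(given)) {
    gmult <- cumprod(c(1L, panel$card[given][-length(given)]))
    as.integer((grid[, as.character(given), drop = FALSE] - 1L) %*% gmult) + 1L
  } else rep(1L, ng)
  den_g <- as.numeric(tapply(w_marg, gcfg, sum))

  function(sample_params = FALSE) {
    thetas <- lapply(fcs, .family_cpt, ess = ess,
                     sample_params = sample_params)
    jk <- function(tval) {
      out <- rep(1, ng)
      for (f in seq_along(thetas))
        out <- out * thetas[[f]][cell_idx[[f]][[tval]]]
      out
    }
    num <- jk(2L)
    p_case <- num / (num + jk(1L))
    as.numeric(tapply(p_case * w_marg, gcfg, sum)) / den_g
  }
}

# single evaluation (kept for the joint-effect path)
.bn_target_given <- function(panel, parents, given, ess,
                             sample_params = FALSE) {
  .bn_given_factory(panel, parents, given, ess)(sample_params)
}

# signature of the target-local structure (its family plus each child's
# family); structures sharing it yield identical conditional ORs
.local_signature <- function(parents, target) {
  V <- length(parents)
  ch <- which(vapply(seq_len(V), function(v)
    v != target && .in_mask(parents[v], target), TRUE))
  paste(parents[target],
        paste(ch, parents[ch], sep = ":", collapse = ","), sep = "|")
}

#' Structure-conditional Bayesian odds-ratio posterior
#'
#' For every structure group in the posterior, the target's conditional
#' case probability under that dependency model is computed with
#' Dirichlet posterior-mean parameters (parametric averaging), the other
#' Markov-blanket members are marginalised over their empirical joint
#' distribution, and the odds ratio of the requested genotype contrast
#' versus the major-homozygote reference is formed. Structures in which
#' the SNP lies outside the target's blanket contribute an odds ratio of
#' exactly 1 (no dependency). The result is a weighted distribution over
#' odds-ratio values whose multimodality is attributable to structure
#' uncertainty.
#'
#' @param panel a [var_panel].
#' @param post a `structure_posterior` over the same panel.
#' @param snp_id variable name of the SNP.
#' @param contrast `"het"` (heterozygote vs major homozygote) or `"hom"`
#'   (minor homozygote vs major homozygote).
#' @param ess Dirichlet equivalent sample size (defaults to the
#'   posterior's).
#' @param n_param_samples Dirichlet parameter draws per structure group.
#'   Each draw contributes an OR atom carrying an equal share of the
#'   group's posterior mass, so segments acquire parameter-level width
#'   while multimodality stays attributable to structure groups alone.
#'   `0` uses Dirichlet posterior means (point OR per group).
#' @param seed seed for the parameter draws.
#' @return object of class `or_posterior`: list with `snp_id`,
#'   `contrast`, `values` (data.frame: or, weight), `inestimable_mass`.
#' @export
structure_or_posterior <- function(panel, post, snp_id,
                                   contrast = c("het", "hom"),
                                   ess = NULL, n_param_samples = 200,
                                   seed = 1L) {
  contrast <- match.arg(contrast)
  if (is.null(ess)) ess <- post$ess
  v <- match(snp_id, post$vars)
  if (is.na(v)) stop("SNP not in panel")
  lev <- if (contrast == "het") 2L else 3L
  if (!any(panel$data[, v] == lev))
    warning("contrast level unobserved; estimates rest on the prior")
  V <- length(post$vars)
  cls <- .classify_structures(post$parents, post$target, V)
  in_mb <- cls$in_mb[, v]
  vals <- list(data.frame(or = 1, weight = sum(post$weight[!in_mb])))

  vals[[1]]$group_or <- 1
  idx <- which(in_mb)
  if (length(idx)) {
    sigs <- vapply(idx, function(i)
      .local_signature(post$parents[i, ], post$target), "")
    w_sig <- tapply(post$weight[idx], sigs, sum)
    # evaluate only the structure groups carrying essentially all of the
    # in-blanket mass: an exact enumeration posterior can contain
    # thousands of groups whose joint mass is < 0.1%, which can never
    # reach any reporting floor; they are dropped and the atom weights
    # renormalised (distortion bounded by 1 - coverage)
    ord <- order(w_sig, decreasing = TRUE)
    covered <- cumsum(w_sig[ord]) / sum(w_sig)
    n_keep <- min(which(covered >= 0.999))
    keep_sigs <- names(w_sig)[ord[seq_len(n_keep)]]
    vals <- c(vals, .rng_local(seed, lapply(keep_sigs, function(s) {
      i0 <- idx[sigs == s][1]
      eval_p <- .bn_given_factory(panel, post$parents[i0, ], v, ess)
      or_of <- function(sample_params) {
        p <- eval_p(sample_params)
        (p[lev] / (1 - p[lev])) / (p[1] / (1 - p[1]))
      }
      point <- or_of(FALSE)   # group label: posterior-mean OR
      if (n_param_samples > 0) {
        ors <- vapply(seq_len(n_param_samples), function(k) or_of(TRUE), 0)
        data.frame(or = ors, weight = w_sig[[s]] / n_param_samples,
                   group_or = point)
      } else data.frame(or = point, weight = w_sig[[s]], group_or = point)
    })))
  }
  vals <- do.call(rbind, vals)
  vals <- vals[vals$weight > 0, , drop = FALSE]
  vals$weight <- vals$weight / sum(vals$weight)
  rownames(vals) <- NULL
  structure(list(snp_id = snp_id, contrast = contrast,
                 values = vals,
                 inestimable_mass = 0,
                 target = post$vars[post$target]),
            class = "or_posterior")
}

#' @export
print.or_posterior <- function(x, ...) {
  cat(sprintf("or_posterior for %s (%s vs reference): %d support points\n",
              x$snp_id, x$contrast, nrow(x$values)))
  print(hpd_segments(x))
  invisible(x)
}

#' Highest-posterior-density segments of an OR posterior
#'
#' Structure groups supporting near-identical odds ratios (chained
#' clustering of the groups' posterior-mean ORs with a gap tolerance on
#' the log-OR scale) are merged, reproducing the "groups of dependency
#' models each supporting different odds ratios" reading of a multimodal
#' Bayesian odds ratio. Each merged group is summarised by the shortest
#' interval containing `level` of its own (parameter-sampled) mass, with
#' a probability weight equal to the group's share of the retained
#' posterior mass; disjoint segments are therefore possible and expected
#' when the posterior is multimodal. A degenerate single-value posterior
#' yields a single zero-width segment.
#'
#' @param orp an `or_posterior`.
#' @param level credible level.
#' @param cluster_gap gap on the log scale of the group-mean ORs above
#'   which adjacent groups stay separate segments.
#' @param min_weight groups below this posterior mass are dropped from
#'   the summary (their mass is renormalised away).
#' @return data.frame of class `hpd_segments`: `low`, `high`,
#'   `prob_weight` (sums to 1 over segments).
#' @export
hpd_segments <- function(orp, level = 0.95, cluster_gap = 0.01,
                         min_weight = 0.02) {
  vals <- orp$values
  if (nrow(vals) == 0) stop("empty posterior")
  if (is.null(vals$group_or)) vals$group_or <- vals$or
  # chain structure groups whose mean ORs nearly coincide
  gm <- sort(unique(vals$group_or))
  chain <- cumsum(c(1, diff(log(gm)) > cluster_gap))
  seg_id <- chain[match(vals$group_or, gm)]
  shortest <- function(xs, ws) {
    o <- order(xs); xs <- xs[o]; ws <- ws[o]
    mass <- sum(ws)
    if (length(xs) == 1L) return(c(xs, xs, mass))
    cw <- cumsum(ws)
    target <- level * mass
    best <- c(xs[1], xs[length(xs)]); best_len <- log(best[2] / best[1])
    for (i in seq_along(xs)) {
      below <- if (i > 1) cw[i - 1] else 0
      jj <- which(cw - below >= target - 1e-12)
      if (!length(jj)) break
      j <- min(jj)
      if (j < i) next
      len <- log(xs[j]) - log(xs[i])
      if (len <= best_len) { best_len <- len; best <- c(xs[i], xs[j]) }
    }
    c(best, mass)
  }
  segs <- t(vapply(split(seq_len(nrow(vals)), seg_id), function(ii)
    shortest(vals$or[ii], vals$weight[ii]), numeric(3)))
  segs <- data.frame(low = segs[, 1], high = segs[, 2], mass = segs[, 3])
  keep <- segs[segs$mass >= min_weight, , drop = FALSE]
  if (nrow(keep)) segs <- keep
  out <- data.frame(low = segs$low, high = segs$high,
                    prob_weight = segs$mass / sum(segs$mass))
  out <- out[order(out$low), ]
  rownames(out) <- NULL
  class(out) <- c("hpd_segments", "data.frame")
  out
}

#' Model-averaged joint effect of two SNPs (dominant coding)
#'
#' For each of the four dominant-coded joint genotype cells (carrier
#' status of each SNP), the conditional case probability is computed per
#' structure with Dirichlet posterior-mean parameters (other blanket
#' members marginalised empirically) and averaged over the structure
#' posterior (parametric averaging). Joint odds ratios compare each cell
#' with the double-reference cell.
#'
#' @param panel a [var_panel].
#' @param post a `structure_posterior`.
#' @param snp_a,snp_b variable names.
#' @param ess Dirichlet equivalent sample size (defaults to the
#'   posterior's).
#' @return object of class `joint_effect`: list with `pair`, `p_case`
#'   (2x2 matrix of model-averaged case probabilities), `joint_or`
#'   (2x2, reference cell exactly 1), `cell_n` (empirical cell counts;
#'   zero-count cells are flagged inestimable).
#' @export
joint_effect <- function(panel, post, snp_a, snp_b, ess = NULL) {
  if (is.null(ess)) ess <- post$ess
  va <- match(snp_a, post$vars); vb <- match(snp_b, post$vars)
  if (is.na(va) || is.na(vb)) stop("SNP not in panel")
  given <- c(va, vb)
  # p(case | ga, gb) per structure signature, then weight-average
  sigs <- vapply(seq_len(nrow(post$parents)), function(i)
    .local_signature(post$parents[i, ], post$target), "")
  p_acc <- matrix(0, 3, 3)
  for (s in unique(sigs)) {
    rows <- sigs == s
    i0 <- which(rows)[1]
    p <- .bn_target_given(panel, post$parents[i0, ], given, ess)
    p_acc <- p_acc + sum(post$weight[rows]) * matrix(p, 3, 3)
  }
  # dominant collapse weighted by the empirical joint genotype distribution
  ja <- panel$data[, va]; jb <- panel$data[, vb]
  wjoint <- matrix(tabulate((jb - 1L) * 3L + ja, nbins = 9), 3, 3)
  dom <- function(i) if (i == 1) 1L else 2L
  p_dom <- matrix(0, 2, 2); n_dom <- matrix(0, 2, 2)
  for (i in 1:3) for (j in 1:3) {
    di <- dom(i); dj <- dom(j)
    p_dom[di, dj] <- p_dom[di, dj] + wjoint[i, j] * p_acc[i, j]
    n_dom[di, dj] <- n_dom[di, dj] + wjoint[i, j]
  }
  p_dom <- ifelse(n_dom > 0, p_dom / n_dom, NA)
  odds <- p_dom / (1 - p_dom)
  joint_or <- odds / odds[1, 1]
  dimnames(p_dom) <- dimnames(joint_or) <- dimnames(n_dom) <-
    list(paste0(snp_a, c("_ref", "_carrier")),
         paste0(snp_b, c("_ref", "_carrier")))
  structure(list(pair = c(snp_a, snp_b), p_case = p_dom,
                 joint_or = joint_or, cell_n = n_dom,
                 inestimable = n_dom == 0),
            class = "joint_effect")
}

#' @export
print.joint_effect <- function(x, ...) {
  cat(sprintf("joint_effect of %s x %s (dominant coding)\n",
              x$pair[1], x$pair[2]))
  cat("model-averaged P(case):\n"); print(round(x$p_case, 4))
  cat("joint OR vs double reference:\n"); print(round(x$joint_or, 4))
  invisible(x)
}
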