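#' EM estimation of haplotype frequencies over a small SNP block
#'
#' Standard expectation-maximisation on the multinomial haplotype-pair
#' likelihood of unphased genotypes (the algorithm behind the usual
#' haplotype/LD tools). The haplotype space is enumerated exhaustively,
#' so blocks are limited to k <= 6 SNPs. Subjects with any missing
#' genotype in the block are dropped. Haplotypes are labelled with the
#' allele characters of each SNP (major/minor), falling back to 0/1 when
#' alleles are unknown.
#'
#' Initialisation is the product of observed allele frequencies; optional
#' random restarts (Dirichlet draws) guard against ties and the best
#' converged log-likelihood is kept. The log-likelihood is checked to be
#' nondecreasing at every iteration.
#'
#' @param cohort a [cohort_data] object.
#' @param snp_ids ordered SNP identifiers forming the block (k <= 6).
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter iteration cap per start.
#' @param restarts number of additional random starts.
#' @param seed integer seed used only for the random restarts.
#' @param status restrict to `"case"`, `"control"` or `"all"` subjects.
#' @return object of class `haplo_block`: list with `snp_ids`,
#'   `hap_freqs` (named, sums to 1), `loglik`, `n_chrom`, `n_subjects`,
#'   `expected_counts` (fractional EM-expected haplotype counts).
#' @export
em_haplotype_freq <- function(cohort, snp_ids, tol = 1e-8, max_iter = 500,
                              restarts = 0, seed = 1L, status = "all") {
  k <- length(snp_ids)
  if (k < 1) stop("need at least one SNP")
  if (k > 6) stop("size error: exhaustive haplotype space limited to k <= 6")
  status <- match.arg(status, c("all", "case", "control"))
  j <- match(snp_ids, cohort$snps$snp_id)
  if (anyNA(j)) stop("unknown SNP in block")
  rows <- if (status == "all") rep(TRUE, nrow(cohort$subjects)) else
    cohort$subjects$status == status
  G <- cohort$genotypes[rows, j, drop = FALSE]
  G <- G[stats::complete.cases(G), , drop = FALSE]
  n <- nrow(G)
  if (n == 0) stop("no complete-case subjects in block")

  H <- 2^k
  # row i corresponds to haplotype index i: SNP s occupies bit s-1
  hap_mat <- as.matrix(expand.grid(rep(list(0:1), k)))
  lab_for <- function(h) {
    paste(vapply(seq_len(k), function(s) {
      maj <- cohort$snps$major[j[s]]; mnr <- cohort$snps$minor[j[s]]
      if (is.na(maj) || is.na(mnr)) as.character(h[s]) else
        if (h[s] == 0) maj else mnr
    }, ""), collapse = "")
  }
  labels <- apply(hap_mat, 1, lab_for)

  # Pre-compute, per distinct multilocus genotype, the compatible
  # haplotype pairs (indices into the haplotype space).
  gkey <- apply(G, 1, paste, collapse = "")
  tab <- table(gkey)
  patterns <- do.call(rbind, strsplit(names(tab), ""))
  storage.mode(patterns) <- "integer"
  wts <- as.numeric(tab)
  pairs_of <- lapply(seq_len(nrow(patterns)), function(i) {
    g <- patterns[i, ]
    het <- which(g == 1L)
    base <- ifelse(g == 2L, 1L, 0L)
    if (length(het) == 0L) {
      idx <- sum(base * 2^(seq_len(k) - 1)) + 1L
      return(cbind(idx, idx))
    }
    m <- length(het)
    combos <- as.matrix(expand.grid(rep(list(0:1), m)))
    h1 <- matrix(rep(base, each = nrow(combos)), nrow(combos), k)
    h1[, het] <- combos
    h2 <- matrix(rep(base, each = nrow(combos)), nrow(combos), k)
    h2[, het] <- 1L - combos
    i1 <- h1 %*% 2^(seq_len(k) - 1) + 1L
    i2 <- h2 %*% 2^(seq_len(k) - 1) + 1L
    keep <- i1 <= i2          # unordered pairs, keep one representative
    cbind(i1[keep], i2[keep])
  })

  run_em <- function(p0) {
    p <- p0 / sum(p0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      exp_counts <- numeric(H)
      ll <- 0
      for (i in seq_along(pairs_of)) {
        pr <- pairs_of[[i]]
        w <- p[pr[, 1]] * p[pr[, 2]] * ifelse(pr[, 1] == pr[, 2], 1, 2)
        tot <- sum(w)
        if (tot <= 0) { ll <- -Inf; break }
        ll <- ll + wts[i] * log(tot)
        wn <- w / tot * wts[i]
        for (r in seq_len(nrow(pr))) {
          exp_counts[pr[r, 1]] <- exp_counts[pr[r, 1]] + wn[r]
          exp_counts[pr[r, 2]] <- exp_counts[pr[r, 2]] + wn[r]
        }
      }
      if (is.infinite(ll)) return(list(p = p, ll = -Inf))
      if (ll < ll_prev - 1e-9)
        stop("EM log-likelihood decreased (internal error)")
      p <- exp_counts / (2 * n)
      if (ll - ll_prev < tol && it > 1) break
      ll_prev <- ll
    }
    list(p = p, ll = ll, counts = exp_counts)
  }

  af <- colMeans(G) / 2
  p0 <- apply(hap_mat, 1, function(h) prod(ifelse(h == 1, af, 1 - af)))
  p0[p0 <= 0] <- 1e-12
  best <- run_em(p0)
  if (restarts > 0) {
    rs <- .rng_local(seed, {
      lapply(seq_len(restarts), function(r) stats::rgamma(H, 1))
    })
    for (start in rs) {
      cand <- run_em(start)
      if (cand$ll > best$ll) best <- cand
    }
  }
  ord <- order(best$p, decreasing = TRUE)
  structure(list(snp_ids = snp_ids,
                 hap_freqs = stats::setNames(best$p, labels)[ord],
                 loglik = best$ll,
                 n_chrom = 2L * n,
                 n_subjects = n,
                 expected_counts = stats::setNames(best$counts, labels)[ord]),
            class = "haplo_block")
}

#' @export
print.haplo_block <- function(x, ...) {
  cat(sprintf("haplo_block over %d SNPs (%d chromosomes), loglik %.3f\n",
              length(x$snp_ids), x$n_chrom, x$loglik))
  shown <- x$hap_freqs[x$hap_freqs > 0.001]
  print(round(shown, 4))
  invisible(x)
}

#' Pairwise linkage disequilibrium from a 2-SNP haplotype block
#'
#' D = p(AB) - p(A) p(B); D' = |D| / Dmax with Dmax the bound implied by
#' the allele frequencies; r^2 = D^2 / (p(A) p(a) p(B) p(b)). Haplotype
#' labels follow the block's ordering: allele "0" of each SNP is its
#' major allele.
#'
#' @param block a `haplo_block` over exactly two SNPs (see
#'   [em_haplotype_freq()]).
#' @return list with `d`, `d_prime`, `r2`.
#' @export
ld_pair <- function(block) {
  if (!inherits(block, "haplo_block") || length(block$snp_ids) != 2)
    stop("ld_pair needs a haplo_block over exactly 2 SNPs")
  f <- block$hap_freqs
  # reconstruct the 2x2 haplotype table from labels: order is unknown,
  # but each label is a 2-character string; split on first/second SNP allele
  a1 <- substr(names(f), 1, 1); a2 <- substr(names(f), 2, 2)
  u1 <- sort(unique(a1)); u2 <- sort(unique(a2))
  if (length(u1) < 2 || length(u2) < 2)
    stop("monomorphic SNP: LD undefined")
  pA <- sum(f[a1 == u1[1]]); pB <- sum(f[a2 == u2[1]])
  pAB <- sum(f[a1 == u1[1] & a2 == u2[1]])
  d <- pAB - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(d = d, d_prime = d_prime, r2 = r2)
}

#' Case-control odds ratio of one haplotype
#'
#' Delegates to [or_2x2()] on the haplotype-versus-rest chromosome counts.
#'
#' @param case_count,case_chrom haplotype count and chromosome total in
#'   cases.
#' @param ctrl_count,ctrl_chrom same for controls.
#' @return as [or_2x2()].
#' @export
haplotype_case_control_or <- function(case_count, case_chrom,
                                      ctrl_count, ctrl_chrom) {
  if (case_count > case_chrom || ctrl_count > ctrl_chrom)
    stop("haplotype count exceeds chromosome total")
  or_2x2(case_count, case_chrom - case_count,
         ctrl_count, ctrl_chrom - ctrl_count)
}

#' Haplotype association table for a block
#'
#' Runs the EM separately in cases and controls, rounds the EM-expected
#' haplotype counts to integers (fractional counts are kept alongside) and
#' reports the case-control odds ratio of every haplotype above
#' `min_freq` in either group.
#'
#' @param cohort a [cohort_data] object.
#' @param snp_ids block SNPs.
#' @param min_freq minimum haplotype frequency to report.
#' @param ... passed to [em_haplotype_freq()].
#' @return data.frame: haplotype, case/control counts (integer and
#'   fractional), frequencies, OR, CI, p.
#' @export
haplotype_assoc <- function(cohort, snp_ids, min_freq = 0.01, ...) {
  bc <- em_haplotype_freq(cohort, snp_ids, status = "case", ...)
  bk <- em_haplotype_freq(cohort, snp_ids, status = "control", ...)
  haps <- union(names(bc$hap_freqs[bc$hap_freqs >= min_freq]),
                names(bk$hap_freqs[bk$hap_freqs >= min_freq]))
  rows <- lapply(haps, function(h) {
    cc <- unname(bc$expected_counts[h]); ck <- unname(bk$expected_counts[h])
    if (is.na(cc)) cc <- 0
    if (is.na(ck)) ck <- 0
    o <- haplotype_case_control_or(round(cc), bc$n_chrom,
                                   round(ck), bk$n_chrom)
    data.frame(haplotype = h,
               case_count = round(cc), case_count_frac = cc,
               case_freq = cc / bc$n_chrom,
               ctrl_count = round(ck), ctrl_count_frac = ck,
               ctrl_freq = ck / bk$n_chrom,
               or_hat = o$or_hat, ci_low = o$ci_low, ci_high = o$ci_high,
               p = o$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$case_freq), ]
}
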