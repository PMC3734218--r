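#' Hardy-Weinberg equilibrium chi-square goodness-of-fit test
#'
#' Compares observed genotype counts to the HWE expectations derived from
#' the observed allele frequency; 1 degree of freedom (three genotype
#' classes, one estimated allele frequency).
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @return list with `chi2` and `p`. For monomorphic input both are `NA`
#'   (the test is undefined; callers treat the SNP as monomorphic, not as
#'   an HWE failure).
#' @export
hwe_chisq <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  if (n <= 0) stop("no observations")
  p <- (2 * n_hom_minor + n_het) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi2 = NA_real_, p = NA_real_))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n_hom_major, n_het, n_hom_minor)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' 2x2 odds ratio with Woolf confidence interval
#'
#' OR = ad/bc with the Woolf (log-OR) 95 percent confidence interval and a
#' two-sided p-value from the log-OR z statistic. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and the
#' result is flagged.
#'
#' @param a,b,c,d cell counts: exposed cases, unexposed cases, exposed
#'   controls, unexposed controls.
#' @param conf confidence level.
#' @return list: `or_hat`, `ci_low`, `ci_high`, `p`, `haldane` (logical).
#' @export
or_2x2 <- function(a, b, c, d, conf = 0.95) {
  if (any(c(a, b, c, d) < 0)) stop("negative counts")
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  zstat <- log(or) / se
  list(or_hat = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p = 2 * stats::pnorm(-abs(zstat)),
       haldane = haldane)
}

.codings <- c("genotype", "dominant", "recessive", "allelic")

#' Per-SNP association under a genetic coding
#'
#' Gender-adjusted logistic regression of case/control status on the coded
#' genotype, mirroring the standard layout of candidate-gene association
#' tables. Codings:
#' \describe{
#'   \item{genotype}{two contrasts, heterozygote vs major homozygote and
#'     minor homozygote vs major homozygote;}
#'   \item{dominant}{allele positivity, carrier (het or minor hom) vs
#'     major homozygote;}
#'   \item{recessive}{minor homozygote vs carrier-of-major;}
#'   \item{allelic}{2N allele-level 2x2 table (no covariate adjustment:
#'     alleles, not subjects, are the units).}
#' }
#' Estimates are maximum-likelihood with Wald 95 percent confidence
#' intervals and Wald p-values. Subgroup analyses keep all controls and
#' the named case subtype. Subjects missing the genotype are dropped
#' (complete-case).
#'
#' @param cohort a [cohort_data] object.
#' @param snp_id SNP to test.
#' @param coding `"genotype"`, `"dominant"`, `"recessive"` or `"allelic"`.
#' @param subgroup `"overall"`, `"B"`, `"T"` or `"HD"`.
#' @param adjust_gender include gender as a covariate (ignored for the
#'   allelic coding).
#' @return data.frame with one row per contrast: `snp_id`, `subgroup`,
#'   `coding`, `contrast`, `or_hat`, `ci_low`, `ci_high`, `p`, `n_used`,
#'   `note` (`""`, `"separation"` or `"inestimable"`).
#' @export
genotype_logistic <- function(cohort, snp_id, coding = "genotype",
                              subgroup = "overall", adjust_gender = TRUE) {
  coding <- match.arg(coding, .codings)
  cohort <- subgroup_cohort(cohort, subgroup)
  j <- match(snp_id, cohort$snps$snp_id)
  if (is.na(j)) stop(sprintf("unknown SNP '%s'", snp_id))
  g <- cohort$genotypes[, j]
  y <- as.integer(cohort$subjects$status == "case")
  sex <- cohort$subjects$gender
  ok <- !is.na(g)
  g <- g[ok]; y <- y[ok]; sex <- sex[ok]
  if (sum(y) == 0 || sum(1 - y) == 0)
    stop("need at least one case and one control with a genotype call")

  res_row <- function(contrast, est, note = "") {
    data.frame(snp_id = snp_id, subgroup = subgroup, coding = coding,
               contrast = contrast,
               or_hat = est[1], ci_low = est[2], ci_high = est[3],
               p = est[4], n_used = length(y), note = note,
               stringsAsFactors = FALSE)
  }

  if (coding == "allelic") {
    case_minor <- sum(g[y == 1]); case_tot <- 2 * sum(y == 1)
    ctrl_minor <- sum(g[y == 0]); ctrl_tot <- 2 * sum(y == 0)
    o <- or_2x2(case_minor, case_tot - case_minor,
                ctrl_minor, ctrl_tot - ctrl_minor)
    out <- res_row("minor vs major allele",
                   c(o$or_hat, o$ci_low, o$ci_high, o$p),
                   if (o$haldane) "haldane" else "")
    out$n_used <- case_tot + ctrl_tot
    return(out)
  }

  x <- switch(coding,
              genotype = factor(g, levels = 0:2),
              dominant = as.integer(g >= 1),
              recessive = as.integer(g == 2))
  dat <- data.frame(y = y, x = x, sex = factor(sex))
  form <- if (adjust_gender && length(unique(sex)) > 1) y ~ x + sex else y ~ x
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  sm <- suppressWarnings(summary(fit))$coefficients
  sep_note <- if (!fit$converged || any(abs(stats::coef(fit)) > 15,
                                        na.rm = TRUE)) "separation" else ""
  grab <- function(name, label) {
    if (!name %in% rownames(sm))
      return(res_row(label, c(NA, NA, NA, NA), "inestimable"))
    b <- sm[name, "Estimate"]; se <- sm[name, "Std. Error"]
    res_row(label, c(exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se),
                     sm[name, "Pr(>|z|)"]), sep_note)
  }
  if (coding == "genotype") {
    rbind(grab("x1", "het vs major hom"), grab("x2", "minor hom vs major hom"))
  } else if (coding == "dominant") {
    grab("x", "carrier vs major hom")
  } else {
    grab("x", "minor hom vs carrier/major hom")
  }
}

#' Sweep one coding across every SNP of a cohort
#'
#' @inheritParams genotype_logistic
#' @return stacked data.frame of [genotype_logistic()] rows.
#' @export
assoc_sweep <- function(cohort, coding = "genotype", subgroup = "overall",
                        adjust_gender = TRUE) {
  do.call(rbind, lapply(cohort$snps$snp_id, function(id) {
    tryCatch(genotype_logistic(cohort, id, coding, subgroup, adjust_gender),
             error = function(e)
               data.frame(snp_id = id, subgroup = subgroup, coding = coding,
                          contrast = NA, or_hat = NA, ci_low = NA,
                          ci_high = NA, p = NA, n_used = 0L,
                          note = conditionMessage(e),
                          stringsAsFactors = FALSE))
  }))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up procedure: with sorted p-values p(1) <= ... <= p(m), the
#' threshold is p(k) for the largest k with p(k) <= (k/m) q; every test
#' with p below or at the threshold is declared significant. If no k
#' qualifies the threshold is 0 and the significant set empty.
#'
#' @param pvals named numeric vector of p-values.
#' @param q target false discovery rate.
#' @return list: `q`, `m`, `threshold`, `significant` (names).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value input")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  m <- length(pvals)
  if (is.null(names(pvals))) names(pvals) <- paste0("t", seq_len(m))
  ps <- sort(pvals)
  ok <- which(ps <= (seq_len(m) / m) * q)
  threshold <- if (length(ok)) ps[max(ok)] else 0
  list(q = q, m = m, threshold = unname(threshold),
       significant = names(pvals)[pvals <= threshold & threshold > 0])
}

#' Case-control genetic power calculator
#'
#' Re-implementation of the Purcell-Sham genetic power calculation for a
#' discrete trait. Expected case and control genotype frequencies are
#' derived from Hardy-Weinberg proportions at the given minor (risk)
#' allele frequency, the genetic model, the genotype relative risk and a
#' baseline prevalence; power is the upper-tail probability of the
#' noncentral chi-square for the coded contingency test, with the
#' noncentrality parameter equal to the Pearson statistic of the expected
#' table.
#'
#' The `dominant` and `recessive` models collapse the 3x2 table to a 1-df
#' 2x2 test; `genotype` keeps the 2-df test; `allelic` tests the 2N allele
#' table (1 df). Under `grr = 1` the noncentrality is 0 and power equals
#' `alpha`.
#'
#' @param maf minor (risk) allele frequency.
#' @param grr genotype relative risk of the risk genotype class.
#' @param model `"recessive"`, `"dominant"`, `"additive"`, `"genotype"`
#'   or `"allelic"`. `additive` uses risks (1, grr, 2 grr - 1) with the
#'   trend collapse replaced by the allele-level test.
#' @param n_case,n_ctrl sample sizes.
#' @param alpha significance level of the test.
#' @param prevalence baseline disease prevalence; the default 5e-4
#'   reflects a rare disease.
#' @return power, a single number in \[0,1\].
#' @export
genetic_power <- function(maf, grr, model = "recessive", n_case, n_ctrl,
                          alpha = 0.05, prevalence = 5e-4) {
  model <- match.arg(model, c("recessive", "dominant", "additive",
                              "genotype", "allelic"))
  stopifnot(grr > 0, alpha > 0, alpha < 1, maf > 0, maf < 1)
  p <- maf; q <- 1 - p
  gf <- c(q^2, 2 * p * q, p^2)       # major hom, het, minor hom
  rr <- switch(model,
               recessive = c(1, 1, grr),
               dominant = c(1, grr, grr),
               additive = c(1, grr, 2 * grr - 1),
               genotype = c(1, grr, grr^2),   # multiplicative per genotype
               allelic = c(1, grr, grr^2))
  f0 <- prevalence / sum(gf * rr)
  f <- f0 * rr
  if (any(f >= 1)) stop("parameter error: implied penetrance >= 1")
  case <- gf * f / sum(gf * f)
  ctrl <- gf * (1 - f) / sum(gf * (1 - f))

  pearson_ncp <- function(p1, p2, n1, n2) {
    e1 <- n1 * p1; e2 <- n2 * p2
    colm <- e1 + e2; nn <- n1 + n2
    sum((e1 - n1 * colm / nn)^2 / (n1 * colm / nn)) +
      sum((e2 - n2 * colm / nn)^2 / (n2 * colm / nn))
  }
  if (model %in% c("recessive")) {
    ncp <- pearson_ncp(c(case[1] + case[2], case[3]),
                       c(ctrl[1] + ctrl[2], ctrl[3]), n_case, n_ctrl)
    df <- 1
  } else if (model == "dominant") {
    ncp <- pearson_ncp(c(case[1], case[2] + case[3]),
                       c(ctrl[1], ctrl[2] + ctrl[3]), n_case, n_ctrl)
    df <- 1
  } else if (model == "genotype") {
    ncp <- pearson_ncp(case, ctrl, n_case, n_ctrl)
    df <- 2
  } else { # additive / allelic: allele-level 2x2 on 2N chromosomes
    ac <- c(case[1] + case[2] / 2, case[3] + case[2] / 2)
    an <- c(ctrl[1] + ctrl[2] / 2, ctrl[3] + ctrl[2] / 2)
    ncp <- pearson_ncp(ac, an, 2 * n_case, 2 * n_ctrl)
    df <- 1
  }
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
}
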