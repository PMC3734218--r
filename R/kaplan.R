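#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator with Greenwood standard errors, the censored
#' fraction, and the restricted mean survival time (area under the step
#' function up to the largest observed time across the analysis, with its
#' standard error). Ties are handled with the standard convention that
#' deaths precede censorings at equal times.
#'
#' @param time event/censoring times.
#' @param event logical, `TRUE` = event observed.
#' @param group label attached to the result.
#' @param tmax upper limit of the restricted mean (defaults to the largest
#'   observed time in this group; pass a common value when comparing
#'   groups).
#' @return object of class `km_curve`: list with `group`, `times`, `surv`,
#'   `se`, `n_total`, `n_events`, `n_censored`, `pct_censored`, `rmean`,
#'   `rmean_se`, `rmean_ci`.
#' @export
km_curve <- function(time, event, group = "all", tmax = NULL) {
  stopifnot(length(time) == length(event), all(time >= 0))
  n <- length(time)
  if (n == 0) stop("empty group")
  if (is.null(tmax)) tmax <- max(time)
  dt <- sort(unique(time[event]))
  at_risk <- vapply(dt, function(t) sum(time >= t), 0)
  d <- vapply(dt, function(t) sum(time == t & event), 0)
  s <- cumprod(1 - d / at_risk)
  # Greenwood variance of S(t)
  gw <- cumsum(d / (at_risk * (at_risk - d)))
  gw[!is.finite(gw)] <- NA
  se <- s * sqrt(gw)

  # restricted mean: area under S(t) on [0, tmax]
  ts <- c(0, dt[dt <= tmax], tmax)
  ss <- c(1, s[dt <= tmax], NA)
  rmean <- sum(diff(ts) * ss[-length(ss)])
  # variance of the restricted mean (standard formula)
  kdt <- dt[dt <= tmax]
  if (length(kdt)) {
    area_after <- vapply(seq_along(kdt), function(i) {
      tt <- c(kdt[i:length(kdt)], tmax)
      svals <- s[dt <= tmax][i:length(kdt)]
      sum(diff(tt) * svals)
    }, 0)
    nr <- at_risk[dt <= tmax]; dd <- d[dt <= tmax]
    varr <- sum(area_after^2 * dd / (nr * (nr - dd)), na.rm = TRUE)
  } else varr <- 0
  rmean_se <- sqrt(varr)
  structure(list(group = group,
                 times = dt, surv = s, se = se,
                 n_total = n, n_events = sum(event),
                 n_censored = sum(!event),
                 pct_censored = sum(!event) / n,
                 rmean = rmean, rmean_se = rmean_se,
                 rmean_ci = rmean + c(-1.96, 1.96) * rmean_se,
                 tmax = tmax),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve '%s': n %d, events %d, censored %d (%.1f%%), rmean %.2f (se %.2f)\n",
              x$group, x$n_total, x$n_events, x$n_censored,
              100 * x$pct_censored, x$rmean, x$rmean_se))
  invisible(x)
}

#' Kaplan-Meier curves by genotype group
#'
#' Cases only; subjects without survival data or without a genotype call
#' are dropped. Grouping `"carrier"` uses wild / carrier / mutant (0 vs 1
#' vs 2 copies of the minor allele, the usual candidate-gene layout);
#' `"genotype"` keeps the three genotypes separately (identical here, but
#' kept distinct for symmetry with collapsed groupings); `"dominant"`
#' merges carrier+mutant.
#'
#' @param cohort a [cohort_data] object.
#' @param snp_id SNP defining the groups.
#' @param grouping `"carrier"`, `"genotype"` or `"dominant"`.
#' @param endpoint unused hook for multiple endpoints; present so callers
#'   can label outputs.
#' @return list of [km_curve] objects (empty groups omitted with a
#'   warning), plus an `"overall"` curve, with a common `tmax`.
#' @export
km_by_genotype <- function(cohort, snp_id, grouping = "carrier",
                           endpoint = "overall_survival") {
  grouping <- match.arg(grouping, c("carrier", "genotype", "dominant"))
  j <- match(snp_id, cohort$snps$snp_id)
  if (is.na(j)) stop(sprintf("unknown SNP '%s'", snp_id))
  sub <- cohort$subjects
  keep <- sub$status == "case" & !is.na(sub$surv_time) &
    !is.na(cohort$genotypes[, j])
  if (!any(keep)) stop("no cases with survival data and genotype call")
  g <- cohort$genotypes[keep, j]
  time <- sub$surv_time[keep]; event <- sub$surv_event[keep]
  lab <- switch(grouping,
                carrier = c("wild", "carrier", "mutant")[g + 1L],
                genotype = c("wild", "carrier", "mutant")[g + 1L],
                dominant = c("wild", "carrier", "carrier")[g + 1L])
  tmax <- max(time)
  levels <- unique(c("wild", "carrier", "mutant"))
  curves <- list()
  for (lv in levels) {
    idx <- lab == lv
    if (!any(idx)) {
      if (lv %in% lab || (grouping != "dominant" && lv == "mutant"))
        warning(sprintf("group '%s' empty; omitted", lv))
      next
    }
    curves[[lv]] <- km_curve(time[idx], event[idx], lv, tmax = tmax)
  }
  curves[["overall"]] <- km_curve(time, event, "overall", tmax = tmax)
  attr(curves, "groups") <- setdiff(names(curves), "overall")
  attr(curves, "raw") <- data.frame(time = time, event = event, group = lab,
                                    stringsAsFactors = FALSE)
  curves
}

#' Mantel-Cox logrank test
#'
#' Observed-minus-expected statistic across pooled event times with the
#' hypergeometric variance, for two or more groups; df = groups - 1.
#'
#' @param time,event,group parallel vectors; `group` any label vector with
#'   at least two distinct values.
#' @return list: `chi2`, `df`, `p`, `observed`, `expected` (per group).
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 non-empty groups")
  if (!any(event)) stop("degenerate test: no events in any group")
  dt <- sort(unique(time[event]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k)
  for (t in dt) {
    at_risk <- table(group[time >= t])
    n <- sum(at_risk)
    d <- table(group[time == t & event])
    dtot <- sum(d)
    O <- O + as.numeric(d)
    e <- dtot * as.numeric(at_risk) / n
    E <- E + e
    if (n > 1) {
      # hypergeometric covariance of the per-group death counts
      nn <- as.numeric(at_risk)
      fac <- dtot * (n - dtot) / (n - 1)
      V <- V + fac * (diag(nn / n) - outer(nn / n, nn / n))
    }
  }
  v <- V[-k, -k, drop = FALSE]
  oe <- (O - E)[-k]
  chi2 <- tryCatch(as.numeric(t(oe) %*% solve(v, oe)),
                   error = function(e) NA_real_)
  df <- k - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Table-5 style survival summary for one SNP
#'
#' Case-processing summary (total, events, censored, percent censored),
#' restricted-mean estimates with standard errors and confidence
#' intervals, and the logrank test across the genotype groups.
#'
#' @inheritParams km_by_genotype
#' @return list: `summary` (data.frame), `logrank` (list).
#' @export
survival_summary <- function(cohort, snp_id, grouping = "carrier") {
  curves <- km_by_genotype(cohort, snp_id, grouping)
  raw <- attr(curves, "raw")
  groups <- attr(curves, "groups")
  tab <- do.call(rbind, lapply(curves, function(cv)
    data.frame(group = cv$group, n_total = cv$n_total,
               n_events = cv$n_events, n_censored = cv$n_censored,
               pct_censored = cv$pct_censored,
               rmean = cv$rmean, rmean_se = cv$rmean_se,
               rmean_ci_low = cv$rmean_ci[1], rmean_ci_high = cv$rmean_ci[2],
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  lr <- if (length(groups) >= 2)
    logrank(raw$time, raw$event, raw$group) else NULL
  list(summary = tab, logrank = lr)
}
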