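#' Subject-level genotype/phenotype container
#'
#' `cohort_data` is the single input object for every analysis stage. It
#' bundles a subject table (case/control status, gender, optional disease
#' subtype and survival columns), a SNP annotation table (gene, position,
#' major/minor alleles, call rate) and a subjects x SNPs genotype matrix
#' coded 0 = major homozygote, 1 = heterozygote, 2 = minor homozygote,
#' `NA` = missing call.
#'
#' @param subjects data.frame with columns `subject_id`, `status`
#'   ("case"/"control"), `gender` ("male"/"female"), and optionally
#'   `subtype` ("B"/"T"/"HD", `NA` for controls or unknown), `surv_time`
#'   (years), `surv_event` (logical, `TRUE` = event).
#' @param snps data.frame with columns `snp_id`, `gene`, `chrom`, `pos`,
#'   `major`, `minor`, `call_rate`.
#' @param genotypes integer matrix, one row per subject, one column per SNP.
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(subjects, snps, genotypes) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!all(c("subject_id", "status", "gender") %in% names(subjects)))
    stop("subjects must have subject_id, status, gender columns")
  for (col in c("subtype", "surv_time", "surv_event"))
    if (!col %in% names(subjects)) subjects[[col]] <- NA
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject identifiers")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP identifiers")
  if (!all(subjects$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (!all(is.na(subjects$subtype) | subjects$subtype %in% c("B", "T", "HD")))
    stop("subtype must be B, T, HD or NA")
  if (any(!is.na(subjects$subtype) & subjects$status != "case"))
    stop("subtype set for a control subject")
  if (any(xor(is.na(subjects$surv_time), is.na(subjects$surv_event))))
    stop("surv_time and surv_event must be present together")
  if (nrow(genotypes) != nrow(subjects) || ncol(genotypes) != nrow(snps))
    stop("genotype matrix dimensions do not match subject/SNP tables")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(!is.na(snps$major) & snps$major == snps$minor))
    stop("major and minor allele identical")
  dimnames(genotypes) <- list(subjects$subject_id, snps$snp_id)
  structure(list(subjects = subjects, snps = snps, genotypes = genotypes),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  st <- table(x$subjects$status)
  cat(sprintf("cohort_data: %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(x$subjects), st[["case"]], st[["control"]],
              nrow(x$snps)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.cohort_data <- function(x) dim(x$genotypes)

.pheno_cols <- c("subject_id", "status", "gender", "subtype",
                 "surv_time", "surv_event")

#' Read a delimited genotype table
#'
#' The file must carry a header with the phenotype columns `subject_id`,
#' `status`, `gender` (optionally `subtype`, `surv_time`, `surv_event`)
#' followed by one column per SNP. Genotype tokens are two-character allele
#' pairs (e.g. `"AG"`), numeric codes 0/1/2, or the declared missing token.
#' The minor allele of each SNP is the less frequent allele among
#' *controls* (ties broken lexicographically: the alphabetically later
#' allele is called minor), so that case enrichment cannot flip codes
#' between analyses.
#'
#' @param path file path.
#' @param sep field delimiter, default tab.
#' @param missing_token token denoting a missing genotype call.
#' @param snp_info optional data.frame of SNP annotation (`snp_id`, `gene`,
#'   `chrom`, `pos`) merged into the result.
#' @return A [cohort_data] object.
#' @export
read_genotype_table <- function(path, sep = "\t", missing_token = "NA",
                                snp_info = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  have <- intersect(.pheno_cols, names(raw))
  if (!all(c("subject_id", "status", "gender") %in% have))
    stop("format error: header must name subject_id, status, gender")
  snp_ids <- setdiff(names(raw), .pheno_cols)
  if (anyDuplicated(names(raw)))
    stop("format error: duplicate column identifiers")
  if (anyDuplicated(raw$subject_id))
    stop("format error: duplicate subject identifiers")
  subjects <- data.frame(subject_id = raw$subject_id,
                         status = raw$status, gender = raw$gender,
                         stringsAsFactors = FALSE)
  subjects$subtype <- if ("subtype" %in% have) {
    s <- raw$subtype; s[s %in% c("", "NA", "none")] <- NA; s
  } else NA
  subjects$surv_time <- if ("surv_time" %in% have)
    suppressWarnings(as.numeric(ifelse(raw$surv_time %in% c("", "NA"),
                                       NA, raw$surv_time))) else NA
  subjects$surv_event <- if ("surv_event" %in% have) {
    ev <- raw$surv_event
    out <- rep(NA, length(ev))
    out[ev %in% c("event", "TRUE", "1")] <- TRUE
    out[ev %in% c("censored", "FALSE", "0")] <- FALSE
    out
  } else NA

  ctrl <- subjects$status == "control"
  n <- nrow(raw)
  geno <- matrix(NA_integer_, n, length(snp_ids))
  major <- minor <- rep(NA_character_, length(snp_ids))
  for (j in seq_along(snp_ids)) {
    tok <- raw[[snp_ids[j]]]
    is_miss <- tok == missing_token
    known <- tok[!is_miss]
    if (all(known %in% c("0", "1", "2"))) {
      geno[, j] <- ifelse(is_miss, NA_integer_, as.integer(tok))
      next
    }
    if (!all(nchar(known) == 2L))
      stop(sprintf("parse error: unknown genotype token '%s' at column %s",
                   known[nchar(known) != 2L][1], snp_ids[j]))
    a1 <- substr(tok, 1, 1); a2 <- substr(tok, 2, 2)
    alleles <- sort(unique(c(a1[!is_miss], a2[!is_miss])))
    if (length(alleles) > 2)
      stop(sprintf("parse error: more than two alleles in column %s",
                   snp_ids[j]))
    if (length(alleles) == 1) alleles <- c(alleles, NA)
    # allele counts among controls decide major/minor
    cnt <- c(sum(a1[ctrl & !is_miss] == alleles[1]) +
               sum(a2[ctrl & !is_miss] == alleles[1]),
             sum(a1[ctrl & !is_miss] == alleles[2]) +
               sum(a2[ctrl & !is_miss] == alleles[2]))
    if (is.na(alleles[2]) || cnt[1] > cnt[2]) {
      major[j] <- alleles[1]; minor[j] <- alleles[2]
    } else if (cnt[1] < cnt[2]) {
      major[j] <- alleles[2]; minor[j] <- alleles[1]
    } else { # tie: alphabetically later allele is called minor
      major[j] <- alleles[1]; minor[j] <- alleles[2]
    }
    g <- (a1 == minor[j]) + (a2 == minor[j])
    g[is_miss] <- NA_integer_
    bad <- !is_miss & !(a1 %in% alleles[!is.na(alleles)] &
                          a2 %in% alleles[!is.na(alleles)])
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("parse error: unknown genotype token '%s' at row %d, column %s",
                   tok[i], i, snp_ids[j]))
    }
    geno[, j] <- as.integer(g)
  }
  snps <- data.frame(snp_id = snp_ids, gene = NA_character_,
                     chrom = NA_character_, pos = NA_integer_,
                     major = major, minor = minor,
                     call_rate = colMeans(!is.na(geno)),
                     stringsAsFactors = FALSE)
  if (!is.null(snp_info)) {
    m <- match(snps$snp_id, snp_info$snp_id)
    for (col in intersect(c("gene", "chrom", "pos"), names(snp_info)))
      snps[[col]] <- snp_info[[col]][m]
  }
  cohort_data(subjects, snps, geno)
}

#' Write a cohort to the delimited genotype format
#'
#' Inverse of [read_genotype_table()]: genotypes are written as allele-pair
#' tokens when both alleles are known, otherwise as numeric 0/1/2 codes.
#'
#' @param cohort a [cohort_data] object.
#' @param path output file path.
#' @param sep field delimiter.
#' @param missing_token token written for missing calls.
#' @export
write_genotype_table <- function(cohort, path, sep = "\t",
                                 missing_token = "NA") {
  sub <- cohort$subjects
  out <- data.frame(subject_id = sub$subject_id, status = sub$status,
                    gender = sub$gender,
                    subtype = ifelse(is.na(sub$subtype), "NA", sub$subtype),
                    surv_time = ifelse(is.na(sub$surv_time), "NA",
                                       format(sub$surv_time, digits = 10)),
                    surv_event = ifelse(is.na(sub$surv_event), "NA",
                                        ifelse(sub$surv_event, "event",
                                               "censored")),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(nrow(cohort$snps))) {
    maj <- cohort$snps$major[j]; min_ <- cohort$snps$minor[j]
    g <- cohort$genotypes[, j]
    tok <- if (is.na(maj) || is.na(min_)) as.character(g) else
      c(paste0(maj, maj), paste0(maj, min_), paste0(min_, min_))[g + 1L]
    tok[is.na(g)] <- missing_token
    out[[cohort$snps$snp_id[j]]] <- tok
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF plus a sample sheet
#'
#' Diploid GT fields are converted to minor-allele dosages: `0/0` -> 0,
#' `0/1` or `1/0` (phased or not) -> 1, `1/1` -> 2, `./.` -> missing.
#' Multi-allelic records are rejected. Case/control status and covariates
#' come from a tab-separated sample sheet with a `subject_id` column
#' matching the VCF sample names.
#'
#' @param path VCF file (may be plain text).
#' @param sample_sheet path to the phenotype TSV.
#' @return A [cohort_data] object.
#' @export
read_vcf <- function(path, sample_sheet) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L))
    stop("unsupported record: multi-allelic site in VCF")
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    bad <- !(x %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    if (any(bad)) stop(sprintf("unsupported GT token '%s'", x[bad][1]))
    out
  }
  geno <- t(apply(gt, 1, code))           # variants x samples
  if (nrow(gt) == 1L) geno <- matrix(geno, nrow = 1L)
  sheet <- utils::read.table(sample_sheet, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  samp <- colnames(gt)
  m <- match(samp, sheet$subject_id)
  if (anyNA(m))
    stop(sprintf("join error: VCF sample '%s' absent from sample sheet",
                 samp[is.na(m)][1]))
  sheet <- sheet[m, , drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    snp_id = rownames(gt),
    gene = NA_character_,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    major = as.character(VariantAnnotation::ref(vcf)),
    minor = vapply(alt, function(a) as.character(a[1]), ""),
    call_rate = rowMeans(!is.na(geno)),
    stringsAsFactors = FALSE)
  cohort_data(sheet, snps, t(geno))
}

#' SNP quality control
#'
#' Removes SNPs failing any of: genotyping call rate below `min_call_rate`,
#' monomorphism (no minor allele observed), or departure from
#' Hardy-Weinberg equilibrium among *controls* at `hwe_alpha`. HWE is
#' tested in controls only so that true case-control association cannot
#' masquerade as a genotyping failure.
#'
#' @param cohort a [cohort_data] object.
#' @param min_call_rate minimum acceptable genotyping call rate.
#' @param hwe_alpha significance level of the control-group HWE chi-square
#'   goodness-of-fit test.
#' @param drop_monomorphic drop SNPs with no observed minor allele.
#' @return list with elements `cohort` (filtered) and `report`
#'   (data.frame: snp_id, reason, statistic, p).
#' @export
apply_qc <- function(cohort, min_call_rate = 0.9, hwe_alpha = 0.05,
                     drop_monomorphic = TRUE) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (nrow(cohort$snps) == 0L) stop("empty cohort")
  ctrl <- cohort$subjects$status == "control"
  rep_rows <- list()
  keep <- rep(TRUE, nrow(cohort$snps))
  for (j in seq_len(nrow(cohort$snps))) {
    id <- cohort$snps$snp_id[j]
    g <- cohort$genotypes[, j]
    cr <- mean(!is.na(g))
    if (cr < min_call_rate) {
      keep[j] <- FALSE
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(snp_id = id, reason = "call_rate", statistic = cr, p = NA)
      next
    }
    counts <- tabulate(g[ctrl & !is.na(g)] + 1L, nbins = 3L)
    mono <- counts[2] + counts[3] == 0L || counts[1] + counts[2] == 0L
    if (drop_monomorphic && mono) {
      keep[j] <- FALSE
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(snp_id = id, reason = "monomorphic", statistic = NA, p = NA)
      next
    }
    if (!mono) {
      h <- hwe_chisq(counts[1], counts[2], counts[3])
      if (!is.na(h$p) && h$p < hwe_alpha) {
        keep[j] <- FALSE
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(snp_id = id, reason = "hwe", statistic = h$chi2, p = h$p)
      }
    }
  }
  if (!any(keep)) stop("empty panel: QC removed every SNP")
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(snp_id = character(), reason = character(),
               statistic = numeric(), p = numeric())
  out <- cohort
  out$snps <- cohort$snps[keep, , drop = FALSE]
  rownames(out$snps) <- NULL
  out$genotypes <- cohort$genotypes[, keep, drop = FALSE]
  list(cohort = out, report = report)
}

#' Restrict a cohort to a case subgroup plus all controls
#'
#' Subgroup analyses keep every control and only the cases of the named
#' subtype; `"overall"` keeps everything.
#'
#' @param cohort a [cohort_data] object.
#' @param subgroup one of `"overall"`, `"B"`, `"T"`, `"HD"`.
#' @export
subgroup_cohort <- function(cohort, subgroup = "overall") {
  subgroup <- match.arg(subgroup, c("overall", "B", "T", "HD"))
  if (subgroup == "overall") return(cohort)
  keep <- cohort$subjects$status == "control" |
    (!is.na(cohort$subjects$subtype) & cohort$subjects$subtype == subgroup)
  out <- cohort
  out$subjects <- cohort$subjects[keep, , drop = FALSE]
  rownames(out$subjects) <- NULL
  out$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  out
}
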