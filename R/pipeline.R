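# FNV-1a hash of a string; used to stamp outputs with their config.
.config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in s) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' A complete, commented-by-documentation run configuration for the
#' bundled study emulation. Fields:
#' \describe{
#'   \item{input}{path to a delimited genotype table, or `NULL` to
#'     simulate the bundled cohort.}
#'   \item{sim}{`list(n_case, n_ctrl)` used when simulating.}
#'   \item{qc}{`list(min_call_rate, hwe_alpha)`.}
#'   \item{subgroups, codings}{association sweep axes.}
#'   \item{fdr_q}{FDR level for each (subgroup x coding) family.}
#'   \item{haplo_blocks}{named list of SNP-id vectors.}
#'   \item{survival_snp}{SNP for the survival stage (`NULL` = skip).}
#'   \item{bn}{`list(enabled, method, snp_preselect, ess, fan_in, iters,
#'     burn_in, thin, chains, subgroup)`; `snp_preselect = 0` analyses
#'     the full panel, a positive k keeps the top-k SNPs by marginal
#'     chi-square dependence on the target (speed).}
#'   \item{effect_snps}{SNPs whose Bayesian OR posteriors are reported.}
#'   \item{seed, out_dir}{run seed and output directory.}
#' }
#' @param out_dir output directory.
#' @param seed run seed.
#' @export
default_run_config <- function(out_dir = tempfile("bnassoc_run_"),
                               seed = 1L) {
  list(input = NULL,
       sim = list(n_case = 543, n_ctrl = 529),
       qc = list(min_call_rate = 0.9, hwe_alpha = 0.05),
       subgroups = c("overall", "HD"),
       codings = c("genotype", "dominant", "recessive", "allelic"),
       fdr_q = 0.05,
       haplo_blocks = list(B2 = c("snp08", "snp09", "snp10", "snp11")),
       survival_snp = "snp50",
       bn = list(enabled = TRUE, method = "mcmc", snp_preselect = 12,
                 ess = 1, fan_in = 3, iters = 6000, burn_in = 1000,
                 thin = 5, chains = 2, subgroup = "overall"),
       effect_snps = c("snp08", "snp01"),
       seed = as.integer(seed),
       out_dir = out_dir)
}

.write_tsv <- function(df, path, stamp = NULL) {
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = !is.null(stamp)))
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - cohort (load or simulate), QC,
#' frequentist association sweeps with FDR, haplotype blocks, survival,
#' Bayesian-network relevance, Bayesian effect size - writing per-stage
#' TSV/JSON artifacts plus a manifest. Every artifact is stamped with the
#' configuration hash; wall-clock timings go to `run.log` so that the
#' analytical outputs of two identically-seeded runs are byte-identical.
#'
#' @param config a configuration list, see [default_run_config()], or a
#'   path to a JSON file with the same fields.
#' @return the manifest (invisibly), a list naming every artifact.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  stamp <- sprintf("config_hash %s seed %d", hash, config$seed)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    log_lines <<- c(log_lines, sprintf("%s\t%.2fs\t%s", name,
                                       proc.time()[["elapsed"]] - s,
                                       if (inherits(res, "error"))
                                         conditionMessage(res) else "ok"))
    if (inherits(res, "error")) stop(sprintf("stage %s failed: %s", name,
                                             conditionMessage(res)))
    res
  }
  manifest <- list(package_version = as.character(utils::packageVersion("bnassoc")),
                   config_hash = hash, seed = config$seed, stages = list())
  artifacts <- character()
  art <- function(x) { artifacts <<- c(artifacts, x); x }

  # --- cohort -------------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$input)) {
      read_genotype_table(config$input)
    } else {
      spec <- default_sim_spec(config$sim$n_case, config$sim$n_ctrl,
                               seed = config$seed)
      simulate_cohort(spec)
    }
  })
  manifest$stages$cohort <- list(n_subjects = nrow(cohort$subjects),
                                 n_snps = nrow(cohort$snps))

  # --- qc -----------------------------------------------------------------
  qc <- stage("qc", apply_qc(cohort, config$qc$min_call_rate,
                             config$qc$hwe_alpha))
  cohort <- qc$cohort
  art(.write_tsv(qc$report, file.path(out, "qc_report.tsv"), stamp))
  manifest$stages$qc <- list(n_removed = nrow(qc$report),
                             n_retained = nrow(cohort$snps))

  # --- association --------------------------------------------------------
  fdr_out <- list()
  for (sg in config$subgroups) for (cd in config$codings) {
    res <- stage(sprintf("assoc_%s_%s", sg, cd),
                 assoc_sweep(cohort, cd, sg))
    art(.write_tsv(res, file.path(out, sprintf("assoc_%s_%s.tsv", sg, cd)), stamp))
    ps <- res$p[!is.na(res$p)]
    names(ps) <- paste(res$snp_id, res$contrast)[!is.na(res$p)]
    if (length(ps))
      fdr_out[[paste(sg, cd, sep = "_")]] <-
        bh_fdr(ps, config$fdr_q)[c("m", "threshold", "significant")]
  }
  manifest$stages$assoc <- list(families = length(fdr_out))
  fdr_out$config_hash <- hash; fdr_out$seed <- config$seed
  jsonlite::write_json(fdr_out, art(file.path(out, "fdr.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- haplotypes ---------------------------------------------------------
  for (bn in names(config$haplo_blocks)) {
    ids <- intersect(config$haplo_blocks[[bn]], cohort$snps$snp_id)
    if (length(ids) < 2) next
    tab <- stage(paste0("haplo_", bn), haplotype_assoc(cohort, ids))
    art(.write_tsv(tab, file.path(out, sprintf("haplo_%s.tsv", bn)), stamp))
  }
  manifest$stages$haplo <- list(blocks = length(config$haplo_blocks))

  # --- survival -----------------------------------------------------------
  if (!is.null(config$survival_snp) &&
      config$survival_snp %in% cohort$snps$snp_id &&
      any(!is.na(cohort$subjects$surv_time))) {
    sv <- stage("survival", survival_summary(cohort, config$survival_snp))
    tab <- sv$summary
    tab$logrank_chi2 <- c(sv$logrank$chi2, rep(NA, nrow(tab) - 1))
    tab$logrank_p <- c(sv$logrank$p, rep(NA, nrow(tab) - 1))
    art(.write_tsv(tab, file.path(out, sprintf("survival_%s.tsv",
                                               config$survival_snp)), stamp))
    manifest$stages$survival <- list(snp = config$survival_snp)
  }

  # --- Bayesian network ---------------------------------------------------
  if (isTRUE(config$bn$enabled)) {
    bncfg <- config$bn
    panel_snps <- stage("bn_preselect", {
      if (bncfg$snp_preselect > 0 &&
          bncfg$snp_preselect < nrow(cohort$snps)) {
        sub <- subgroup_cohort(cohort, bncfg$subgroup)
        y <- sub$subjects$status == "case"
        chi <- vapply(seq_len(nrow(sub$snps)), function(j) {
          g <- sub$genotypes[, j]
          tryCatch(suppressWarnings(
            stats::chisq.test(table(g, y))$statistic), error = function(e) 0)
        }, 0)
        sub$snps$snp_id[order(-chi)[seq_len(bncfg$snp_preselect)]]
      } else cohort$snps$snp_id
    })
    panel <- var_panel(cohort, panel_snps, subgroup = bncfg$subgroup)
    post <- stage("bn_posterior", {
      if (bncfg$method == "exact")
        enumerate_posterior(panel, bncfg$ess, bncfg$fan_in)
      else
        mcmc_posterior(panel, bncfg$ess, bncfg$fan_in, bncfg$iters,
                       bncfg$burn_in, bncfg$thin, bncfg$chains,
                       seed = .derive_seed(config$seed, 11L))
    })
    rel <- stage("relevance", relevance_posteriors(post))
    rel_json <- c(as.list(as.data.frame(rel)),
                  list(config_hash = hash, seed = config$seed))
    jsonlite::write_json(rel_json,
                         art(file.path(out, "relevance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ratios <- stage("pair_ratios", pair_ratio_matrix(post))
    art(.write_tsv(ratios, file.path(out, "pair_ratios.tsv"), stamp))
    map <- interaction_map(post)
    art(write_dot(map, file.path(out, "interaction_map.dot")))
    manifest$stages$bn <- list(method = post$provenance,
                               n_structures = nrow(post$parents),
                               panel_size = length(panel$vars))

    # --- effect size ------------------------------------------------------
    eff_rows <- list()
    for (id in intersect(config$effect_snps, panel$vars)) {
      for (ct in c("het", "hom")) {
        orp <- stage(sprintf("effect_%s_%s", id, ct),
                     structure_or_posterior(panel, post, id, ct))
        seg <- hpd_segments(orp)
        eff_rows[[paste(id, ct)]] <-
          data.frame(snp_id = id, contrast = ct,
                     cr_low = seg$low, cr_high = seg$high,
                     prob_weight = seg$prob_weight)
      }
    }
    if (length(eff_rows))
      art(.write_tsv(do.call(rbind, eff_rows),
                     file.path(out, "effectsize.tsv"), stamp))
    manifest$stages$effectsize <- list(snps = length(config$effect_snps))
  }

  manifest$artifacts <- basename(artifacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("total\t%.2fs", proc.time()[["elapsed"]] - t0),
               log_lines), file.path(out, "run.log"))
  invisible(manifest)
}
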