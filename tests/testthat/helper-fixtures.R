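# Shared fixtures, all generated in code.

# Minimal delimited genotype file: 3 subjects, 2 SNPs, allele-pair tokens.
write_toy_table <- function(path, snp1 = c("AA", "AG", "GG"),
                            snp2 = c("CC", "CC", "CT"),
                            status = c("control", "control", "case")) {
  df <- data.frame(subject_id = c("s1", "s2", "s3"),
                   status = status,
                   gender = c("male", "female", "male"),
                   snp1 = snp1, snp2 = snp2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Cohort built directly from matrices (no file round trip).
toy_cohort <- function(genotypes, status = NULL, gender = NULL,
                       major = "A", minor = "G") {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  if (is.null(gender)) gender <- rep(c("male", "female"), length.out = n)
  cohort_data(
    data.frame(subject_id = paste0("s", seq_len(n)), status = status,
               gender = gender),
    data.frame(snp_id = paste0("snp", seq_len(m)), gene = NA, chrom = NA,
               pos = NA, major = major, minor = minor,
               call_rate = colMeans(!is.na(genotypes))),
    genotypes)
}

# One-SNP case-control cohort with a planted genotype effect, drawn by
# outcome-stratified rejection through the package generator.
planted_cohort <- function(seed, n_case = 543, n_ctrl = 529, maf = 0.3,
                           or_het = sqrt(2), or_hom = 2, extra_null = 0) {
  ids <- c("s1", if (extra_null > 0) paste0("null", seq_len(extra_null)))
  snps <- data.frame(snp_id = ids, gene = NA,
                     maf = c(maf, rep(0.25, extra_null)))
  spec <- sim_spec(n_case, n_ctrl, snps,
                   effects = sim_effects(direct = list(s1 = c(or_het, or_hom))),
                   seed = seed)
  simulate_cohort(spec)
}

# Hand-rolled structure posterior over explicit parent-mask rows.
manual_posterior <- function(parents, weight, vars,
                             card = c(2L, rep(3L, length(vars) - 1L))) {
  structure(list(parents = parents, weight = weight / sum(weight),
                 vars = vars, card = card, target = 1L,
                 provenance = "exact", ess = 1),
            class = "structure_posterior")
}

# Independent per-DAG relevance classification used as an oracle against
# the vectorised implementation: walks edges explicitly.
oracle_classify <- function(parents, target) {
  V <- length(parents)
  pa <- function(v) which(bitwAnd(parents[v], bitwShiftL(1L, 0:(V - 1))) != 0L)
  ch <- which(vapply(seq_len(V), function(v) target %in% pa(v), TRUE))
  sp <- setdiff(unique(unlist(lapply(ch, pa))), target)
  mb <- sort(unique(c(pa(target), ch, sp)))
  anc <- function(v) {
    seen <- integer(0); stack <- v
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      if (x %in% seen) next
      seen <- c(seen, x); stack <- c(stack, pa(x))
    }
    seen
  }
  at <- anc(target)
  list(mb = mb,
       adj = sort(unique(c(pa(target), ch))),
       # associated = shares an ancestor with the target, or is a blanket
       # member (spouses count as associated in the taxonomy)
       dcon = sort(unique(c(mb,
         Filter(function(v) length(intersect(anc(v), at)) > 0,
                setdiff(seq_len(V), target))))))
}
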