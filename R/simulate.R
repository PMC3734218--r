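#' Margin-constant 3x3 penetrance table (pure epistasis)
#'
#' Builds a penetrance table over the 3x3 joint genotypes of two SNPs
#' whose single-SNP margins are *exactly* constant under Hardy-Weinberg
#' genotype distributions at the stated minor allele frequencies, while
#' the joint distribution carries association of the stated strength.
#'
#' The construction is additive: pen(i, j) = p0 + s u_i v_j with u, v the
#' HWE-centred allele dosages (so every margin integrates to p0 exactly),
#' and s chosen so that the most extreme cell's disease odds equal
#' `strength` times the baseline odds. An additive - rather than
#' product-on-the-logit - form is used because exact marginal nullity is
#' the point: this is the Bayesian-network notion of pure interaction
#' (dependence only through the joint).
#'
#' @param strength odds multiplier of the most extreme joint-genotype cell
#'   relative to baseline; must exceed 1.
#' @param maf_a,maf_b minor allele frequencies of the two SNPs.
#' @param p0 baseline penetrance.
#' @param marginal_null if `FALSE`, returns instead a logit-multiplicative
#'   table (product interaction) whose margins are *not* null; useful as a
#'   contrast case.
#' @return 3x3 matrix (rows: SNP A genotype 0/1/2, columns: SNP B) with
#'   attributes `p0`, `maf_a`, `maf_b`.
#' @export
make_pure_interaction_table <- function(strength, maf_a = 0.5, maf_b = 0.5,
                                        p0 = 0.5, marginal_null = TRUE) {
  if (strength <= 1) stop("strength must exceed 1")
  u <- (0:2) - 2 * maf_a
  v <- (0:2) - 2 * maf_b
  if (!marginal_null) {
    tab <- .inv_logit(.logit(p0) + log(strength) * outer(u, v) /
                        max(abs(outer(u, v))))
    dimnames(tab) <- list(paste0("a", 0:2), paste0("b", 0:2))
    attr(tab, "p0") <- p0; attr(tab, "maf_a") <- maf_a
    attr(tab, "maf_b") <- maf_b
    return(tab)
  }
  odds0 <- p0 / (1 - p0)
  p_max <- strength * odds0 / (1 + strength * odds0)
  s <- (p_max - p0) / max(abs(outer(u, v)))
  tab <- p0 + s * outer(u, v)
  if (any(tab <= 0) || any(tab >= 1))
    stop("parameter error: strength too large for penetrances in (0,1)")
  dimnames(tab) <- list(paste0("a", 0:2), paste0("b", 0:2))
  attr(tab, "p0") <- p0
  attr(tab, "maf_a") <- maf_a
  attr(tab, "maf_b") <- maf_b
  tab
}

#' Effect specification for the cohort simulator
#'
#' @param direct named list: `snp_id -> c(or_het, or_hom)` odds ratios on
#'   disease risk relative to the major homozygote.
#' @param interaction_pairs list of `list(a =, b =, table =)` where
#'   `table` is a 3x3 penetrance table (see
#'   [make_pure_interaction_table()]); contributes the table's log-odds
#'   deviation from its baseline to the disease logit.
#' @param spouse_motifs list of `list(child =, parents = c(a, b),
#'   strength =)`: the child SNP is drawn *conditionally* on case status
#'   and the parent genotypes (multiplicative tilt of its HWE
#'   distribution), creating the collider motif in which the parents are
#'   spouses of the target - strong relevance without adjacency. This is
#'   how epistasis detectable as "pure interaction" in a Markov-blanket
#'   sense is planted; a penetrance table on the disease odds would make
#'   both SNPs *parents* of the target instead.
#' @param subtype_mixture proportions of case subtypes, named `B`, `T`,
#'   `HD`; must sum to <= 1 (remainder: unclassified).
#' @param subtype_effects named list `subtype -> named list(snp_id ->
#'   c(or_het, or_hom))`: multiplies the subtype assignment weight of a
#'   case by the genotype odds, planting effects visible only in that
#'   subtype.
#' @param survival `list(snp_id =, hazard_mult = c(m0, m1, m2),
#'   baseline_hazard =, follow_up = c(min, max))`; see
#'   [simulate_survival()].
#' @export
sim_effects <- function(direct = list(), interaction_pairs = list(),
                        spouse_motifs = list(),
                        subtype_mixture = c(B = 0.711, T = 0.144, HD = 0.145),
                        subtype_effects = list(), survival = NULL) {
  if (length(direct) && any(unlist(direct) <= 0))
    stop("odds ratios must be positive")
  if (sum(subtype_mixture) > 1 + 1e-9)
    stop("subtype proportions must sum to <= 1")
  structure(list(direct = direct, interaction_pairs = interaction_pairs,
                 spouse_motifs = spouse_motifs,
                 subtype_mixture = subtype_mixture,
                 subtype_effects = subtype_effects, survival = survival),
            class = "sim_effects")
}

#' Full simulation specification
#'
#' @param n_case,n_ctrl target sample sizes.
#' @param snps data.frame with columns `snp_id`, `gene`, `maf` and
#'   optionally `block_id` (`NA` = unlinked).
#' @param blocks named list: `block_id -> named haplotype-frequency
#'   vector` over 0/1 strings (1 = minor allele), one character per block
#'   SNP in panel order; frequencies must sum to 1.
#' @param effects a [sim_effects] object.
#' @param seed integer seed; identical specs give bit-identical cohorts.
#' @export
sim_spec <- function(n_case, n_ctrl, snps, blocks = list(),
                     effects = sim_effects(), seed = 1L) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!"block_id" %in% names(snps)) snps$block_id <- NA_character_
  if (!"gene" %in% names(snps)) snps$gene <- NA_character_
  stopifnot(all(snps$maf > 0), all(snps$maf <= 0.5))
  used <- unique(snps$block_id[!is.na(snps$block_id)])
  if (!all(used %in% names(blocks)))
    stop("block_id referenced by a SNP has no haplotype table")
  for (b in used) {
    k <- sum(snps$block_id == b, na.rm = TRUE)
    f <- blocks[[b]]
    if (abs(sum(f) - 1) > 1e-9) stop("block haplotype frequencies must sum to 1")
    if (any(nchar(names(f)) != k)) stop("haplotype string length mismatch")
  }
  structure(list(n_case = n_case, n_ctrl = n_ctrl, snps = snps,
                 blocks = blocks, effects = effects, seed = as.integer(seed)),
            class = "sim_spec")
}

# Draw genotype rows for `n` subjects under the spec's population model:
# unlinked SNPs binomial under HWE, block SNPs as two haplotypes per
# subject from the block table.
.draw_genotypes <- function(spec, n) {
  snps <- spec$snps
  m <- nrow(snps)
  G <- matrix(NA_integer_, n, m)
  unl <- which(is.na(snps$block_id))
  for (j in unl) G[, j] <- stats::rbinom(n, 2, snps$maf[j])
  for (b in unique(snps$block_id[!is.na(snps$block_id)])) {
    cols <- which(snps$block_id == b)
    f <- spec$blocks[[b]]
    hmat <- do.call(rbind, strsplit(names(f), ""))
    storage.mode(hmat) <- "integer"
    h1 <- sample.int(length(f), n, replace = TRUE, prob = f)
    h2 <- sample.int(length(f), n, replace = TRUE, prob = f)
    G[, cols] <- hmat[h1, , drop = FALSE] + hmat[h2, , drop = FALSE]
  }
  G
}

# Disease-model logit for a genotype matrix (shared effects only).
.disease_logit <- function(spec, G, beta0 = 0) {
  eff <- spec$effects
  snps <- spec$snps
  lp <- rep(beta0, nrow(G))
  for (id in names(eff$direct)) {
    j <- match(id, snps$snp_id)
    ors <- eff$direct[[id]]
    lp <- lp + log(c(1, ors[1], ors[2]))[G[, j] + 1L]
  }
  for (ip in eff$interaction_pairs) {
    ja <- match(ip$a, snps$snp_id); jb <- match(ip$b, snps$snp_id)
    tab <- ip$table
    p0 <- attr(tab, "p0")
    if (is.null(p0)) p0 <- mean(tab)
    lp <- lp + .logit(tab[cbind(G[, ja] + 1L, G[, jb] + 1L)]) - .logit(p0)
  }
  lp
}

#' Simulate a case-control cohort
#'
#' Outcome-stratified rejection sampling: genotype vectors are drawn from
#' the population model (HWE for unlinked SNPs, haplotype pairs for block
#' SNPs), disease status from a logistic model combining planted direct
#' effects and interaction penetrance deviations, and subjects are
#' accepted until the requested case and control counts are reached. The
#' intercept is a nuisance under outcome-stratified sampling (logistic
#' odds ratios are invariant to it) and defaults to 0 so both outcomes
#' are sampled efficiently. Case subtypes are assigned by a multinomial
#' draw whose weights can depend on genotype (subtype-specific effects).
#' Spouse-motif child SNPs are then re-drawn conditionally on status and
#' parent genotypes. If a survival specification is present, censored
#' survival is attached to the cases.
#'
#' @param spec a [sim_spec] object.
#' @param beta0 disease-model intercept (log-odds).
#' @param max_tries cap on sampling rounds before declaring the case
#'   count unattainable.
#' @return A [cohort_data] object; deterministic given `spec$seed`.
#' @export
simulate_cohort <- function(spec, beta0 = 0, max_tries = 200L) {
  stopifnot(inherits(spec, "sim_spec"))
  .rng_local(spec$seed, {
    snps <- spec$snps
    m <- nrow(snps)
    need_case <- spec$n_case; need_ctrl <- spec$n_ctrl
    batch <- max(1000L, 2L * (need_case + need_ctrl))
    Gc <- Gk <- NULL
    tries <- 0L
    while ((is.null(Gc) || nrow(Gc) < need_case ||
            nrow(Gk) < need_ctrl) && tries < max_tries) {
      tries <- tries + 1L
      G <- .draw_genotypes(spec, batch)
      pr <- .inv_logit(.disease_logit(spec, G, beta0))
      is_case <- stats::runif(batch) < pr
      Gc <- rbind(Gc, G[is_case, , drop = FALSE])
      Gk <- rbind(Gk, G[!is_case, , drop = FALSE])
    }
    if (nrow(Gc) < need_case || nrow(Gk) < need_ctrl)
      stop("simulation error: could not reach requested case/control counts")
    Gc <- Gc[seq_len(need_case), , drop = FALSE]
    Gk <- Gk[seq_len(need_ctrl), , drop = FALSE]
    G <- rbind(Gc, Gk)
    n <- nrow(G)
    status <- rep(c("case", "control"), c(need_case, need_ctrl))
    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(0.57, 0.43))

    # subtype assignment with genotype-dependent weights
    eff <- spec$effects
    subtype <- rep(NA_character_, n)
    mix <- eff$subtype_mixture
    if (length(mix) && need_case > 0) {
      W <- matrix(rep(mix, each = need_case), need_case, length(mix))
      colnames(W) <- names(mix)
      for (s in names(eff$subtype_effects)) {
        for (id in names(eff$subtype_effects[[s]])) {
          j <- match(id, snps$snp_id)
          ors <- eff$subtype_effects[[s]][[id]]
          W[, s] <- W[, s] * c(1, ors[1], ors[2])[Gc[, j] + 1L]
        }
      }
      resid <- pmax(0, 1 - sum(mix))
      W <- cbind(W, none = resid)
      picks <- apply(W, 1, function(w)
        sample(colnames(W), 1, prob = w / sum(w)))
      subtype[seq_len(need_case)] <- ifelse(picks == "none", NA, picks)
    }

    # spouse motifs: redraw child SNP | status, parent genotypes.
    # The child's log-distribution is tilted by three components: an
    # LD-like main dependence on each parent genotype (`ld`), a direct
    # case-control dependence (`direct`, making the child itself a
    # strongly relevant edge variable), and a target-by-parent
    # interaction of log-odds scale log(strength)/2. The parents'
    # joint distribution with the target is untouched, so they remain
    # exactly marginally independent of case status - strong relevance
    # can arise only through the collider child.
    y <- as.integer(status == "case")
    for (mo in eff$spouse_motifs) {
      jc <- match(mo$child, snps$snp_id)
      jp <- match(mo$parents, snps$snp_id)
      ld <- if (is.null(mo$ld)) 1 else mo$ld
      direct <- if (is.null(mo$direct)) 0.5 else mo$direct
      lam <- log(mo$strength) / 2
      h <- stats::dbinom(0:2, 2, snps$maf[jc])
      u_t <- 2 * y - 1
      w_ab <- rowSums(G[, jp, drop = FALSE] -
                        matrix(2 * snps$maf[jp], n, length(jp), byrow = TRUE))
      xc <- (0:2) - 2 * snps$maf[jc]
      for (i in seq_len(n)) {
        tilt <- exp(xc * (ld * w_ab[i] + direct * u_t[i] +
                            lam * u_t[i] * w_ab[i] / 2))
        pc <- h * tilt
        G[i, jc] <- sample(0:2, 1, prob = pc / sum(pc))
      }
    }

    subjects <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                           status = status, gender = gender,
                           subtype = subtype,
                           surv_time = NA_real_, surv_event = NA,
                           stringsAsFactors = FALSE)
    snp_tab <- data.frame(snp_id = snps$snp_id, gene = snps$gene,
                          chrom = NA_character_, pos = NA_integer_,
                          major = "A", minor = "G",
                          call_rate = 1, stringsAsFactors = FALSE)
    cohort <- cohort_data(subjects, snp_tab, G)
    if (!is.null(eff$survival))
      cohort <- simulate_survival(cohort, eff,
                                  seed = .derive_seed(spec$seed, 7L))
    cohort
  })
}

#' Baseline hazard giving a target censored fraction
#'
#' Solves for the exponential baseline hazard under which the expected
#' censored fraction (administrative censoring at a follow-up drawn
#' uniformly on `follow_up`) equals `censor_frac`, ignoring genotype
#' hazard multipliers.
#'
#' @param censor_frac target fraction censored.
#' @param follow_up `c(min, max)` follow-up years.
#' @export
calibrate_baseline_hazard <- function(censor_frac = 0.85,
                                      follow_up = c(2, 20)) {
  expected_cens <- function(h) {
    stats::integrate(function(c) exp(-h * c), follow_up[1], follow_up[2])$value /
      diff(follow_up)
  }
  stats::uniroot(function(h) expected_cens(h) - censor_frac,
                 c(1e-6, 5))$root
}

#' Attach censored survival to the cases of a cohort
#'
#' Exponential event times with a genotype-dependent hazard
#' (`baseline_hazard * hazard_mult[genotype + 1]` for the named SNP) and
#' administrative censoring at a follow-up time drawn uniformly on
#' `follow_up` (staggered accrual). The censored fraction is controlled
#' by the baseline hazard; see [calibrate_baseline_hazard()].
#'
#' @param cohort a [cohort_data] with cases.
#' @param effects a [sim_effects] whose `survival` element is
#'   `list(snp_id, hazard_mult, baseline_hazard, follow_up)`.
#' @param seed integer seed.
#' @return the cohort with `surv_time` / `surv_event` filled for cases.
#' @export
simulate_survival <- function(cohort, effects, seed = 1L) {
  sv <- effects$survival
  if (is.null(sv)) stop("effects carry no survival specification")
  cases <- which(cohort$subjects$status == "case")
  if (!length(cases)) stop("cohort has no cases")
  fu <- if (is.null(sv$follow_up)) c(2, 20) else sv$follow_up
  .rng_local(seed, {
    mult <- rep(1, length(cases))
    if (!is.null(sv$snp_id)) {
      j <- match(sv$snp_id, cohort$snps$snp_id)
      g <- cohort$genotypes[cases, j]
      mult <- sv$hazard_mult[ifelse(is.na(g), 1L, g + 1L)]
    }
    tev <- stats::rexp(length(cases), rate = sv$baseline_hazard * mult)
    cens <- stats::runif(length(cases), fu[1], fu[2])
    cohort$subjects$surv_time[cases] <- pmin(tev, cens)
    cohort$subjects$surv_event[cases] <- tev <= cens
  })
  cohort
}

#' Read or write a simulation specification as JSON
#'
#' Human-editable round trip for [sim_spec()]: `write_sim_spec()`
#' serialises a spec; `read_sim_spec()` rebuilds it (re-validating all
#' invariants). Penetrance tables are stored as flat 9-vectors in
#' row-major genotype order with their baseline.
#'
#' @param spec a [sim_spec].
#' @param path JSON file path.
#' @export
write_sim_spec <- function(spec, path) {
  eff <- spec$effects
  ser <- list(
    n_case = spec$n_case, n_ctrl = spec$n_ctrl, seed = spec$seed,
    snps = spec$snps, blocks = lapply(spec$blocks, as.list),
    effects = list(
      direct = eff$direct,
      interaction_pairs = lapply(eff$interaction_pairs, function(ip)
        list(a = ip$a, b = ip$b, table = as.vector(ip$table),
             p0 = attr(ip$table, "p0"))),
      spouse_motifs = eff$spouse_motifs,
      subtype_mixture = as.list(eff$subtype_mixture),
      subtype_effects = eff$subtype_effects,
      survival = eff$survival))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  ip <- lapply(seq_along(s$effects$interaction_pairs$a), function(i) {
    tab <- matrix(s$effects$interaction_pairs$table[[i]], 3, 3)
    attr(tab, "p0") <- s$effects$interaction_pairs$p0[i]
    list(a = s$effects$interaction_pairs$a[i],
         b = s$effects$interaction_pairs$b[i], table = tab)
  })
  sm <- s$effects$spouse_motifs
  motifs <- if (is.data.frame(sm))
    lapply(seq_len(nrow(sm)), function(i)
      list(child = sm$child[i], parents = sm$parents[[i]],
           strength = sm$strength[i])) else sm
  eff <- sim_effects(direct = as.list(s$effects$direct),
                     interaction_pairs = ip,
                     spouse_motifs = motifs,
                     subtype_mixture = unlist(s$effects$subtype_mixture),
                     subtype_effects = lapply(s$effects$subtype_effects,
                                              as.list),
                     survival = s$effects$survival)
  sim_spec(s$n_case, s$n_ctrl, s$snps,
           blocks = lapply(s$blocks, unlist), effects = eff, seed = s$seed)
}

#' Bundled study-emulation specification
#'
#' A ready-made [sim_spec] emulating the structure of a folate-pathway
#' candidate-gene study: 543 cases / 529 controls, 64 polymorphic SNPs in
#' 15 genes, one 7-SNP LD block with a tagSNP (one haplotype pair carries
#' the minor alleles together so a single SNP determines the others), one
#' 4-SNP haplotype block, two planted direct effects (genotype ORs 1.5
#' and 2.0, the latter visible mainly through the homozygote), one
#' spouse-motif epistatic triplet, a subtype-specific effect confined to
#' the hyperdiploid subgroup, and censored survival with an 85 percent
#' overall survival target.
#'
#' @param n_case,n_ctrl sample sizes.
#' @param seed integer seed.
#' @return a [sim_spec].
#' @export
default_sim_spec <- function(n_case = 543, n_ctrl = 529, seed = 1L) {
  genes <- c("GENE01", "GENE02", "GENE03", "GENE04", "GENE05", "GENE06",
             "GENE07", "GENE08", "GENE09", "GENE10", "GENE11", "GENE12",
             "GENE13", "GENE14", "GENE15")
  # 64 SNPs spread over 15 genes; first 7 form block B1, next 4 block B2
  n_snp <- 64
  gene_of <- rep(genes, times = c(7, 4, rep(5, 13)))[seq_len(n_snp)]
  maf <- rep(c(0.12, 0.2, 0.28, 0.35, 0.42, 0.3, 0.25, 0.18), length.out = n_snp)
  snps <- data.frame(snp_id = sprintf("snp%02d", seq_len(n_snp)),
                     gene = gene_of, maf = maf,
                     block_id = NA_character_, stringsAsFactors = FALSE)
  snps$block_id[1:7] <- "B1"
  snps$block_id[8:11] <- "B2"
  snps$gene[1:7] <- "GENE01"
  snps$gene[8:11] <- "GENE02"

  # B1: tagSNP structure - minor allele of snp01 tags the minors of the
  # other six (two major haplotypes at 0.70/0.25 plus a recombinant).
  b1 <- c("0000000" = 0.70, "1111111" = 0.25, "0000011" = 0.05)
  # B2: 4-SNP block with four common haplotypes
  b2 <- c("0000" = 0.40, "1010" = 0.29, "0110" = 0.17, "0001" = 0.14)
  snps$maf[1:7] <- NA  # implied by haplotype tables
  snps$maf[1:7] <- vapply(1:7, function(s)
    sum(b1[substr(names(b1), s, s) == "1"]), 0)
  snps$maf[8:11] <- vapply(1:4, function(s)
    sum(b2[substr(names(b2), s, s) == "1"]), 0)

  eff <- sim_effects(
    direct = list(snp08 = c(1.5, 2.0),   # block-2 lead SNP
                  snp01 = c(1.1, 0.55)), # tagSNP, protective homozygote
    spouse_motifs = list(list(child = "snp20", parents = c("snp25", "snp30"),
                              strength = 3)),
    subtype_mixture = c(B = 0.711, T = 0.144, HD = 0.145),
    subtype_effects = list(HD = list(snp40 = c(1.6, 2.4))),
    survival = list(snp_id = "snp50", hazard_mult = c(1, 2, 2),
                    baseline_hazard = calibrate_baseline_hazard(0.87),
                    follow_up = c(2, 20)))
  sim_spec(n_case, n_ctrl, snps, blocks = list(B1 = b1, B2 = b2),
           effects = eff, seed = seed)
}
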