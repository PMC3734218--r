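#' Markov blanket of a variable in a DAG
#'
#' Parents, children and the children's other parents; conditioning on
#' this set renders the variable independent of everything else in the
#' network.
#'
#' @param parents integer vector of parent bitmasks (one per variable).
#' @param target variable index.
#' @return integer vector of blanket member indices.
#' @export
markov_blanket <- function(parents, target) {
  V <- length(parents)
  pa <- .mask_vars(parents[target], V)
  ch <- which(vapply(seq_len(V), function(v)
    .in_mask(parents[v], target), TRUE))
  sp <- unlist(lapply(ch, function(c) .mask_vars(parents[c], V)))
  sort(setdiff(unique(c(pa, ch, sp)), target))
}

#' Multilevel relevance posteriors from a structure posterior
#'
#' Turns a posterior over DAGs into per-variable posteriors of the
#' structural relevance types with respect to the target:
#' \describe{
#'   \item{p_strong}{strong relevance - membership in the target's Markov
#'     blanket (the variable directly influences the target or shields it
#'     jointly with a child);}
#'   \item{p_edge}{direct strong relevance - adjacency to the target;}
#'   \item{p_pure_interaction}{blanket membership without adjacency (a
#'     spouse: co-parent of a common child, effect only jointly);}
#'   \item{p_association}{association with the target - marginal
#'     d-connection (common-ancestor criterion) or blanket membership
#'     (spouses are d-separated marginally but count as associated, so
#'     the transitive remainder below stays nonnegative);}
#'   \item{p_transitive}{association fully mediated by strongly relevant
#'     variables: `p_association - p_strong`.}
#' }
#'
#' @param post a `structure_posterior`.
#' @return object of class `relevance_report`: data.frame with one row
#'   per non-target variable plus attributes linking the posterior.
#' @export
relevance_posteriors <- function(post) {
  stopifnot(inherits(post, "structure_posterior"))
  if (abs(sum(post$weight) - 1) > 1e-6)
    stop("posterior weights are not normalised")
  V <- length(post$vars)
  cls <- .classify_structures(post$parents, post$target, V)
  w <- post$weight
  vars <- setdiff(seq_len(V), post$target)
  rep <- data.frame(
    variable = post$vars[vars],
    p_strong = as.numeric(t(cls$in_mb[, vars, drop = FALSE]) %*% w),
    p_edge = as.numeric(t(cls$in_adj[, vars, drop = FALSE]) %*% w),
    p_pure_interaction =
      as.numeric(t(cls$in_spouse_only[, vars, drop = FALSE]) %*% w),
    p_association = as.numeric(t(cls$dcon[, vars, drop = FALSE]) %*% w),
    stringsAsFactors = FALSE)
  rep$p_transitive <- pmax(0, rep$p_association - rep$p_strong)
  structure(rep, class = c("relevance_report", "data.frame"),
            target = post$vars[post$target],
            provenance = post$provenance)
}

#' Interaction / redundancy ratio of a variable pair
#'
#' The posterior probability that both variables are strongly relevant
#' simultaneously, divided by the product of their marginal
#' strong-relevance posteriors. A ratio above 1 means the pair occurs in
#' strongly relevant sets together more often than independent relevance
#' would predict (statistical interaction); below 1, the variables tend
#' to be interchangeable (redundancy).
#'
#' @param post a `structure_posterior`.
#' @param a,b variable names or indices.
#' @param tau neutrality band half-width: ratio > 1 + tau labels
#'   interaction, < 1 - tau redundancy.
#' @return list: `pair`, `p_joint`, `p_a`, `p_b`, `ratio`, `label`.
#' @export
pair_ratio <- function(post, a, b, tau = 0.05) {
  V <- length(post$vars)
  ia <- if (is.character(a)) match(a, post$vars) else a
  ib <- if (is.character(b)) match(b, post$vars) else b
  if (is.na(ia) || is.na(ib)) stop("unknown variable")
  cls <- .classify_structures(post$parents, post$target, V)
  w <- post$weight
  p_a <- sum(w[cls$in_mb[, ia]])
  p_b <- sum(w[cls$in_mb[, ib]])
  if (p_a == 0 || p_b == 0)
    stop("undefined ratio: a marginal strong-relevance posterior is zero")
  p_joint <- sum(w[cls$in_mb[, ia] & cls$in_mb[, ib]])
  ratio <- p_joint / (p_a * p_b)
  label <- if (ratio > 1 + tau) "interaction" else
    if (ratio < 1 - tau) "redundancy" else "neutral"
  list(pair = post$vars[c(ia, ib)], p_joint = p_joint,
       p_a = p_a, p_b = p_b, ratio = ratio, label = label)
}

#' Pairwise interaction/redundancy ratio matrix
#'
#' @param post a `structure_posterior`.
#' @param min_strong only variables with `p_strong` above this enter the
#'   matrix (ratios of never-relevant variables are noise).
#' @param tau neutrality band, see [pair_ratio()].
#' @return data.frame of pairs with ratio and label.
#' @export
pair_ratio_matrix <- function(post, min_strong = 0.05, tau = 0.05) {
  rep <- relevance_posteriors(post)
  keep <- rep$variable[rep$p_strong >= min_strong]
  if (length(keep) < 2)
    return(data.frame(a = character(), b = character(), p_joint = numeric(),
                      ratio = numeric(), label = character()))
  combos <- utils::combn(keep, 2)
  do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    pr <- pair_ratio(post, combos[1, i], combos[2, i], tau)
    data.frame(a = pr$pair[1], b = pr$pair[2], p_joint = pr$p_joint,
               p_a = pr$p_a, p_b = pr$p_b, ratio = pr$ratio,
               label = pr$label, stringsAsFactors = FALSE)
  }))
}

#' Posterior interaction map around the target
#'
#' Nodes are the target plus every variable whose strong-relevance
#' posterior reaches the threshold; edge weights are posterior directed
#' adjacency probabilities restricted to these nodes. Edges state
#' probabilistic, not causal, relationships.
#'
#' @param post a `structure_posterior`.
#' @param min_strong strong-relevance threshold for inclusion.
#' @param min_edge_posterior drop edges below this posterior.
#' @return object of class `interaction_map`: list with `nodes`
#'   (data.frame: name, p_strong) and `edges` (data.frame: from, to,
#'   weight).
#' @export
interaction_map <- function(post, min_strong = 0.2,
                            min_edge_posterior = 0.05) {
  rep <- relevance_posteriors(post)
  V <- length(post$vars)
  keep_idx <- c(post$target,
                match(rep$variable[rep$p_strong >= min_strong], post$vars))
  nodes <- data.frame(
    name = post$vars[keep_idx],
    p_strong = c(1, rep$p_strong[rep$p_strong >= min_strong]),
    stringsAsFactors = FALSE)
  edges <- NULL
  for (u in keep_idx) for (v in keep_idx) {
    if (u == v) next
    wgt <- sum(post$weight[bitwAnd(post$parents[, v], .bit(u)) != 0L])
    if (wgt >= min_edge_posterior)
      edges <- rbind(edges, data.frame(from = post$vars[u],
                                       to = post$vars[v],
                                       weight = wgt,
                                       stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  structure(list(nodes = nodes, edges = edges,
                 target = post$vars[post$target]),
            class = "interaction_map")
}

#' Write an interaction map as a DOT graph
#'
#' @param map an [interaction_map()] result.
#' @param path output file.
#' @export
write_dot <- function(map, path) {
  lines <- c("digraph interaction_map {",
             sprintf('  "%s" [shape=box, color=red];', map$target),
             vapply(setdiff(map$nodes$name, map$target),
                    function(n) sprintf('  "%s";', n), ""),
             vapply(seq_len(nrow(map$edges)), function(i)
               sprintf('  "%s" -> "%s" [penwidth=%.2f, label="%.2f"];',
                       map$edges$from[i], map$edges$to[i],
                       0.5 + 4 * map$edges$weight[i], map$edges$weight[i]),
               ""),
             "}")
  writeLines(lines, path)
  invisible(path)
}
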