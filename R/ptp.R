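# Poisson tree process delimitation: branch lengths (expected substitutions)
# fall into two exponential classes, between-species and within-species.  A
# candidate delimitation is an antichain of nodes whose clades partition the
# tips; branches inside a delimited clade are "within", all others
# "between".  Zero-length branches are excluded from the likelihood (counted
# and reported).  The null model is a single exponential class.

# Per-node aggregates over nonzero-length subtree edges: count and length sum.
.ptp_node_stats <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  cnt <- integer(nn); s <- numeric(nn)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    len <- phy$edge.length[e]
    add_c <- cnt[ch]; add_s <- s[ch]
    if (len > 0) { add_c <- add_c + 1L; add_s <- add_s + len }
    cnt[par] <- cnt[par] + add_c
    s[par] <- s[par] + add_s
  }
  n_zero <- sum(phy$edge.length == 0)
  root <- ntip + 1L
  list(cnt = cnt, s = s, total_cnt = cnt[root], total_s = s[root],
       n_zero = n_zero, phy = phy)
}

# exponential class log-likelihood at its MLE rate: n log(n/S) - n
.exp_class_ll <- function(n, S) if (n == 0) 0 else n * (log(n / S) - 1)

# log-likelihood of an antichain (vector of cluster-root node ids) given
# precomputed node stats; returns list(logL, rate_within, rate_between,
# within_empty)
.ptp_score <- function(stats, roots) {
  nw <- sum(stats$cnt[roots]); sw <- sum(stats$s[roots])
  nb <- stats$total_cnt - nw; sb <- stats$total_s - sw
  within_empty <- nw == 0
  ll <- .exp_class_ll(nw, sw) + .exp_class_ll(nb, sb)
  list(logL = ll,
       rate_within = if (nw > 0) nw / sw else NA_real_,
       rate_between = if (nb > 0) nb / sb else NA_real_,
       within_empty = within_empty)
}

#' PTP log-likelihood of a given partition
#'
#' Each cluster must be a clade (its tips' most recent common ancestor
#' subtends exactly the cluster). Branches inside a delimited clade are
#' within-species, all others between-species; each class is exponential at
#' its maximum-likelihood rate (class size / class length sum).
#' Zero-length branches are excluded as non-informative. If the within
#' class is empty (all clusters singletons short of the full-tree case) the
#' likelihood is computed over the between class only and flagged.
#'
#' @param tree a [gene_tree()] or `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param partition a [cluster_partition()], or a list of tip-label /
#'   specimen-id vectors.
#' @return list with `logL`, `rate_within`, `rate_between`, `n_zero`
#'   (excluded zero-length branches), `within_empty`.
#' @export
ptp_loglik <- function(tree, partition) {
  gt <- if (inherits(tree, "gene_tree")) tree else gene_tree(tree, gene = NA)
  phy <- gt$phy
  clusters <- if (inherits(partition, "cluster_partition"))
    partition$clusters else partition
  # map specimen ids back to tips
  id2tip <- setNames(rep(names(gt$tip_map), lengths(gt$tip_map)),
                     unlist(gt$tip_map, use.names = FALSE))
  roots <- vapply(clusters, function(cl) {
    tips <- unique(unname(id2tip[as.character(cl)]))
    if (anyNA(tips)) stop("partition names not in tree", call. = FALSE)
    idx <- match(tips, phy$tip.label)
    if (length(idx) == 1L) return(idx)
    m <- ape::getMRCA(phy, idx)
    if (length(.clade_tips_idx(phy, m)) != length(idx))
      stop("cluster is not a clade: ", paste(head(tips, 4), collapse = ","),
           call. = FALSE)
    m
  }, 0L)
  stats <- .ptp_node_stats(phy)
  sc <- .ptp_score(stats, roots)
  c(sc, list(n_zero = stats$n_zero))
}

# enumerate all antichains (as lists of node-id vectors) partitioning the
# tips of the subtree below `node`
.enumerate_antichains <- function(phy, node, ntip) {
  if (node <= ntip) return(list(node))
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  kid_sets <- lapply(kids, .enumerate_antichains, phy = phy, ntip = ntip)
  combos <- Reduce(function(a, b) {
    out <- list()
    for (x in a) for (y in b) out[[length(out) + 1L]] <- c(x, y)
    out
  }, kid_sets)
  c(list(node), combos)
}

#' Exact maximum-likelihood PTP by exhaustive enumeration
#'
#' Enumerates every partition of the tree into clades (every antichain of
#' nodes covering all tips) and returns the maximum-likelihood one. Usable
#' as an oracle on small trees only.
#'
#' @param tree a [gene_tree()] or `phylo`; at most `max_tips` tips.
#' @param df degrees of freedom for the LRT against the one-class null
#'   (default 1: one extra rate).
#' @param max_tips refusal limit for the enumeration.
#' @return object of class `ptp_fit`: `partition` ([cluster_partition()]),
#'   `rate_between`, `rate_within`, `logL`, `null_logL`, `lrt_pvalue`,
#'   `df`, `n_zero`, `n_partitions` (number of candidates enumerated).
#' @export
fit_ptp_exact <- function(tree, df = 1, max_tips = 12L) {
  gt <- if (inherits(tree, "gene_tree")) tree else gene_tree(tree, gene = NA)
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("fit_ptp_exact: need at least 2 tips", call. = FALSE)
  if (ntip > max_tips)
    stop("fit_ptp_exact: ", ntip, " tips exceeds the enumeration limit (",
         max_tips, "); use fit_ptp_heuristic()", call. = FALSE)
  stats <- .ptp_node_stats(phy)
  root <- ntip + 1L
  antichains <- .enumerate_antichains(stats$phy, root, ntip)
  best <- NULL
  for (ac in antichains) {
    sc <- .ptp_score(stats, ac)
    if (is.null(best) || sc$logL > best$sc$logL + 1e-12)
      best <- list(roots = ac, sc = sc)
  }
  .ptp_result(gt, stats, best$roots, best$sc, df,
              n_partitions = length(antichains))
}

# random antichain: from the root, stop at each node with prob `p_stop`
.random_antichain <- function(phy, ntip, p_stop = 0.5) {
  out <- integer(0)
  stack <- ntip + 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip || runif(1) < p_stop) out <- c(out, v)
    else stack <- c(stack, phy$edge[phy$edge[, 1] == v, 2])
  }
  out
}

#' Heuristic maximum-likelihood PTP by hill-climbing over clade cuts
#'
#' Greedy search over antichains: from each start, repeatedly applies the
#' single best split (replace a cluster root by its children) or merge
#' (replace a complete sibling group by its parent) until no move improves
#' the likelihood. Starts are the one-cluster null, the all-singleton
#' partition, and seeded random antichains. Deterministic given `seed`.
#'
#' @param tree a [gene_tree()] or `phylo`, at least 2 tips.
#' @param seed integer seed.
#' @param n_restarts number of random restarts in addition to the two
#'   deterministic starts.
#' @param df LRT degrees of freedom (default 1).
#' @return a `ptp_fit` (see [fit_ptp_exact()]); `n_partitions` is `NA`.
#' @export
fit_ptp_heuristic <- function(tree, seed = 1L, n_restarts = 5L, df = 1) {
  gt <- if (inherits(tree, "gene_tree")) tree else gene_tree(tree, gene = NA)
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("fit_ptp_heuristic: need at least 2 tips", call. = FALSE)
  set.seed(seed)
  stats <- .ptp_node_stats(phy)
  phy <- stats$phy
  root <- ntip + 1L
  parent_of <- integer(ntip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]

  climb <- function(roots) {
    sc <- .ptp_score(stats, roots)
    repeat {
      best_move <- NULL
      # splits
      for (i in seq_along(roots)) {
        v <- roots[i]
        if (v <= ntip) next
        kids <- phy$edge[phy$edge[, 1] == v, 2]
        cand <- c(roots[-i], kids)
        s2 <- .ptp_score(stats, cand)
        if (s2$logL > sc$logL + 1e-10 &&
            (is.null(best_move) || s2$logL > best_move$sc$logL))
          best_move <- list(roots = cand, sc = s2)
      }
      # merges
      pars <- unique(parent_of[roots])
      pars <- pars[pars != 0]
      for (p in pars) {
        kids <- phy$edge[phy$edge[, 1] == p, 2]
        if (!all(kids %in% roots)) next
        cand <- c(setdiff(roots, kids), p)
        s2 <- .ptp_score(stats, cand)
        if (s2$logL > sc$logL + 1e-10 &&
            (is.null(best_move) || s2$logL > best_move$sc$logL))
          best_move <- list(roots = cand, sc = s2)
      }
      if (is.null(best_move)) break
      roots <- best_move$roots
      sc <- best_move$sc
    }
    list(roots = roots, sc = sc)
  }

  starts <- list(root, seq_len(ntip))
  for (r in seq_len(n_restarts))
    starts[[length(starts) + 1L]] <- .random_antichain(phy, ntip)
  best <- NULL
  for (s in starts) {
    res <- climb(s)
    if (is.null(best) || res$sc$logL > best$sc$logL + 1e-12) best <- res
  }
  .ptp_result(gt, stats, best$roots, best$sc, df, n_partitions = NA_integer_)
}

.ptp_result <- function(gt, stats, roots, sc, df, n_partitions) {
  phy <- stats$phy
  tip_clusters <- lapply(roots, function(v) .clade_tips(phy, v))
  spec_clusters <- .expand_tips(gt, tip_clusters)
  part <- cluster_partition(spec_clusters,
                            gene = if (is.null(gt$gene)) NA else gt$gene,
                            method = "PTP")
  null_ll <- .exp_class_ll(stats$total_cnt, stats$total_s)
  lrt <- 2 * (sc$logL - null_ll)
  structure(list(
    partition = part, tip_clusters = tip_clusters,
    rate_between = sc$rate_between, rate_within = sc$rate_within,
    logL = sc$logL, null_logL = null_ll,
    lrt_pvalue = pchisq(max(lrt, 0), df = df, lower.tail = FALSE),
    df = df, n_zero = stats$n_zero, within_empty = sc$within_empty,
    n_partitions = n_partitions), class = "ptp_fit")
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat("PTP maximum-likelihood fit\n")
  cat(sprintf("  clusters    : %d\n", length(x$partition$clusters)))
  cat(sprintf("  logL        : %.4f (null %.4f)\n", x$logL, x$null_logL))
  cat(sprintf("  LRT p-value : %.4g (df = %d)\n", x$lrt_pvalue, x$df))
  if (x$n_zero > 0)
    cat(sprintf("  zero-length branches excluded: %d\n", x$n_zero))
  if (x$within_empty)
    cat("  note: within class empty; scored on between class only\n")
  invisible(x)
}
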