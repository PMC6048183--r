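# Single-threshold GMYC: a time threshold T splits an ultrametric tree into
# a between-species (Yule-like) zone older than T and within-species
# coalescent zones younger than T.  Branching events and waiting intervals
# follow the coalescent waiting-time construction: intervals run from the
# present toward the root, each terminated at its older end by a node event,
# with lineage counts taken on the younger side of the event.  Per interval
# the total event rate is
#   r_i = lambda_div * k_i^p_div + lambda_coal * sum_j [n_ij (n_ij - 1)]^p_coal
# where k_i is the between-species lineage count (number of delimited
# clusters once the process is younger than T) and n_ij the lineage count
# of cluster j.  The event term is the terminating event's process
# component of r_i (the diversification term for a between-species node,
# the full coalescent sum for a within-species node).  With the threshold
# older than the root the model reduces to the Kingman single-population
# coalescent (the null).

# node ages of an ultrametric tree, indexed by node number (tips age 0)
.node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths[seq_along(phy$tip.label)]) - depths
}

# Collapse near-zero internal branches to soft polytomies, then respread the
# resulting identical node ages by `eps` so every interval has positive
# duration.
.regularize_ages <- function(ages, ntip, eps = 1e-12) {
  node_ages <- ages[(ntip + 1):length(ages)]
  ord <- order(node_ages, decreasing = TRUE)
  sorted <- node_ages[ord]
  for (i in 2:length(sorted)) {
    if (i <= length(sorted) && sorted[i] >= sorted[i - 1] - eps)
      sorted[i] <- sorted[i - 1] - eps
  }
  node_ages[ord] <- sorted
  ages[(ntip + 1):length(ages)] <- node_ages
  ages
}

#' GMYC interval table for a given threshold
#'
#' Orders the internal-node ages of an ultrametric tree and, for each
#' inter-event interval, reports its duration, the between-species lineage
#' count, the per-cluster within-species lineage counts and the terminating
#' event (diversification, coalescence, or none for the interval split at
#' the threshold itself).
#'
#' @param tree a [gene_tree()] or `phylo`; must be ultrametric.
#' @param threshold_age time before present separating within- from
#'   between-species branching.
#' @param tol ultrametricity tolerance.
#' @return list with `x` (durations), `k` (between-species lineage count
#'   per interval), `C` (matrix intervals x clusters of pair products
#'   `n_ij (n_ij - 1)`), `event` (`"div"`, `"coal"`, `"none"`),
#'   `event_size` (the `k_i` or `n_ij (n_ij - 1)` of the terminating
#'   event's subprocess), `clusters` (list of tip labels per cluster).
#' @export
gmyc_interval_table <- function(tree, threshold_age, tol = 1e-6) {
  phy <- if (inherits(tree, "gene_tree")) tree$phy else tree
  if (!is_ultrametric(phy, tol))
    stop("gmyc_interval_table: tree is not ultrametric", call. = FALSE)
  ntip <- length(phy$tip.label)
  ages <- .regularize_ages(.node_ages(phy), ntip)
  node_ids <- (ntip + 1):(ntip + phy$Nnode)
  node_ages <- ages[node_ids]

  # clusters: branches crossing the threshold (parent older, child younger)
  if (threshold_age > max(node_ages)) {
    cluster_roots <- ntip + 1L  # root: one cluster holding everything
  } else {
    cross <- ages[phy$edge[, 1]] > threshold_age &
             ages[phy$edge[, 2]] <= threshold_age
    cluster_roots <- phy$edge[cross, 2]
  }
  clusters <- lapply(cluster_roots, function(v) .clade_tips(phy, v))
  n_cl <- length(clusters)

  # assign each internal node to its cluster (NA = between-species node)
  node_cluster <- rep(NA_integer_, phy$Nnode)
  for (ci in seq_len(n_cl)) {
    v <- cluster_roots[ci]
    if (v <= ntip) next
    desc <- .clade_nodes(phy, v)
    node_cluster[desc - ntip] <- ci
  }

  brk <- sort(unique(c(0, node_ages, threshold_age)))
  brk <- brk[brk <= max(node_ages)]
  if (threshold_age > max(node_ages)) brk <- sort(unique(c(brk, max(node_ages))))
  n_int <- length(brk) - 1L
  x <- diff(brk)
  k <- numeric(n_int)
  C <- matrix(0, n_int, max(n_cl, 1L))
  event <- character(n_int)
  event_size <- numeric(n_int)

  # per-cluster tip counts and node ages
  cl_ntips <- lengths(clusters)
  cl_node_ages <- lapply(seq_len(n_cl), function(ci)
    node_ages[which(node_cluster == ci)])

  for (i in seq_len(n_int)) {
    lo <- brk[i]; hi <- brk[i + 1L]
    mid <- (lo + hi) / 2
    # between-species lineages: tree lineages at mid if mid older than T,
    # else the clusters persist as species lineages
    k[i] <- if (mid > threshold_age) 1L + sum(node_ages > mid) else n_cl
    for (ci in seq_len(n_cl)) {
      n_l <- if (mid > threshold_age) 0L
             else cl_ntips[ci] - sum(cl_node_ages[[ci]] <= mid)
      C[i, ci] <- n_l * (n_l - 1)
    }
    ev <- which(abs(node_ages - hi) < 1e-15)
    if (!length(ev)) { event[i] <- "none"; next }
    ev <- ev[[1]]
    if (node_ages[ev] > threshold_age) {
      event[i] <- "div"
      event_size[i] <- k[i]
    } else {
      event[i] <- "coal"
      event_size[i] <- C[i, node_cluster[ev]]  # the coalescing cluster's pairs
    }
  }
  list(x = x, k = k, C = C, event = event, event_size = event_size,
       clusters = clusters, threshold_age = threshold_age)
}

# internal nodes (ids) in the clade under v, v included
.clade_nodes <- function(phy, v) {
  ntip <- length(phy$tip.label)
  out <- v
  stack <- v
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == u, 2]
    kids <- kids[kids > ntip]
    out <- c(out, kids)
    stack <- c(stack, kids)
  }
  out
}

#' GMYC log-likelihood for a fixed interval table and parameters
#'
#' The survival term integrates the total event rate over every interval;
#' the event term at each branching is the terminating event's process
#' component of the rate: `lambda_div * k_i^p_div` for a between-species
#' node, `lambda_coal * sum_j [n_ij (n_ij - 1)]^p_coal` for a
#' within-species node.
#'
#' @param intervals output of [gmyc_interval_table()].
#' @param lambda_div,lambda_coal process rates (> 0).
#' @param p_div,p_coal rate-scaling exponents.
#' @return log-likelihood.
#' @export
gmyc_loglik <- function(intervals, lambda_div, p_div, lambda_coal, p_coal) {
  stopifnot(lambda_div > 0, lambda_coal > 0)
  it <- intervals
  pwr <- function(v, p) ifelse(v > 0, v^p, 0)
  r_div <- lambda_div * pwr(it$k, p_div)
  Cw <- pwr(it$C, p_coal)
  r_coal <- lambda_coal * if (is.matrix(Cw)) rowSums(Cw) else Cw
  ll <- -sum((r_div + r_coal) * it$x)
  d <- it$event == "div"
  co <- it$event == "coal"
  if (any(d)) ll <- ll + sum(log(r_div[d]))
  if (any(co)) ll <- ll + sum(log(r_coal[co]))
  ll
}

# Profile log-likelihood: rates maximized in closed form given exponents.
# Returns list(logL, lambda_div, lambda_coal).  Sufficient statistics are
# precomputed once per threshold for speed; coal event terms need the
# per-event rows of the pair-product matrix (kept sparse).
.gmyc_profile_stats <- function(it) {
  d <- it$event == "div"; co <- which(it$event == "coal")
  nz <- which(it$C > 0)
  coal_rows <- lapply(co, function(i) { v <- it$C[i, ]; v[v > 0] })
  list(k = it$k, x = it$x,
       cvals = it$C[nz], cx = it$x[row(it$C)[nz]],
       n_div = sum(d), n_coal = length(co),
       k_div = it$k[d], coal_rows = coal_rows)
}

.gmyc_profile_ll <- function(st, p_div, p_coal) {
  ll <- 0; ld <- 0; lc <- 0
  if (st$n_div > 0) {
    A <- sum(st$x * st$k^p_div)
    ld <- st$n_div / A
    ll <- ll + st$n_div * (log(ld) - 1) + p_div * sum(log(st$k_div))
  }
  if (st$n_coal > 0) {
    B <- sum(st$cx * st$cvals^p_coal)
    lc <- st$n_coal / B
    sev <- sum(vapply(st$coal_rows, function(v) log(sum(v^p_coal)), 0))
    ll <- ll + st$n_coal * (log(lc) - 1) + sev
  }
  list(logL = ll, lambda_div = ld, lambda_coal = lc)
}

# maximize the profile likelihood over exponents in [0, 10] with multi-start
# clamped Nelder-Mead; returns list(logL, p_div, p_coal, lambda_div, lambda_coal)
.gmyc_max_threshold <- function(st, n_starts = 3L, p_max = 10) {
  clamp <- function(p) pmin(pmax(p, 0), p_max)
  obj <- function(p) {
    p <- clamp(p)
    -.gmyc_profile_ll(st, p[1], p[2])$logL
  }
  starts <- list(c(1, 1))
  if (n_starts > 1) starts <- c(starts, list(c(0.2, 2), c(3, 0.5)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  p <- clamp(best$par)
  pr <- .gmyc_profile_ll(st, p[1], p[2])
  list(logL = pr$logL, p_div = p[1], p_coal = p[2],
       lambda_div = pr$lambda_div, lambda_coal = pr$lambda_coal)
}

#' Fit the single-threshold GMYC model
#'
#' Scans candidate thresholds placed at midpoints between consecutive
#' distinct node ages (plus one older than the root, which is the
#' single-coalescent null); at each threshold the likelihood is maximized
#' over the four process parameters (rates profiled in closed form,
#' exponents by seeded multi-start Nelder-Mead). Ties between thresholds
#' break toward the older threshold (fewer, more inclusive entities). The
#' likelihood-ratio test against the null uses a chi-square approximation.
#'
#' @param tree a [gene_tree()] (or `phylo`) with an ultrametric tree and at
#'   least 3 tips. If a `gene_tree` carries a tip map, entities are expanded
#'   from haplotype tips to specimen ids; if every tip maps to itself a
#'   warning notes that the tree does not look haplotype-collapsed.
#' @param df degrees of freedom for the LRT (default 2, commonly also 3).
#' @param n_starts optimizer starts per threshold.
#' @param seed seed for optimizer starts (kept for interface stability; the
#'   default starts are deterministic).
#' @param tol ultrametricity tolerance.
#' @return object of class `gmyc_fit`: list with `threshold_age`,
#'   `lambda_div`, `p_div`, `lambda_coal`, `p_coal`, `logL`, `null_logL`,
#'   `lrt_pvalue`, `df`, `entities` (a [cluster_partition()]), and
#'   `n_entities`.
#' @export
fit_gmyc <- function(tree, df = 2, n_starts = 3L, seed = 1L, tol = 1e-6) {
  gt <- if (inherits(tree, "gene_tree")) tree else gene_tree(tree, gene = NA)
  phy <- gt$phy
  if (length(phy$tip.label) < 3)
    stop("fit_gmyc: need at least 3 tips", call. = FALSE)
  if (!is_ultrametric(phy, tol))
    stop("fit_gmyc: tree is not ultrametric", call. = FALSE)
  if (all(lengths(gt$tip_map) == 1L) &&
      all(unlist(gt$tip_map) == names(gt$tip_map)))
    warning("tip map is the identity: tree does not look haplotype-collapsed",
            call. = FALSE)
  set.seed(seed)
  ntip <- length(phy$tip.label)
  ages <- .regularize_ages(.node_ages(phy), ntip)
  node_ages <- sort(unique(ages[(ntip + 1):(ntip + phy$Nnode)]),
                    decreasing = TRUE)
  root_age <- node_ages[[1]]
  mids <- if (length(node_ages) > 1)
    (node_ages[-1] + node_ages[-length(node_ages)]) / 2 else numeric(0)
  # oldest first so ties break toward the older threshold
  cands <- c(root_age * 1.1, mids)

  best <- NULL
  null_fit <- NULL
  failures <- 0L
  for (thr in cands) {
    it <- gmyc_interval_table(phy, thr, tol = tol)
    st <- .gmyc_profile_stats(it)
    mx <- .gmyc_max_threshold(st, n_starts = n_starts)
    if (is.null(mx)) { failures <- failures + 1L; next }
    if (thr > root_age) null_fit <- mx
    if (is.null(best) || mx$logL > best$fit$logL + 1e-9)
      best <- list(threshold = thr, fit = mx, intervals = it)
  }
  if (is.null(best))
    stop("fit_gmyc: optimization failed at every threshold", call. = FALSE)
  if (failures > 0)
    warning(failures, " threshold(s) skipped after optimization failure",
            call. = FALSE)
  if (is.null(null_fit))
    stop("fit_gmyc: null model failed to fit", call. = FALSE)

  tips_clusters <- best$intervals$clusters
  spec_clusters <- .expand_tips(gt, tips_clusters)
  part <- cluster_partition(spec_clusters,
                            gene = if (is.null(gt$gene)) NA else gt$gene,
                            method = "GMYC")
  lrt <- 2 * (best$fit$logL - null_fit$logL)
  structure(list(
    threshold_age = best$threshold,
    lambda_div = best$fit$lambda_div, p_div = best$fit$p_div,
    lambda_coal = best$fit$lambda_coal, p_coal = best$fit$p_coal,
    logL = best$fit$logL, null_logL = null_fit$logL,
    lrt_pvalue = pchisq(max(lrt, 0), df = df, lower.tail = FALSE),
    df = df,
    entities = part, n_entities = length(part$clusters),
    tip_clusters = tips_clusters), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC single-threshold fit\n")
  cat(sprintf("  threshold age : %.6g\n", x$threshold_age))
  cat(sprintf("  entities      : %d\n", x$n_entities))
  cat(sprintf("  logL          : %.4f (null %.4f)\n", x$logL, x$null_logL))
  cat(sprintf("  LRT p-value   : %.4g (df = %d)\n", x$lrt_pvalue, x$df))
  invisible(x)
}
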