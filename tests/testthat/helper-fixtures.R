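# Shared in-code fixtures and independent oracles.

# small hand-checkable trees
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
caterpillar4 <- function()
  ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")

# specimen table builder
make_specimens <- function(ids, stages, species = NULL, genes = NULL) {
  tab <- data.frame(id = ids, stage = stages, stringsAsFactors = FALSE)
  tab$species <- if (is.null(species)) "" else species
  if (!is.null(genes))
    for (g in names(genes)) tab[[paste0("has_", g)]] <- genes[[g]]
  as_specimen_table(tab)
}

# random non-ultrametric rooted tree with exponential branch lengths
random_subst_tree <- function(n, mean_len = 0.1) {
  phy <- ape::rtree(n, rooted = TRUE)
  phy$edge.length <- rexp(length(phy$edge.length), 1 / mean_len)
  phy
}

# --- independent oracles ---------------------------------------------------

# monophyly by exhaustive clade enumeration: walk every node, collect its
# tip set, and look for one that equals the target exactly
oracle_monophyly <- function(phy, target_tips, supports = NULL,
                             support_threshold = 0) {
  ntip <- length(phy$tip.label)
  for (node in seq_len(ntip + phy$Nnode)) {
    tips <- if (node <= ntip) phy$tip.label[node]
            else ape::extract.clade(phy, node)$tip.label
    if (setequal(tips, target_tips)) {
      if (support_threshold == 0) return("yes")
      sup <- if (node == ntip + 1L) 1.0
             else if (!is.null(supports)) supports[node - ntip] else NA_real_
      return(if (!is.na(sup) && sup >= support_threshold) "yes" else "no")
    }
  }
  "no"
}

# number of clade partitions of a rooted tree by direct recursion
# f(tip) = 1;  f(v) = 1 + prod f(children)
oracle_count_clade_partitions <- function(phy, node = NULL) {
  ntip <- length(phy$tip.label)
  if (is.null(node)) node <- ntip + 1L
  if (node <= ntip) return(1)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  1 + prod(vapply(kids, function(k)
    oracle_count_clade_partitions(phy, k), 0))
}

# standard coalescent log-density of an ultrametric genealogy with
# per-ordered-pair rate `lambda` (rate while k lineages: lambda * k * (k-1))
oracle_coalescent_loglik <- function(phy, lambda) {
  bt <- sort(ape::branching.times(phy))
  n <- length(phy$tip.label)
  ages <- c(0, bt)
  ll <- 0
  for (k in n:2) {
    w <- ages[n - k + 2] - ages[n - k + 1]
    r <- lambda * k * (k - 1)
    ll <- ll + log(r) - r * w
  }
  ll
}

# dense grid search over the GMYC exponents at one threshold (rates profiled
# in closed form), finished with a bounded PORT polish from the grid argmax;
# search strategy independent of the package's multi-start Nelder-Mead
oracle_gmyc_grid <- function(phy, threshold, p_max = 10) {
  it <- gmyc_interval_table(phy, threshold)
  st <- stagematch:::.gmyc_profile_stats(it)
  ll <- function(pd, pc) stagematch:::.gmyc_profile_ll(st, pd, pc)$logL
  grid1 <- seq(0, p_max, by = 0.05)
  best <- c(NA, NA, -Inf)
  for (pd in grid1) {
    row <- vapply(grid1, function(pc) ll(pd, pc), 0)
    j <- which.max(row)
    if (row[j] > best[3]) best <- c(pd, grid1[j], row[j])
  }
  pol <- stats::nlminb(best[1:2], function(p) -ll(p[1], p[2]),
                       lower = c(0, 0), upper = c(p_max, p_max))
  max(best[3], -pol$objective)
}

# maximum GMYC log-likelihood over all candidate thresholds by grid oracle
oracle_gmyc_fit <- function(phy) {
  ntip <- length(phy$tip.label)
  ages <- stagematch:::.regularize_ages(stagematch:::.node_ages(phy), ntip)
  na <- sort(unique(ages[(ntip + 1):(ntip + phy$Nnode)]), decreasing = TRUE)
  mids <- if (length(na) > 1) (na[-1] + na[-length(na)]) / 2 else numeric(0)
  cands <- c(na[1] * 1.1, mids)
  max(vapply(cands, function(thr) oracle_gmyc_grid(phy, thr), 0))
}
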