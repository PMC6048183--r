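#' Simulation configuration
#'
#' Describes a two-locus sampling design: a Yule species process, a
#' constant-size single-population coalescent within each species, adult or
#' immature labelling, and per-gene specimen-level missingness. The default
#' genes mirror a nuclear locus (736 bp, most specimens sequenced) and a
#' mitochondrial barcode (658 bp, effective population size one quarter of
#' the nuclear value, faster substitution rate, fewer missing specimens).
#'
#' @param n_species number of species (Yule tips).
#' @param yule_rate speciation rate (events per unit time).
#' @param samples_per_species integer, or vector of length `n_species`.
#' @param larva_fraction probability a specimen is a larva.
#' @param pupa_fraction probability a specimen is a pupa.
#' @param genes named list of per-gene settings; each element a list with
#'   `ne` (coalescent effective-size parameter, time units), `subst_rate`
#'   (substitutions/site/time), `seq_length` (bp), `missing_prob`
#'   (probability a specimen lacks the gene), `rate_jitter_cv`
#'   (coefficient of variation of per-branch Gamma rate multipliers;
#'   0 disables).
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_species = 10,
                       yule_rate = 1,
                       samples_per_species = 5,
                       larva_fraction = 0.6,
                       pupa_fraction = 0.015,
                       genes = list(
                         CAD = list(ne = 0.02, subst_rate = 0.02,
                                    seq_length = 736, missing_prob = 0.33,
                                    rate_jitter_cv = 0),
                         COI = list(ne = 0.005, subst_rate = 0.1,
                                    seq_length = 658, missing_prob = 0.14,
                                    rate_jitter_cv = 0)),
                       seed = 1L) {
  stopifnot(n_species >= 1, yule_rate > 0,
            larva_fraction >= 0, larva_fraction <= 1,
            pupa_fraction >= 0, larva_fraction + pupa_fraction <= 1,
            length(genes) >= 1, !is.null(names(genes)))
  if (length(samples_per_species) == 1L)
    samples_per_species <- rep(samples_per_species, n_species)
  stopifnot(length(samples_per_species) == n_species,
            all(samples_per_species >= 1))
  for (g in genes)
    stopifnot(g$ne > 0, g$subst_rate > 0, g$seq_length >= 1,
              g$missing_prob >= 0, g$missing_prob < 1)
  structure(list(n_species = n_species, yule_rate = yule_rate,
                 samples_per_species = samples_per_species,
                 larva_fraction = larva_fraction,
                 pupa_fraction = pupa_fraction,
                 genes = genes, seed = as.integer(seed)),
            class = "sim_config")
}

# Kingman coalescent on `ids`: returns list(newick_core, depth).
# Pair-coalescence rate = choose(k,2)/ne.  Single id -> depth 0.
.sim_coalescent <- function(ids, ne) {
  k <- length(ids)
  if (k == 1L) return(list(nwk = ids, depth = 0))
  items <- data.frame(nwk = ids, age = 0, stringsAsFactors = FALSE)
  age <- 0
  while (nrow(items) > 1L) {
    k <- nrow(items)
    age <- age + rexp(1, rate = k * (k - 1) / 2 / ne)
    pair <- sample.int(k, 2L)
    merged <- sprintf("(%s:%.12g,%s:%.12g)",
                      items$nwk[pair[1]], age - items$age[pair[1]],
                      items$nwk[pair[2]], age - items$age[pair[2]])
    items <- rbind(items[-pair, , drop = FALSE],
                   data.frame(nwk = merged, age = age, stringsAsFactors = FALSE))
  }
  list(nwk = items$nwk[1], depth = items$age[1])
}

# Recursive newick assembly of a gene tree over the species-tree topology.
# `subtrees[[sp]]` holds list(nwk, depth) for the species' sampled lineages.
# Species with no sampled lineage are skipped; returns NULL if a clade is
# entirely unsampled.
.assemble_gene_newick <- function(sp_phy, sp_ages, node, parent_age, subtrees) {
  ntip <- length(sp_phy$tip.label)
  if (node <= ntip) {
    sp <- sp_phy$tip.label[node]
    st <- subtrees[[sp]]
    if (is.null(st)) return(NULL)
    return(sprintf("%s:%.12g", st$nwk, parent_age - st$depth))
  }
  age <- sp_ages[[as.character(node)]]
  kids <- sp_phy$edge[sp_phy$edge[, 1] == node, 2]
  parts <- lapply(kids, .assemble_gene_newick, sp_phy = sp_phy,
                  sp_ages = sp_ages, parent_age = age, subtrees = subtrees)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(NULL)
  if (length(parts) == 1L) {
    # unsampled sister: splice through, extending the branch
    child_str <- parts[[1]]
    # child_str ends with ":len"; extend by (parent_age - age)
    m <- regmatches(child_str, regexpr(":[0-9.eE+-]+$", child_str))
    len <- as.numeric(sub(":", "", m))
    return(sub(":[0-9.eE+-]+$", sprintf(":%.12g", len + parent_age - age),
               child_str))
  }
  sprintf("(%s):%.12g", paste(unlist(parts), collapse = ","),
          parent_age - age)
}

#' Simulate a two-locus life-stage dataset
#'
#' Draws a Yule species tree, grafts per-species coalescent genealogies at
#' its tips (ultrametric gene tree in time units), scales branches by the
#' gene's substitution rate (optionally Gamma-jittered per branch) to get a
#' substitution tree, and evolves sequences under Jukes-Cantor. Specimens
#' are labelled adult (species known), larva or pupa (species withheld but
#' recorded in `species_truth`); per-gene availability is dropped at the
#' gene's `missing_prob`. Node supports are 1.0 on true between-species
#' nodes and Uniform(0.5, 1) on within-species nodes. Deterministic given
#' the config seed.
#'
#' If a species' within-species TMRCA would exceed the species' stem age the
#' genealogy is rescaled to 90% of the stem, keeping the gene tree
#' ultrametric and free of deep coalescence (the intended no-ILS regime).
#'
#' @param cfg a [sim_config()].
#' @return list with `species_tree` (`phylo`), `specimens`
#'   (`specimen_table`), `species_truth` (named character vector specimen id
#'   -> true species), and `genes`: per gene a list with `tree_time` and
#'   `tree_subst` ([gene_tree()]s), `alignment` ([alignment()]) and
#'   `depth_ratio` (mean species stem age / mean within-species TMRCA).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_sp <- cfg$n_species
  sp_names <- sprintf("sp%02d", seq_len(n_sp))
  if (n_sp >= 2) {
    sp_phy <- ape::rphylo(n_sp, birth = cfg$yule_rate, death = 0)
    sp_phy$tip.label <- sp_names
    sp_ages_num <- ape::branching.times(sp_phy)
    sp_ages <- as.list(sp_ages_num)
  } else {
    sp_phy <- NULL
    sp_ages <- list()
  }

  # specimens
  ids <- unlist(lapply(seq_len(n_sp), function(i)
    sprintf("%s_%02d", sp_names[i], seq_len(cfg$samples_per_species[i]))))
  truth <- rep(sp_names, cfg$samples_per_species)
  names(truth) <- ids
  u <- runif(length(ids))
  stage <- ifelse(u < cfg$larva_fraction, "larva",
                  ifelse(u < cfg$larva_fraction + cfg$pupa_fraction,
                         "pupa", "adult"))
  spec_tab <- data.frame(id = ids, stage = stage,
                         species = ifelse(stage == "adult", truth, ""),
                         stringsAsFactors = FALSE)

  genes_out <- list()
  for (gname in names(cfg$genes)) {
    gcfg <- cfg$genes[[gname]]
    keep <- runif(length(ids)) >= gcfg$missing_prob
    spec_tab[[paste0("has_", gname)]] <- as.integer(keep)
    g_ids <- ids[keep]
    if (length(g_ids) < 2)
      stop("gene ", gname, ": fewer than 2 specimens sampled; ",
           "lower missing_prob or raise sampling", call. = FALSE)
    # per-species coalescent subtrees
    subtrees <- list()
    tmrcas <- numeric(0)
    stem_ages <- numeric(0)
    for (i in seq_len(n_sp)) {
      sp <- sp_names[i]
      lineages <- g_ids[truth[g_ids] == sp]
      if (!length(lineages)) next
      st <- .sim_coalescent(lineages, gcfg$ne)
      if (n_sp >= 2) {
        tip_idx <- match(sp, sp_phy$tip.label)
        parent <- sp_phy$edge[sp_phy$edge[, 2] == tip_idx, 1]
        stem <- sp_ages[[as.character(parent)]]
        if (st$depth >= 0.9 * stem && st$depth > 0) {
          # rescale genealogy into the stem to avoid deep coalescence
          st <- .rescale_subtree(st, 0.9 * stem / st$depth)
        }
        stem_ages <- c(stem_ages, stem)
      }
      if (st$depth > 0) tmrcas <- c(tmrcas, st$depth)
      subtrees[[sp]] <- st
    }
    if (n_sp >= 2) {
      root <- length(sp_phy$tip.label) + 1L
      nwk <- .assemble_gene_newick(sp_phy, sp_ages, root, NA, subtrees)
      # root call: strip the trailing ":NA" stub
      nwk <- sub(":(NA|[0-9.eE+-]+)$", "", nwk)
    } else {
      nwk <- subtrees[[sp_names[1]]]$nwk
    }
    phy <- ape::read.tree(text = paste0(nwk, ";"))
    phy <- ape::reorder.phylo(phy, "cladewise")

    # supports: 1.0 where the node spans >= 2 true species
    spans <- .node_species_spans(phy, truth)
    sup <- ifelse(spans >= 2, 1.0, runif(phy$Nnode, 0.5, 1.0))
    tree_time <- gene_tree(phy, gene = gname, supports = sup)

    subst_phy <- phy
    mult <- gcfg$subst_rate
    if (gcfg$rate_jitter_cv > 0) {
      shp <- 1 / gcfg$rate_jitter_cv^2
      mult <- mult * rgamma(length(phy$edge.length), shape = shp, rate = shp)
    }
    subst_phy$edge.length <- phy$edge.length * mult
    tree_subst <- gene_tree(subst_phy, gene = gname, supports = sup)

    sim <- phangorn::simSeq(subst_phy, l = gcfg$seq_length, type = "DNA")
    mat <- toupper(as.character(sim))
    seqs <- setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
    aln <- alignment(seqs[phy$tip.label], gene = gname)

    depth_ratio <- if (length(tmrcas) && length(stem_ages))
      mean(stem_ages) / mean(tmrcas) else NA_real_
    genes_out[[gname]] <- list(tree_time = tree_time,
                               tree_subst = tree_subst,
                               alignment = aln,
                               depth_ratio = depth_ratio)
  }
  list(species_tree = sp_phy,
       specimens = as_specimen_table(spec_tab),
       species_truth = truth,
       genes = genes_out)
}

# rescale all branch lengths in a coalescent subtree string by `sc`
.rescale_subtree <- function(st, sc) {
  phy <- ape::read.tree(text = paste0(st$nwk, ";"))
  phy$edge.length <- phy$edge.length * sc
  nwk <- ape::write.tree(phy)
  list(nwk = sub(";$", "", nwk), depth = st$depth * sc)
}

# number of distinct true species under each internal node
.node_species_spans <- function(phy, truth) {
  ntip <- length(phy$tip.label)
  tip_sp <- truth[phy$tip.label]
  vapply(seq_len(phy$Nnode), function(i) {
    node <- ntip + i
    tips <- .clade_tips(phy, node)
    length(unique(tip_sp[tips]))
  }, 0L)
}

# tip indices under `node` (node may be a tip)
.clade_tips_idx <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

.clade_tips <- function(phy, node) phy$tip.label[.clade_tips_idx(phy, node)]

#' Inject paraphyly between two species on one gene
#'
#' Re-attaches a fraction of the first species' lineages inside the second
#' species' clade on the chosen gene's trees, emulating the non-monophyly
#' produced by incomplete lineage sorting or recent gene flow. Specimen
#' truth labels are unchanged: the moved lineages still belong to their
#' original species, so per-gene monophyly of the pair fails while other
#' genes are untouched. The substitution tree is regenerated from the
#' modified time tree (rate jitter, if any, is redrawn). Deterministic
#' given `seed`.
#'
#' @param ds dataset from [simulate_dataset()].
#' @param species_pair character vector of two species names
#'   `c(donor, recipient)`.
#' @param swap_fraction fraction of the donor's lineages to move, in
#'   `[0, 1]`.
#' @param gene gene to modify (default: first gene in the dataset).
#' @param seed integer seed.
#' @param cfg the [sim_config()] used to build `ds` (needed to rebuild the
#'   substitution tree); optional, defaults to unit rate without jitter.
#' @return modified dataset.
#' @export
inject_paraphyly <- function(ds, species_pair, swap_fraction, gene = NULL,
                             seed = 1L, cfg = NULL) {
  stopifnot(length(species_pair) == 2, swap_fraction >= 0, swap_fraction <= 1)
  if (is.null(gene)) gene <- names(ds$genes)[[1]]
  if (!gene %in% names(ds$genes))
    stop("gene '", gene, "' not in dataset", call. = FALSE)
  unknown <- setdiff(species_pair, unique(ds$species_truth))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (swap_fraction == 0) return(ds)
  set.seed(seed)
  donor <- species_pair[[1]]; recipient <- species_pair[[2]]
  g <- ds$genes[[gene]]
  phy <- g$tree_time$phy
  donor_tips <- intersect(phy$tip.label,
                          names(ds$species_truth)[ds$species_truth == donor])
  recip_tips <- intersect(phy$tip.label,
                          names(ds$species_truth)[ds$species_truth == recipient])
  if (!length(donor_tips) || !length(recip_tips))
    stop("both species need tips on gene ", gene, call. = FALSE)
  n_move <- max(1L, round(swap_fraction * length(donor_tips)))
  n_move <- min(n_move, length(donor_tips))
  move <- sample(donor_tips, n_move)
  for (tp in move) {
    if (sum(!phy$tip.label %in% tp) < 2) break
    phy <- ape::drop.tip(phy, tp)
    recip_here <- intersect(recip_tips, phy$tip.label)
    if (!length(recip_here)) stop("recipient clade vanished", call. = FALSE)
    host <- sample(recip_here, 1)
    host_idx <- match(host, phy$tip.label)
    host_len <- phy$edge.length[phy$edge[, 2] == host_idx]
    h <- 0.5 * host_len   # attach halfway down the host's terminal branch
    phy <- .bind_tip_ultra(phy, tp, host_idx, h)
  }
  phy <- ape::reorder.phylo(phy, "cladewise")
  spans <- .node_species_spans(phy, ds$species_truth)
  sup <- ifelse(spans >= 2, 1.0, runif(phy$Nnode, 0.5, 1.0))
  g$tree_time <- gene_tree(phy, gene = gene, supports = sup)
  rate <- if (!is.null(cfg)) cfg$genes[[gene]]$subst_rate else 1
  cv <- if (!is.null(cfg)) cfg$genes[[gene]]$rate_jitter_cv else 0
  subst_phy <- phy
  mult <- rate
  if (cv > 0) {
    shp <- 1 / cv^2
    mult <- rate * rgamma(length(phy$edge.length), shape = shp, rate = shp)
  }
  subst_phy$edge.length <- phy$edge.length * mult
  g$tree_subst <- gene_tree(subst_phy, gene = gene, supports = sup)
  ds$genes[[gene]] <- g
  ds
}

# attach a new tip at height `h` on the terminal branch of tip `host_idx`
# (ultrametric tree, tips at age 0): new node at age h, new tip edge h.
.bind_tip_ultra <- function(phy, new_label, host_idx, h) {
  host_edge <- which(phy$edge[, 2] == host_idx)
  host_len <- phy$edge.length[host_edge]
  stopifnot(h > 0, h < host_len)
  ntip <- length(phy$tip.label)
  # renumber: new tip gets index ntip+1 -> shift all node indices by 1
  edge <- phy$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  new_tip <- ntip + 1L
  new_node <- ntip + 1L + phy$Nnode + 1L
  host_idx2 <- host_idx  # tips keep their indices
  he <- which(edge[, 2] == host_idx2)
  parent <- edge[he, 1]
  # replace host edge: parent -> new_node (len host_len - h)
  edge[he, ] <- c(parent, new_node)
  phy$edge.length[he] <- host_len - h
  # add: new_node -> host (len h), new_node -> new tip (len h)
  edge <- rbind(edge, c(new_node, host_idx2), c(new_node, new_tip))
  phy$edge.length <- c(phy$edge.length, h, h)
  phy$edge <- edge
  phy$tip.label <- c(phy$tip.label, new_label)
  phy$Nnode <- phy$Nnode + 1L
  phy$node.label <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits, per gene, the ultrametric and substitution newick trees, the FASTA
#' alignment and an identity tip map, plus the specimen table and a truth
#' table — the same formats [read_gene_tree()], [read_alignment()] and
#' [read_specimen_table()] consume.
#'
#' @param ds dataset from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ds$specimens, file.path(dir, "specimens.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = names(ds$species_truth),
                         species = unname(ds$species_truth)),
              file.path(dir, "species_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (gname in names(ds$genes)) {
    g <- ds$genes[[gname]]
    write_gene_tree(g$tree_time, file.path(dir, paste0(gname, "_time.nwk")))
    write_gene_tree(g$tree_subst, file.path(dir, paste0(gname, "_subst.nwk")))
    write_alignment(g$alignment, file.path(dir, paste0(gname, ".fasta")))
    write_tip_map(g$tree_time$tip_map, file.path(dir, paste0(gname, "_tipmap.tsv")))
  }
  invisible(dir)
}
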