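#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim optimize pchisq runif rexp rgamma setNames var
#' @importFrom utils read.delim write.table combn head tail
NULL

STAGES <- c("adult", "larva", "pupa")
UNKNOWN_SPECIES <- "UNKNOWN"

#' Gene tree container
#'
#' Bundles a rooted `phylo` tree with the gene it was estimated from, its
#' node supports (posterior probabilities) and the map from tip labels to
#' specimen ids (one-to-many when tips are collapsed haplotypes).
#'
#' @param phy rooted `phylo` object with branch lengths.
#' @param gene gene name, e.g. `"COI"`.
#' @param supports numeric vector of node supports in `[0, 1]`, one per
#'   internal node in `phy`'s node order, or `NULL`. `NA` entries mean
#'   "no support recorded".
#' @param tip_map named list: tip label -> character vector of specimen ids.
#'   Defaults to the identity map (each tip is one specimen).
#' @return an object of class `gene_tree`.
#' @export
gene_tree <- function(phy, gene, supports = NULL, tip_map = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length))
    stop("gene_tree: tree has no branch lengths", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("gene_tree: duplicate tip labels", call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("gene_tree: negative branch lengths", call. = FALSE)
  if (is.null(tip_map)) {
    tip_map <- as.list(phy$tip.label)
    names(tip_map) <- phy$tip.label
  }
  missing_tips <- setdiff(phy$tip.label, names(tip_map))
  if (length(missing_tips))
    stop("gene_tree: tips without tip_map entry: ",
         paste(head(missing_tips, 5), collapse = ", "), call. = FALSE)
  ids <- unlist(tip_map[phy$tip.label], use.names = FALSE)
  if (anyDuplicated(ids))
    stop("gene_tree: a specimen appears under more than one tip", call. = FALSE)
  if (!is.null(supports)) {
    supports <- as.numeric(supports)
    if (length(supports) != phy$Nnode)
      stop("gene_tree: need one support per internal node", call. = FALSE)
    bad <- !is.na(supports) & (supports < 0 | supports > 1)
    if (any(bad))
      stop("gene_tree: supports outside [0,1]", call. = FALSE)
  }
  structure(
    list(phy = phy, gene = gene, supports = supports,
         tip_map = tip_map[phy$tip.label]),
    class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", x$gene, "-", length(x$phy$tip.label), "tips,",
      sum(lengths(x$tip_map)), "specimens\n")
  if (!is.null(x$supports))
    cat("  supports on", sum(!is.na(x$supports)), "internal nodes\n")
  cat("  ultrametric:", is_ultrametric(x$phy), "\n")
  invisible(x)
}

#' Check a tree for ultrametricity
#'
#' A tree is ultrametric when every root-to-tip path has the same length,
#' up to an absolute tolerance.
#'
#' @param phy a `phylo` or `gene_tree`.
#' @param tol absolute tolerance on root-to-tip depth differences.
#' @return logical.
#' @export
is_ultrametric <- function(phy, tol = 1e-6) {
  if (inherits(phy, "gene_tree")) phy <- phy$phy
  depths <- ape::node.depth.edgelength(phy)
  tip_depths <- depths[seq_along(phy$tip.label)]
  diff(range(tip_depths)) <= tol
}

# Turn BEAST-style bracket comments on nodes into plain newick node labels
# carrying the posterior, so ape can parse them.  Handles `[&posterior=0.97,..]`
# and bare `[&prob=0.97]` styles.
.comments_to_labels <- function(txt) {
  # first pull posterior-like values out of each comment
  txt <- gsub("\\[&[^]]*?(?:posterior|prob)=([0-9.eE+-]+)[^]]*\\]", "\\1", txt,
              perl = TRUE)
  # drop any remaining comments
  gsub("\\[[^]]*\\]", "", txt)
}

#' Read a gene tree from newick or NEXUS
#'
#' Node supports are taken from internal node labels by default; with
#' `supports = "comment"` BEAST-style `[&posterior=...]` comments are parsed
#' instead. Supports written as percentages (values > 1) are rescaled to
#' `[0, 1]`. A named outgroup tip can be used to root a basally trifurcating
#' tree and is then pruned.
#'
#' @param path file path.
#' @param gene gene name attached to the tree.
#' @param format `"newick"` or `"nexus"`.
#' @param supports `"label"` (default) or `"comment"`.
#' @param outgroup optional tip label: the tree is rooted on it (if not
#'   already rooted) and the tip is removed.
#' @param tip_map optional named list tip label -> specimen ids (see
#'   [read_tip_map()]).
#' @return a [gene_tree()].
#' @export
read_gene_tree <- function(path, gene, format = c("newick", "nexus"),
                           supports = c("label", "comment"),
                           outgroup = NULL, tip_map = NULL) {
  format <- match.arg(format)
  supports <- match.arg(supports)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (supports == "comment") txt <- .comments_to_labels(txt)
  phy <- if (format == "newick") {
    ape::read.tree(text = txt)
  } else {
    tf <- tempfile(fileext = ".nex")
    writeLines(txt, tf)
    on.exit(unlink(tf), add = TRUE)
    ape::read.nexus(tf)
  }
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.null(phy)) stop("could not parse tree in ", path, call. = FALSE)
  if (is.null(phy$edge.length))
    stop("tree in ", path, " has no branch lengths", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels in ", path, call. = FALSE)
  rooted_by_outgroup <- FALSE
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label)
      stop("outgroup tip '", outgroup, "' not in tree", call. = FALSE)
    if (!ape::is.rooted(phy))
      phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
    phy <- ape::drop.tip(phy, outgroup)
    # the ingroup root is now defined even if it is a polytomy
    rooted_by_outgroup <- TRUE
  }
  if (!rooted_by_outgroup && !ape::is.rooted(phy))
    stop("tree is unrooted; supply an outgroup tip to root it", call. = FALSE)
  sup <- NULL
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    if (all(is.na(sup))) sup <- NULL
    else if (any(sup > 1, na.rm = TRUE)) sup <- sup / 100
  }
  gene_tree(phy, gene = gene, supports = sup, tip_map = tip_map)
}

#' Write a gene tree to newick
#'
#' Supports are written back as internal node labels.
#'
#' @param gt a [gene_tree()].
#' @param path output path.
#' @param digits significant digits for branch lengths.
#' @export
write_gene_tree <- function(gt, path, digits = 12) {
  phy <- gt$phy
  if (!is.null(gt$supports)) {
    lab <- ifelse(is.na(gt$supports), "", format(gt$supports, digits = 15))
    phy$node.label <- lab
  }
  ape::write.tree(phy, file = path, digits = digits)
  invisible(path)
}

#' Read a tip map
#'
#' Two-column TSV (`tip`, `specimens`) where `specimens` is a
#' comma-separated list of specimen ids collapsed under the tip.
#'
#' @param path file path.
#' @return named list tip label -> character vector of specimen ids.
#' @export
read_tip_map <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", strip.white = TRUE)
  if (!all(c("tip", "specimens") %in% names(tab)))
    stop("tip map needs columns 'tip' and 'specimens'", call. = FALSE)
  if (anyDuplicated(tab$tip))
    stop("duplicate tips in tip map", call. = FALSE)
  out <- lapply(strsplit(tab$specimens, ","), trimws)
  names(out) <- tab$tip
  out
}

#' Write a tip map
#' @param tip_map named list tip -> specimen ids.
#' @param path output path.
#' @export
write_tip_map <- function(tip_map, path) {
  tab <- data.frame(tip = names(tip_map),
                    specimens = vapply(tip_map, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a specimen table
#'
#' TSV or CSV with header. Required columns: `id`, `stage` (one of
#' `adult`, `larva`, `pupa`), `species` (empty or `UNKNOWN` for
#' unidentified). Optional: `sex` (`M`/`F`), and one `has_<gene>` 0/1
#' column per gene (e.g. `has_COI`). Larvae and pupae always start
#' unidentified; an identified larva row is rejected.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension by default.
#' @return data.frame of class `specimen_table` with columns `id`, `stage`,
#'   `species`, `sex` and logical `has_<gene>` columns.
#' @export
read_specimen_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", strip.white = TRUE)
  as_specimen_table(tab)
}

#' Validate a raw data.frame as a specimen table
#'
#' @param tab data.frame with at least `id` and `stage` columns.
#' @return validated `specimen_table` data.frame.
#' @export
as_specimen_table <- function(tab) {
  if (!all(c("id", "stage") %in% names(tab)))
    stop("specimen table needs 'id' and 'stage' columns", call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("duplicate specimen ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  bad_stage <- setdiff(unique(tab$stage), STAGES)
  if (length(bad_stage))
    stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$species)) tab$species <- ""
  tab$species[is.na(tab$species) | trimws(tab$species) == ""] <- UNKNOWN_SPECIES
  immature <- tab$stage %in% c("larva", "pupa")
  if (any(immature & tab$species != UNKNOWN_SPECIES))
    stop("larvae/pupae must start unidentified (species empty or UNKNOWN)",
         call. = FALSE)
  if (is.null(tab$sex)) tab$sex <- NA_character_
  tab$sex[!tab$sex %in% c("M", "F")] <- NA_character_
  gene_cols <- grep("^has_", names(tab), value = TRUE)
  for (g in gene_cols) tab[[g]] <- tab[[g]] %in% c("1", "TRUE", "yes", TRUE)
  tab <- tab[, c("id", "stage", "species", "sex", gene_cols)]
  class(tab) <- c("specimen_table", "data.frame")
  tab
}

#' Genes declared in a specimen table
#' @param specimens a `specimen_table`.
#' @return character vector of gene names.
#' @export
specimen_genes <- function(specimens) {
  sub("^has_", "", grep("^has_", names(specimens), value = TRUE))
}

#' Specimen ids with data for a gene
#' @param specimens a `specimen_table`.
#' @param gene gene name.
#' @return character vector of ids.
#' @export
specimens_with_gene <- function(specimens, gene) {
  col <- paste0("has_", gene)
  if (!col %in% names(specimens)) return(character(0))
  specimens$id[specimens[[col]]]
}

#' Cluster partition container
#'
#' A disjoint assignment of specimen ids to delimited clusters for one gene
#' and one method.
#'
#' @param clusters list of character vectors (specimen ids).
#' @param gene gene name.
#' @param method `"GMYC"` or `"PTP"`.
#' @return object of class `cluster_partition`.
#' @export
cluster_partition <- function(clusters, gene, method) {
  if (!length(clusters) || any(lengths(clusters) == 0))
    stop("cluster_partition: empty cluster", call. = FALSE)
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("cluster_partition: clusters are not disjoint", call. = FALSE)
  structure(list(clusters = lapply(clusters, as.character),
                 gene = gene, method = method),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition:", x$method, "on", x$gene, "-",
      length(x$clusters), "clusters,",
      length(unlist(x$clusters)), "specimens\n")
  invisible(x)
}

#' Write a cluster partition as TSV
#' @param part a `cluster_partition`.
#' @param path output path.
#' @export
write_partition <- function(part, path) {
  tab <- data.frame(
    specimen = unlist(part$clusters, use.names = FALSE),
    cluster = rep(seq_along(part$clusters), lengths(part$clusters)),
    gene = part$gene, method = part$method, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Expand a tip-level grouping to specimen ids through a gene_tree's tip_map.
.expand_tips <- function(gt, tip_groups) {
  lapply(tip_groups, function(tips)
    unlist(gt$tip_map[tips], use.names = FALSE))
}
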