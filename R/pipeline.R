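# End-to-end orchestration: collapse haplotypes, delimit with GMYC and PTP,
# test reciprocal monophyly, vote, and write TSV/JSON reports.  Gene names
# are data: any one or two loci work.

#' Build a run configuration
#'
#' @param genes named list, one entry per gene, each a list with paths:
#'   `tree_time` (ultrametric newick, for GMYC), `tree_subst`
#'   (substitution-scaled newick, for PTP), optional `alignment` (FASTA),
#'   optional `tip_map` (TSV). Either tree may be omitted; the matching
#'   criteria become not evaluable.
#' @param specimens path to the specimen table (TSV/CSV).
#' @param out_dir output directory.
#' @param support_threshold posterior support threshold for monophyly.
#' @param gmyc_df,ptp_df LRT degrees of freedom.
#' @param ptp_mode `"heuristic"` or `"exact"`.
#' @param seed top-level seed; per-stage seeds are expanded from it.
#' @param collapse collapse alignments to haplotypes and report membership.
#' @return object of class `run_config`.
#' @export
run_config <- function(genes, specimens, out_dir,
                       support_threshold = 0.95, gmyc_df = 2, ptp_df = 1,
                       ptp_mode = c("heuristic", "exact"), seed = 1L,
                       collapse = TRUE) {
  ptp_mode <- match.arg(ptp_mode)
  stopifnot(length(genes) >= 1, !is.null(names(genes)))
  structure(list(genes = genes, specimens = specimens, out_dir = out_dir,
                 support_threshold = support_threshold,
                 gmyc_df = gmyc_df, ptp_df = ptp_df, ptp_mode = ptp_mode,
                 seed = as.integer(seed), collapse = collapse),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: a `genes` mapping (per gene:
#' `tree_time`, `tree_subst`, `alignment`, `tip_map`), `specimens`,
#' `out_dir`, and optional `support_threshold`, `gmyc_df`, `ptp_df`,
#' `ptp_mode`, `seed`, `collapse`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("genes", "specimens", "out_dir", "support_threshold",
                        "gmyc_df", "ptp_df", "ptp_mode", "seed", "collapse"))]
  do.call(run_config, args)
}

#' Run the full life-stage association pipeline
#'
#' Stages: read inputs, collapse haplotypes (optional), check trees, fit
#' GMYC on each ultrametric tree and PTP on each substitution tree, test
#' reciprocal monophyly, assemble OTUs, vote, and write: per-gene alignment
#' statistics and haplotype membership, per-partition cluster tables, the
#' association table, a summary JSON and a JSON run log recording versions,
#' seeds and every setting in force. A failing stage aborts with a
#' stage-labelled error; artifacts written so far are listed in `MANIFEST`
#' with a note that the run is incomplete.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `rows` (association rows), `summary`,
#'   `partitions`, `fits`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  log <- list(package_version = as.character(utils::packageVersion("stagematch")),
              r_version = R.version.string,
              seed = cfg$seed,
              support_threshold = cfg$support_threshold,
              gmyc_df = cfg$gmyc_df, ptp_df = cfg$ptp_df,
              ptp_mode = cfg$ptp_mode, collapse = cfg$collapse,
              genes = names(cfg$genes))
  emit <- function(name) manifest <<- c(manifest, name)
  fail <- function(stage, e) {
    writeLines(c(manifest, paste0("# INCOMPLETE: failed at stage ", stage)),
               file.path(cfg$out_dir, "MANIFEST"))
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) fail(name, e))

  specimens <- stage("read_specimens", read_specimen_table(cfg$specimens))

  genes <- names(cfg$genes)
  trees_time <- list(); trees_subst <- list()
  stats_rows <- list()
  for (g in genes) {
    gcfg <- cfg$genes[[g]]
    tip_map <- if (!is.null(gcfg$tip_map))
      stage(paste0("tip_map_", g), read_tip_map(gcfg$tip_map)) else NULL
    if (!is.null(gcfg$alignment)) {
      aln <- stage(paste0("alignment_", g),
                   read_alignment(gcfg$alignment, gene = g))
      st <- alignment_stats(aln)
      stats_rows[[g]] <- data.frame(gene = g, n_seqs = st$n_seqs,
                                    length = st$length,
                                    pct_variable = st$pct_variable,
                                    pct_parsimony_informative =
                                      st$pct_parsimony_informative,
                                    pct_missing = st$pct_missing)
      if (cfg$collapse) {
        hs <- stage(paste0("collapse_", g), collapse_haplotypes(aln))
        write_haplotypes(hs, file.path(cfg$out_dir, paste0(g, "_haplotypes.fasta")),
                         file.path(cfg$out_dir, paste0(g, "_haplotypes.tsv")))
        emit(paste0(g, "_haplotypes.fasta")); emit(paste0(g, "_haplotypes.tsv"))
        if (is.null(tip_map)) tip_map <- hs$membership
      }
    }
    if (!is.null(gcfg$tree_time))
      trees_time[[g]] <- stage(paste0("tree_time_", g),
        read_gene_tree(gcfg$tree_time, gene = g,
                       outgroup = gcfg$outgroup,
                       tip_map = .maybe_tip_map(tip_map, gcfg$tree_time)))
    if (!is.null(gcfg$tree_subst))
      trees_subst[[g]] <- stage(paste0("tree_subst_", g),
        read_gene_tree(gcfg$tree_subst, gene = g,
                       outgroup = gcfg$outgroup,
                       tip_map = .maybe_tip_map(tip_map, gcfg$tree_subst)))
  }
  if (length(stats_rows)) {
    write.table(do.call(rbind, stats_rows),
                file.path(cfg$out_dir, "alignment_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("alignment_stats.tsv")
  }

  partitions <- list()
  fits <- list()
  cluster_rows <- list()
  for (g in names(trees_time)) {
    fit <- stage(paste0("gmyc_", g),
                 suppressWarnings(fit_gmyc(trees_time[[g]], df = cfg$gmyc_df,
                                           seed = cfg$seed + 101L)))
    fits[[paste0(g, "_GMYC")]] <- fit
    partitions[[paste0(g, "_GMYC")]] <- fit$entities
    cluster_rows[[paste0(g, "_GMYC")]] <-
      data.frame(gene = g, method = "GMYC",
                 n_clusters = fit$n_entities,
                 logL = fit$logL, null_logL = fit$null_logL,
                 lrt_pvalue = fit$lrt_pvalue)
  }
  for (g in names(trees_subst)) {
    fit <- stage(paste0("ptp_", g), {
      if (cfg$ptp_mode == "exact")
        fit_ptp_exact(trees_subst[[g]], df = cfg$ptp_df)
      else fit_ptp_heuristic(trees_subst[[g]], seed = cfg$seed + 202L,
                             df = cfg$ptp_df)
    })
    fits[[paste0(g, "_PTP")]] <- fit
    partitions[[paste0(g, "_PTP")]] <- fit$partition
    cluster_rows[[paste0(g, "_PTP")]] <-
      data.frame(gene = g, method = "PTP",
                 n_clusters = length(fit$partition$clusters),
                 logL = fit$logL, null_logL = fit$null_logL,
                 lrt_pvalue = fit$lrt_pvalue)
  }
  if (length(cluster_rows)) {
    write.table(do.call(rbind, cluster_rows),
                file.path(cfg$out_dir, "cluster_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("cluster_counts.tsv")
    for (nm in names(partitions)) {
      write_partition(partitions[[nm]],
                      file.path(cfg$out_dir, paste0("partition_", nm, ".tsv")))
      emit(paste0("partition_", nm, ".tsv"))
    }
  }

  recip_trees <- if (length(trees_time) >= 2) trees_time
                 else if (length(trees_subst) >= 2) trees_subst
                 else NULL
  rows <- stage("associate",
                assemble_otus(partitions, specimens, trees = recip_trees,
                              support_threshold = cfg$support_threshold,
                              genes = genes))
  tab <- association_table(rows)
  write.table(tab, file.path(cfg$out_dir, "association_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emit("association_table.tsv")
  larvae_tab <- do.call(rbind, lapply(rows, function(r)
    if (length(r$larvae))
      data.frame(specimen = r$larvae, otu = r$otu,
                 level = r$larval_association_level) else NULL))
  if (!is.null(larvae_tab)) {
    write.table(larvae_tab, file.path(cfg$out_dir, "larvae_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("larvae_assignments.tsv")
  }
  summ <- summarize_associations(rows)
  jsonlite::write_json(summ, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("summary.json")
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("run_log.json")
  writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))
  invisible(list(rows = rows, summary = summ, partitions = partitions,
                 fits = fits))
}

# a tip map is only usable if it covers the tree's tips; otherwise fall back
# to the identity map (read_gene_tree default)
.maybe_tip_map <- function(tip_map, tree_path) {
  if (is.null(tip_map)) return(NULL)
  phy <- ape::read.tree(tree_path)
  if (is.null(phy)) return(tip_map)
  if (all(phy$tip.label %in% names(tip_map))) tip_map else NULL
}
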