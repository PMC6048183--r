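# Five-criterion life-stage association: a per-gene PTP cluster criterion,
# a per-gene GMYC cluster criterion, and reciprocal monophyly across genes.
# Association is successful when at least three of the five criteria are
# fulfilled; a criterion that cannot be evaluated counts as not fulfilled.

OUTCOMES <- c("yes", "no", "not_evaluable")

criterion_outcome <- function(criterion, outcome, detail = "",
                              larvae = character(0)) {
  stopifnot(outcome %in% OUTCOMES)
  structure(list(criterion = criterion, outcome = outcome,
                 detail = detail, larvae = larvae),
            class = "criterion_outcome")
}

#' Cluster-based association criterion for one species on one partition
#'
#' Larvae are conspecific with an adult species when they share a delimited
#' cluster containing that species and no other identified adult species.
#' The outcome is `yes` when candidate larvae exist, every cluster holding
#' an adult of the species is free of other identified adult species, and
#' no hypothesized larva sits in a cluster lacking the species' adults.
#' Unidentified adults never veto a cluster but are recorded in the detail.
#' The criterion is `not_evaluable` when the species has no identified
#' adult with data on the partition's gene.
#'
#' @param partition a [cluster_partition()].
#' @param specimens a `specimen_table`.
#' @param species species name (must occur in `specimens`).
#' @param candidate_larvae optional specimen ids: the larval hypothesis for
#'   the species' OTU (e.g. assembled from all partitions); when supplied,
#'   a hypothesized larva clustering away from the species' adults is a
#'   violation. When `NULL`, only the larvae co-clustered here are used.
#' @return a `criterion_outcome` with the candidate larvae attached.
#' @export
cluster_criterion <- function(partition, specimens, species,
                              candidate_larvae = NULL) {
  stopifnot(inherits(partition, "cluster_partition"),
            inherits(specimens, "specimen_table"))
  if (!species %in% specimens$species)
    stop("species '", species, "' not in specimen table", call. = FALSE)
  label <- paste0(partition$gene, "_", partition$method)
  info <- specimens[match(unlist(partition$clusters), specimens$id), ]
  if (anyNA(info$id))
    stop("partition contains unknown specimen ids", call. = FALSE)
  stage_of <- setNames(specimens$stage, specimens$id)
  species_of <- setNames(specimens$species, specimens$id)

  present <- unlist(partition$clusters, use.names = FALSE)
  sp_adults <- specimens$id[specimens$species == species &
                            specimens$stage == "adult"]
  sp_adults_here <- intersect(sp_adults, present)
  if (!length(sp_adults_here))
    return(criterion_outcome(label, "not_evaluable",
                             "no identified adult of the species on this gene"))
  details <- character(0)
  candidates <- character(0)
  mixed <- FALSE
  for (cl in partition$clusters) {
    has_sp_adult <- any(cl %in% sp_adults_here)
    if (!has_sp_adult) next
    cl_adults_sp <- unique(species_of[cl][stage_of[cl] == "adult"])
    others <- setdiff(cl_adults_sp, c(species, UNKNOWN_SPECIES))
    if (length(others)) {
      mixed <- TRUE
      details <- c(details, paste0("cluster mixes adults of: ",
                                   paste(sort(others), collapse = ", ")))
    }
    if (UNKNOWN_SPECIES %in% cl_adults_sp)
      details <- c(details, "cluster contains unidentified adult(s)")
    candidates <- c(candidates,
                    cl[stage_of[cl] %in% c("larva", "pupa")])
  }
  stray <- FALSE
  if (!is.null(candidate_larvae)) {
    hyp <- intersect(candidate_larvae, present)
    out_of_place <- setdiff(hyp, candidates)
    if (length(out_of_place)) {
      stray <- TRUE
      details <- c(details,
                   paste0("hypothesized larvae away from the species' adults: ",
                          paste(sort(out_of_place), collapse = ", ")))
    }
  }
  outcome <- if (mixed || stray) "no"
             else if (!length(candidates)) "no"
             else "yes"
  if (!length(candidates) && !mixed && !stray)
    details <- c(details, "no larvae share a cluster with the species' adults")
  criterion_outcome(label, outcome, paste(details, collapse = "; "),
                    larvae = unique(candidates))
}

#' Consensus vote over the five association criteria
#'
#' @param outcomes list of `criterion_outcome`s, or a character vector of
#'   `"yes"`/`"no"`/`"not_evaluable"`; criterion labels (list names or
#'   vector names) must be unique. Exactly five outcomes are expected.
#' @return list with `n_fulfilled` (count of `yes`) and `success`
#'   (`n_fulfilled >= 3`).
#' @export
vote <- function(outcomes) {
  if (length(outcomes) != 5L)
    stop("vote: expected exactly five criterion outcomes", call. = FALSE)
  if (is.list(outcomes) && all(vapply(outcomes, inherits, TRUE,
                                      "criterion_outcome"))) {
    labels <- vapply(outcomes, `[[`, "", "criterion")
    verdicts <- vapply(outcomes, `[[`, "", "outcome")
  } else {
    verdicts <- as.character(outcomes)
    labels <- names(outcomes)
  }
  if (!is.null(labels) && anyDuplicated(labels))
    stop("vote: duplicate criterion labels", call. = FALSE)
  if (!all(verdicts %in% OUTCOMES))
    stop("vote: outcomes must be yes/no/not_evaluable", call. = FALSE)
  n <- sum(verdicts == "yes")
  list(n_fulfilled = n, success = n >= 3L)
}

# union-find for species-complex components
.components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in edges) parent[[find(e[1])]] <- find(e[2])
  comp <- vapply(nodes, find, "")
  split(nodes, comp)
}

#' Assemble OTUs and evaluate all association criteria
#'
#' Builds a graph over identified adult species with an edge whenever two
#' species' adults share a delimited cluster in any partition, or one
#' species' clade on a gene tree is intruded by the other's adults;
#' connected components of size > 1 become species complexes (named after
#' the alphabetically first member), singletons keep their species name.
#' Specimens never co-clustered with any identified adult are grouped by
#' co-clustering into larva-only OTUs named `sp. <smallest id> (L)`. Each
#' OTU row carries the per-gene PTP and GMYC cluster criteria, the
#' reciprocal-monophyly criterion, and the consensus vote.
#'
#' @param partitions list of [cluster_partition()]s (typically both genes
#'   x both methods; fewer are allowed and the absent criteria become
#'   `not_evaluable`).
#' @param specimens a `specimen_table`.
#' @param trees optional named list of two [gene_tree()]s (names = genes)
#'   for the reciprocal-monophyly criterion; with fewer than two trees that
#'   criterion is `not_evaluable`.
#' @param support_threshold posterior-support threshold for monophyly.
#' @param genes the two gene names defining the criterion labels; defaults
#'   to the genes seen in `partitions`/`trees`.
#' @return list of `association_row`s; see [association_table()] for a
#'   data.frame view.
#' @export
assemble_otus <- function(partitions, specimens, trees = NULL,
                          support_threshold = 0.95, genes = NULL) {
  stopifnot(length(partitions) >= 1,
            inherits(specimens, "specimen_table"))
  if (is.null(genes)) {
    genes <- unique(c(vapply(partitions, `[[`, "", "gene"), names(trees)))
    genes <- genes[!is.na(genes)]
  }
  if (length(genes) == 1L) genes <- c(genes, "gene2")
  stopifnot(length(genes) == 2L)
  species_of <- setNames(specimens$species, specimens$id)
  stage_of <- setNames(specimens$stage, specimens$id)
  id_species <- specimens$species[specimens$stage == "adult" &
                                  specimens$species != UNKNOWN_SPECIES]
  sp_names <- sort(unique(id_species))

  # edges from shared clusters
  edges <- list()
  for (part in partitions) {
    for (cl in part$clusters) {
      sps <- unique(species_of[cl][stage_of[cl] == "adult"])
      sps <- setdiff(sps, UNKNOWN_SPECIES)
      if (length(sps) >= 2)
        for (pr in combn(sort(sps), 2, simplify = FALSE))
          edges[[length(edges) + 1L]] <- pr
    }
  }
  # edges from monophyly intrusion
  if (!is.null(trees)) {
    for (gt in trees) {
      for (sp in sp_names) {
        adults <- specimens$id[specimens$species == sp &
                               specimens$stage == "adult"]
        r <- test_monophyly(gt, adults, support_threshold = 0)
        if (r$is_monophyletic == "no") {
          intruders <- unique(species_of[r$clade_members])
          intruders <- setdiff(intruders[!is.na(intruders)],
                               c(sp, UNKNOWN_SPECIES))
          intruders <- intruders[intruders %in%
            species_of[r$clade_members][stage_of[r$clade_members] == "adult"]]
          for (o in intruders)
            edges[[length(edges) + 1L]] <- sort(c(sp, o))
        }
      }
    }
  }
  comps <- if (length(sp_names)) .components(sp_names, edges) else list()

  # larval hypotheses: immatures (and unknown adults) co-clustered with
  # identified adults of each component
  adult_ids_of <- function(members)
    specimens$id[specimens$species %in% members & specimens$stage == "adult"]
  unassigned <- specimens$id[species_of == UNKNOWN_SPECIES]
  rows <- list()
  claimed <- character(0)
  for (members in comps) {
    adults <- adult_ids_of(members)
    larvae <- character(0)
    for (part in partitions)
      for (cl in part$clusters)
        if (any(cl %in% adults))
          larvae <- union(larvae, cl[stage_of[cl] %in% c("larva", "pupa")])
    otu <- if (length(members) == 1L) members
           else paste0(members[[1]], "-complex")
    rows[[otu]] <- list(otu = otu, species_members = members,
                        larvae = sort(larvae))
    claimed <- union(claimed, larvae)
  }

  # larva-only OTUs: co-clustering components over the remaining specimens
  leftover <- setdiff(unassigned[stage_of[unassigned] %in% c("larva", "pupa")],
                      claimed)
  if (length(leftover)) {
    lo_edges <- list()
    for (part in partitions)
      for (cl in part$clusters) {
        got <- intersect(cl, leftover)
        if (length(got) >= 2)
          for (pr in combn(sort(got), 2, simplify = FALSE))
            lo_edges[[length(lo_edges) + 1L]] <- pr
      }
    for (grp in .components(sort(leftover), lo_edges)) {
      otu <- paste0("sp. ", min(grp), " (L)")
      rows[[otu]] <- list(otu = otu, species_members = character(0),
                          larvae = sort(unname(grp)))
    }
  }

  # evaluate criteria per row
  part_key <- vapply(partitions, function(p) paste0(p$gene, "_", p$method), "")
  out <- list()
  for (row in rows) {
    outcomes <- list()
    for (g in genes) for (m in c("PTP", "GMYC")) {
      label <- paste0(g, "_", m)
      idx <- match(label, part_key)
      if (is.na(idx)) {
        outcomes[[label]] <- criterion_outcome(label, "not_evaluable",
                                               "no partition for this gene/method")
        next
      }
      if (!length(row$species_members)) {
        outcomes[[label]] <- criterion_outcome(label, "not_evaluable",
                                               "larva-only OTU: no adults")
        next
      }
      per_sp <- lapply(row$species_members, function(sp)
        cluster_criterion(partitions[[idx]], specimens, sp,
                          candidate_larvae = row$larvae))
      verdicts <- vapply(per_sp, `[[`, "", "outcome")
      agg <- if (all(verdicts == "not_evaluable")) "not_evaluable"
             else if (any(verdicts == "no")) "no"
             else "yes"
      outcomes[[label]] <- criterion_outcome(
        label, agg,
        paste(unlist(lapply(per_sp, `[[`, "detail")), collapse = "; "),
        larvae = unique(unlist(lapply(per_sp, `[[`, "larvae"))))
    }
    recip_label <- "RECIP_MONO"
    if (!is.null(trees) && length(trees) >= 2 &&
        length(row$species_members)) {
      adults <- adult_ids_of(row$species_members)
      rr <- reciprocal_monophyly(trees[[1]], trees[[2]], adults,
                                 larvae_hypothesis = row$larvae,
                                 support_threshold = support_threshold)
      outcomes[[recip_label]] <- criterion_outcome(recip_label, rr$outcome)
    } else {
      outcomes[[recip_label]] <- criterion_outcome(
        recip_label, "not_evaluable",
        if (length(row$species_members)) "fewer than two gene trees"
        else "larva-only OTU: no adults")
    }
    v <- vote(unname(outcomes))
    level <- if (!length(row$larvae)) "none"
             else if (length(row$species_members) == 1L && v$success) "species"
             else "otu_only"
    out[[row$otu]] <- structure(
      list(otu = row$otu, species_members = row$species_members,
           larvae = row$larvae, outcomes = outcomes,
           n_fulfilled = v$n_fulfilled, success = v$success,
           larval_association_level = level),
      class = "association_row")
  }
  out[order(names(out))]
}

#' Flatten association rows into a data.frame
#'
#' One row per OTU with the five criterion verdicts, the criteria count,
#' the success flag and the association level.
#'
#' @param rows list of `association_row`s from [assemble_otus()] or
#'   [example_association_table()].
#' @return data.frame.
#' @export
association_table <- function(rows) {
  labels <- names(rows[[1]]$outcomes)
  tab <- do.call(rbind, lapply(rows, function(r) {
    verdicts <- vapply(r$outcomes, `[[`, "", "outcome")
    df <- data.frame(otu = r$otu,
                     species = paste(r$species_members, collapse = ";"),
                     n_larvae = length(r$larvae),
                     stringsAsFactors = FALSE)
    for (i in seq_along(labels)) df[[labels[i]]] <- verdicts[[i]]
    df$n_fulfilled <- r$n_fulfilled
    df$success <- r$success
    df$level <- r$larval_association_level
    df
  }))
  rownames(tab) <- NULL
  tab
}

#' Summarize association rows
#'
#' @param rows list of `association_row`s.
#' @return list with `n_otus`, `n_species_level` (single-species OTUs whose
#'   larvae are associated at species level), `n_otu_level` (OTUs whose
#'   larvae attach at OTU level only), `n_larvae_species` and
#'   `n_larvae_otu` (immature specimens attached at each level; pupae are
#'   counted with larvae).
#' @export
summarize_associations <- function(rows) {
  stopifnot(length(rows) >= 1)
  lv <- vapply(rows, `[[`, "", "larval_association_level")
  nl <- vapply(rows, function(r) length(r$larvae), 0L)
  list(n_otus = length(rows),
       n_species_level = sum(lv == "species"),
       n_otu_level = sum(lv == "otu_only"),
       n_larvae_species = sum(nl[lv == "species"]),
       n_larvae_otu = sum(nl[lv == "otu_only"]))
}

# parse a printed "yes/yes"-style cell into two verdicts
.parse_pair <- function(cell) {
  if (cell %in% c("-", "", NA)) return(c("not_evaluable", "not_evaluable"))
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2, all(parts %in% c("yes", "no")))
  parts
}

#' Worked example: published caddisfly life-stage association outcomes
#'
#' Loads the packaged per-OTU association table for the caddisfly genus
#' *Himalopsyche* (two loci: nuclear CAD and mitochondrial COI; 32 OTUs,
#' five criteria per OTU) and rebuilds each row's criteria count with
#' [vote()]. Rows whose larvae lack molecular data, or without larvae, have
#' no evaluable association and carry `NA` counts. The `note` column marks
#' cells where the published table is internally inconsistent and records
#' the printed value.
#'
#' @param path optional path to an equivalent TSV; defaults to the packaged
#'   table.
#' @return list of `association_row`s with an extra attribute
#'   `printed_counts` (the published criteria-count column, `NA` where not
#'   printed).
#' @export
example_association_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "himalopsyche_otus.tsv",
                        package = "stagematch", mustWork = TRUE)
  tab <- read.delim(path, sep = "\t", colClasses = "character",
                    strip.white = TRUE)
  rows <- list()
  printed <- rep(NA_integer_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cad <- .parse_pair(tab$assoc_cad[i])
    coi <- .parse_pair(tab$assoc_coi[i])
    recip <- switch(tab$recip_mono[i],
                    yes = "yes", no = "no", "not_evaluable")
    outcomes <- list(
      CAD_PTP = criterion_outcome("CAD_PTP", cad[1]),
      CAD_GMYC = criterion_outcome("CAD_GMYC", cad[2]),
      COI_PTP = criterion_outcome("COI_PTP", coi[1]),
      COI_GMYC = criterion_outcome("COI_GMYC", coi[2]),
      RECIP_MONO = criterion_outcome("RECIP_MONO", recip))
    members <- if (tab$species[i] %in% c("NA", "")) character(0)
               else strsplit(tab$species[i], ";")[[1]]
    larvae_with_data <- tab$larvae[i] == "yes"
    v <- vote(unname(outcomes))
    evaluated <- tab$n_criteria[i] != "-"
    n_f <- if (evaluated) v$n_fulfilled else NA_integer_
    success <- if (evaluated) v$success else NA
    level <- if (!larvae_with_data) "none"
             else if (length(members) == 1L && isTRUE(success)) "species"
             else "otu_only"
    if (evaluated) printed[i] <- as.integer(tab$n_criteria[i])
    rows[[tab$otu[i]]] <- structure(
      list(otu = tab$otu[i], species_members = members,
           larvae = character(0), n_larvae = NA_integer_,
           outcomes = outcomes,
           n_fulfilled = n_f, success = success,
           larval_association_level = level,
           note = tab$note[i]),
      class = "association_row")
  }
  attr(rows, "printed_counts") <- printed
  rows
}
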