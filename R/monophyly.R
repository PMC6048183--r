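# Support-aware monophyly testing.  A target specimen set is monophyletic on
# a gene tree when the smallest clade containing all its tips contains no
# non-target tips, and (if support filtering is on) that clade's posterior
# support meets the threshold.  The root carries support 1.0 by convention.

#' Test monophyly of a specimen set on one gene tree
#'
#' Specimens without a tip in the tree are ignored; the verdict is
#' `not_evaluable` when fewer than two target tips are present. Exclusivity
#' is judged at tip level: on a haplotype-collapsed tree, a specimen whose
#' sequence is identical to a target's (same tip) cannot veto the clade,
#' but it is reported in `clade_members`.
#'
#' @param tree a [gene_tree()].
#' @param target character vector of specimen ids.
#' @param support_threshold posterior-probability threshold in `[0, 1]`;
#'   0 disables support filtering. Nodes without a recorded support are
#'   treated as unsupported when filtering is on.
#' @return list of class `monophyly_result`: `gene`, `is_monophyletic`
#'   (`"yes"`, `"no"`, `"not_evaluable"`), `clade_support` (or `NA`),
#'   `clade_members` (specimen ids in the defining clade), `reason`.
#' @export
test_monophyly <- function(tree, target, support_threshold = 0.95) {
  stopifnot(inherits(tree, "gene_tree"), length(target) >= 1)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  id2tip <- setNames(rep(names(tree$tip_map), lengths(tree$tip_map)),
                     unlist(tree$tip_map, use.names = FALSE))
  target_tips <- unique(unname(id2tip[as.character(target)]))
  target_tips <- target_tips[!is.na(target_tips)]
  res <- function(verdict, support = NA_real_, members = character(0), reason = "")
    structure(list(gene = tree$gene, is_monophyletic = verdict,
                   clade_support = support, clade_members = members,
                   reason = reason), class = "monophyly_result")
  if (length(target_tips) == 0)
    return(res("not_evaluable", reason = "no target specimens in tree"))
  if (length(target_tips) == 1)
    return(res("not_evaluable", reason = "fewer than 2 target tips"))
  idx <- match(target_tips, phy$tip.label)
  mrca <- if (length(idx) == ntip) ntip + 1L else ape::getMRCA(phy, idx)
  clade_tip_idx <- .clade_tips_idx(phy, mrca)
  members <- unlist(tree$tip_map[phy$tip.label[clade_tip_idx]],
                    use.names = FALSE)
  support <- if (mrca == ntip + 1L) 1.0
             else if (!is.null(tree$supports)) tree$supports[mrca - ntip]
             else NA_real_
  if (length(clade_tip_idx) > length(idx))
    return(res("no", support, members, "clade contains non-target tips"))
  if (support_threshold > 0) {
    if (is.na(support) || support < support_threshold)
      return(res("no", support, members,
                 sprintf("clade support %s below threshold %.2f",
                         ifelse(is.na(support), "absent",
                                sprintf("%.2f", support)),
                         support_threshold)))
  }
  res("yes", support, members)
}

#' Test reciprocal monophyly of a species plus a larval hypothesis
#'
#' A species (its identified adults) together with a hypothesized larval set
#' is reciprocally monophyletic when both gene trees return an exclusive
#' (and, when filtering is on, supported) clade of exactly those specimens.
#' Specimens missing a gene are excluded from that gene's target; the
#' "same larval specimens" condition is enforced on the larvae with data on
#' both genes. The test is `not_evaluable` when either gene has fewer than
#' two target specimens present.
#'
#' @param treeA,treeB [gene_tree()]s of the two genes.
#' @param adults character vector: identified adult specimen ids of the
#'   species (or species complex).
#' @param larvae_hypothesis character vector of larval/pupal specimen ids
#'   (may be empty).
#' @param support_threshold passed to [test_monophyly()].
#' @return list of class `recip_result`: `outcome` (`"yes"`, `"no"`,
#'   `"not_evaluable"`), per-gene `monophyly_result`s in `per_gene`,
#'   `larvae_tested`.
#' @export
reciprocal_monophyly <- function(treeA, treeB, adults, larvae_hypothesis =
                                   character(0), support_threshold = 0.95) {
  stopifnot(length(adults) >= 1)
  in_tree <- function(gt) {
    ids <- unlist(gt$tip_map, use.names = FALSE)
    function(x) x[x %in% ids]
  }
  fA <- in_tree(treeA); fB <- in_tree(treeB)
  larvae_both <- intersect(fA(larvae_hypothesis), fB(larvae_hypothesis))
  targetA <- c(fA(adults), larvae_both)
  targetB <- c(fB(adults), larvae_both)
  out <- function(outcome, per_gene = NULL)
    structure(list(outcome = outcome, per_gene = per_gene,
                   larvae_tested = larvae_both), class = "recip_result")
  if (length(targetA) < 2 || length(targetB) < 2)
    return(out("not_evaluable"))
  rA <- test_monophyly(treeA, targetA, support_threshold)
  rB <- test_monophyly(treeB, targetB, support_threshold)
  per_gene <- list(rA, rB)
  names(per_gene) <- c(treeA$gene, treeB$gene)
  if (rA$is_monophyletic == "not_evaluable" ||
      rB$is_monophyletic == "not_evaluable")
    return(out("not_evaluable", per_gene))
  out(if (rA$is_monophyletic == "yes" && rB$is_monophyletic == "yes")
        "yes" else "no", per_gene)
}
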