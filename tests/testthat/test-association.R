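specimens6 <- function() {
  make_specimens(
    ids = c("a1", "a2", "b1", "u1", "l1", "l2", "l3"),
    stages = c("adult", "adult", "adult", "adult", "larva", "larva", "larva"),
    species = c("sp_a", "sp_a", "sp_b", "", "", "", ""))
}

test_that("cluster criterion accepts clean co-clustering and flags mixtures", {
  spec <- specimens6()
  # clean: a-adults with two larvae; b alone; one larva with b
  part <- cluster_partition(list(c("a1", "a2", "l1", "l2"), c("b1", "l3")),
                            gene = "COI", method = "PTP")
  out <- cluster_criterion(part, spec, "sp_a")
  expect_equal(out$outcome, "yes")
  expect_setequal(out$larvae, c("l1", "l2"))
  expect_equal(cluster_criterion(part, spec, "sp_b")$larvae, "l3")

  # mixed adult species vetoes
  part2 <- cluster_partition(list(c("a1", "a2", "b1", "l1")),
                             gene = "COI", method = "PTP")
  out2 <- cluster_criterion(part2, spec, "sp_a")
  expect_equal(out2$outcome, "no")
  expect_match(out2$detail, "sp_b")

  # unidentified adults do not veto but are recorded
  part3 <- cluster_partition(list(c("a1", "a2", "u1", "l1")),
                             gene = "COI", method = "PTP")
  out3 <- cluster_criterion(part3, spec, "sp_a")
  expect_equal(out3$outcome, "yes")
  expect_match(out3$detail, "unidentified")

  # no adult of the species on this gene: not evaluable
  part4 <- cluster_partition(list(c("b1", "l1")), gene = "COI", method = "PTP")
  expect_equal(cluster_criterion(part4, spec, "sp_a")$outcome,
               "not_evaluable")
  expect_error(cluster_criterion(part, spec, "sp_z"), "sp_z")
})

test_that("a split species with a stray larva fails the criterion", {
  spec <- specimens6()
  # species a split over two clusters; hypothesized larva l2 sits alone
  part <- cluster_partition(list(c("a1", "l1"), c("a2"), c("l2")),
                            gene = "COI", method = "PTP")
  out <- cluster_criterion(part, spec, "sp_a",
                           candidate_larvae = c("l1", "l2"))
  expect_equal(out$outcome, "no")
  expect_match(out$detail, "l2")
  # without the hypothesis the co-clustered larva alone is enough
  expect_equal(cluster_criterion(part, spec, "sp_a")$outcome, "yes")
})

test_that("the vote counts yes outcomes and requires three of five", {
  expect_equal(vote(c(a = "yes", b = "yes", c = "yes", d = "yes", e = "yes")),
               list(n_fulfilled = 5L, success = TRUE))
  expect_equal(vote(c(a = "yes", b = "yes", c = "no", d = "no", e = "yes")),
               list(n_fulfilled = 3L, success = TRUE))
  expect_equal(vote(c(a = "no", b = "no", c = "no", d = "no", e = "yes")),
               list(n_fulfilled = 1L, success = FALSE))
  # not_evaluable counts as not fulfilled
  expect_equal(
    vote(c(a = "yes", b = "yes", c = "not_evaluable", d = "yes", e = "no")),
    list(n_fulfilled = 3L, success = TRUE))
  expect_error(vote(c(a = "yes", b = "yes")), "five")
  expect_error(vote(c(a = "yes", a = "yes", b = "no", c = "no", d = "no")),
               "duplicate")
  expect_error(vote(c(a = "maybe", b = "yes", c = "no", d = "no", e = "no")),
               "yes/no")
})

test_that("the vote is symmetric and monotone in its inputs", {
  set.seed(4)
  for (rep in 1:20) {
    v <- sample(c("yes", "no", "not_evaluable"), 5, replace = TRUE)
    names(v) <- paste0("c", 1:5)
    base <- vote(v)
    perm <- sample(5)
    expect_equal(vote(setNames(v[perm], names(v))), base)
    i <- sample(which(v != "yes"), 1)
    if (length(i)) {
      v2 <- v; v2[i] <- "yes"
      expect_gte(vote(v2)$n_fulfilled, base$n_fulfilled)
    }
  }
})

make_two_gene_partitions <- function(clusters_by_gene_method) {
  out <- list()
  for (g in names(clusters_by_gene_method))
    for (m in names(clusters_by_gene_method[[g]]))
      out[[paste0(g, "_", m)]] <-
        cluster_partition(clusters_by_gene_method[[g]][[m]], gene = g,
                          method = m)
  out
}

test_that("congruent partitions yield single-species OTUs with full votes", {
  spec <- make_specimens(
    ids = c("a1", "a2", "b1", "b2", "l1", "l2"),
    stages = c("adult", "adult", "adult", "adult", "larva", "larva"),
    species = c("sp_a", "sp_a", "sp_b", "sp_b", "", ""))
  cls <- list(list(c("a1", "a2", "l1"), c("b1", "b2", "l2")))
  parts <- make_two_gene_partitions(list(
    CAD = list(PTP = cls[[1]], GMYC = cls[[1]]),
    COI = list(PTP = cls[[1]], GMYC = cls[[1]])))
  phy <- ape::read.tree(text = "(((a1:1,a2:1):1,l1:2):2,((b1:1,b2:1):1,l2:2):2);")
  trees <- list(CAD = gene_tree(phy, "CAD"), COI = gene_tree(phy, "COI"))
  rows <- assemble_otus(parts, spec, trees = trees, support_threshold = 0)
  expect_equal(length(rows), 2)
  expect_equal(rows$sp_a$n_fulfilled, 5)
  expect_true(rows$sp_a$success)
  expect_equal(rows$sp_a$larval_association_level, "species")
  expect_setequal(rows$sp_a$larvae, "l1")
  expect_equal(rows$sp_b$larvae, "l2")
})

test_that("shared clusters merge species into a complex that fails", {
  spec <- make_specimens(
    ids = c("a1", "a2", "b1", "b2", "c1", "c2", "l1"),
    stages = c(rep("adult", 6), "larva"),
    species = c("sp_a", "sp_a", "sp_b", "sp_b", "sp_c", "sp_c", ""))
  mixed <- list(c("a1", "a2", "b1", "b2", "l1"), c("c1", "c2"))
  clean <- list(c("a1", "a2", "l1"), c("b1", "b2"), c("c1", "c2"))
  parts <- make_two_gene_partitions(list(
    CAD = list(PTP = clean, GMYC = clean),
    COI = list(PTP = mixed, GMYC = mixed)))
  rows <- assemble_otus(parts, spec)
  expect_setequal(names(rows), c("sp_a-complex", "sp_c"))
  cx <- rows$`sp_a-complex`
  expect_setequal(cx$species_members, c("sp_a", "sp_b"))
  expect_false(cx$success)
  expect_equal(cx$larval_association_level, "otu_only")
  verdicts <- vapply(cx$outcomes, `[[`, "", "outcome")
  expect_equal(unname(verdicts[c("COI_PTP", "COI_GMYC")]), c("no", "no"))
})

test_that("larvae never co-clustered with adults form larva-only OTUs", {
  spec <- make_specimens(
    ids = c("a1", "a2", "l1", "l2", "l3"),
    stages = c("adult", "adult", "larva", "larva", "larva"),
    species = c("sp_a", "sp_a", "", "", ""))
  cls <- list(c("a1", "a2"), c("l1", "l2"), c("l3"))
  parts <- make_two_gene_partitions(list(CAD = list(PTP = cls, GMYC = cls)))
  rows <- assemble_otus(parts, spec, genes = c("CAD", "COI"))
  expect_setequal(names(rows), c("sp_a", "sp. l1 (L)", "sp. l3 (L)"))
  lo <- rows$`sp. l1 (L)`
  expect_equal(lo$species_members, character(0))
  expect_setequal(lo$larvae, c("l1", "l2"))
  expect_equal(lo$larval_association_level, "otu_only")
  verdicts <- vapply(lo$outcomes, `[[`, "", "outcome")
  expect_true(all(verdicts == "not_evaluable"))
  # the adult-only OTU has no larvae at all
  expect_equal(rows$sp_a$larval_association_level, "none")
})

test_that("summaries count OTUs and association levels", {
  rows <- list(
    structure(list(otu = "x", species_members = "x", larvae = c("l1", "l2"),
                   outcomes = list(), n_fulfilled = 4, success = TRUE,
                   larval_association_level = "species"),
              class = "association_row"),
    structure(list(otu = "y-complex", species_members = c("y", "z"),
                   larvae = "l3", outcomes = list(), n_fulfilled = 1,
                   success = FALSE, larval_association_level = "otu_only"),
              class = "association_row"),
    structure(list(otu = "w", species_members = "w", larvae = character(0),
                   outcomes = list(), n_fulfilled = NA, success = NA,
                   larval_association_level = "none"),
              class = "association_row"))
  s <- summarize_associations(rows)
  expect_equal(s$n_otus, 3)
  expect_equal(s$n_species_level, 1)
  expect_equal(s$n_otu_level, 1)
  expect_equal(s$n_larvae_species, 2)
  expect_equal(s$n_larvae_otu, 1)
})

test_that("the published worked example reproduces its printed counts", {
  rows <- example_association_table()
  printed <- attr(rows, "printed_counts")
  computed <- vapply(rows, `[[`, 0L, "n_fulfilled")
  expect_equal(length(rows), 32)
  expect_equal(sum(!is.na(printed)), 13)
  expect_equal(unname(computed[!is.na(printed)]), printed[!is.na(printed)])
  s <- summarize_associations(rows)
  expect_equal(s$n_otus, 32)
  expect_equal(s$n_species_level, 9)
  expect_equal(s$n_otu_level, 7)
})
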