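gt4 <- function(sup = c(NA, 0.99, 0.80)) {
  # ((A,B)0.99,(C,D)0.80) with root support NA (convention fills 1.0)
  gene_tree(balanced4(), gene = "COI", supports = sup)
}

test_that("monophyly verdicts follow exclusivity and support", {
  gt <- gt4()
  # all tips: root clade, support 1 by convention
  r <- test_monophyly(gt, c("A", "B", "C", "D"))
  expect_equal(r$is_monophyletic, "yes")
  expect_equal(r$clade_support, 1.0)
  # supported sister pair
  expect_equal(test_monophyly(gt, c("A", "B"))$is_monophyletic, "yes")
  # clade exists but support below threshold; passes with filtering off
  r2 <- test_monophyly(gt, c("C", "D"), support_threshold = 0.95)
  expect_equal(r2$is_monophyletic, "no")
  expect_match(r2$reason, "support")
  expect_equal(test_monophyly(gt, c("C", "D"),
                              support_threshold = 0)$is_monophyletic, "yes")
  # non-exclusive target
  r3 <- test_monophyly(gt, c("A", "C"), support_threshold = 0)
  expect_equal(r3$is_monophyletic, "no")
  expect_setequal(r3$clade_members, c("A", "B", "C", "D"))
  # single or absent target tips are not evaluable
  expect_equal(test_monophyly(gt, "A")$is_monophyletic, "not_evaluable")
  expect_equal(test_monophyly(gt, c("X", "Y"))$is_monophyletic,
               "not_evaluable")
})

test_that("raising the support threshold never turns no into yes", {
  set.seed(19)
  for (rep in 1:20) {
    phy <- ape::rcoal(8)
    gt <- gene_tree(phy, gene = "g", supports = runif(phy$Nnode, 0.3, 1))
    target <- sample(phy$tip.label, sample(2:5, 1))
    verdicts <- vapply(c(0, 0.5, 0.9, 0.99), function(th)
      test_monophyly(gt, target, support_threshold = th)$is_monophyletic, "")
    ranks <- c(yes = 1, no = 0)[verdicts]
    expect_true(all(diff(ranks) <= 0))
  }
})

test_that("verdicts agree with exhaustive clade enumeration", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    phy <- ape::rcoal(n)
    sup <- runif(phy$Nnode, 0.3, 1)
    gt <- gene_tree(phy, gene = "g", supports = sup)
    for (th in c(0, 0.95)) {
      target <- sample(phy$tip.label, sample(2:n, 1))
      got <- test_monophyly(gt, target, support_threshold = th)$is_monophyletic
      want <- oracle_monophyly(phy, target, sup, th)
      expect_equal(got, want)
    }
  }
})

test_that("reciprocal monophyly requires the same larvae on both genes", {
  phyA <- ape::read.tree(text = "(((a1:1,a2:1):1,l1:2):2,(b1:1,l2:1):3);")
  phyB <- phyA
  tA <- gene_tree(phyA, gene = "CAD")
  tB <- gene_tree(phyB, gene = "COI")
  # adults a1,a2 with larva l1 form an exclusive clade on both genes
  r <- reciprocal_monophyly(tA, tB, adults = c("a1", "a2"),
                            larvae_hypothesis = "l1", support_threshold = 0)
  expect_equal(r$outcome, "yes")
  # wrong larva: clade not exclusive
  r2 <- reciprocal_monophyly(tA, tB, adults = c("a1", "a2"),
                             larvae_hypothesis = "l2", support_threshold = 0)
  expect_equal(r2$outcome, "no")
  # paraphyletic on gene B only
  phyB2 <- ape::read.tree(text = "(((a1:1,b1:1):1,l1:2):2,(a2:1,l2:1):3);")
  tB2 <- gene_tree(phyB2, gene = "COI")
  r3 <- reciprocal_monophyly(tA, tB2, adults = c("a1", "a2"),
                             larvae_hypothesis = "l1", support_threshold = 0)
  expect_equal(r3$outcome, "no")
})

test_that("larvae missing one gene are dropped from both targets", {
  # l1 has no tip on gene B; the hypothesis shrinks to the shared larvae
  phyA <- ape::read.tree(text = "(((a1:1,a2:1):1,l1:2):2,(b1:1,b2:1):3);")
  phyB <- ape::read.tree(text = "((a1:1,a2:1):2,(b1:1,b2:1):2);")
  tA <- gene_tree(phyA, gene = "CAD")
  tB <- gene_tree(phyB, gene = "COI")
  r <- reciprocal_monophyly(tA, tB, adults = c("a1", "a2"),
                            larvae_hypothesis = "l1", support_threshold = 0)
  expect_equal(length(r$larvae_tested), 0)
  # with l1 dropped from both genes, the adults alone are exclusive
  expect_equal(r$outcome, "yes")
})

test_that("reciprocal monophyly is not evaluable below two specimens per gene", {
  phyA <- ape::read.tree(text = "((a1:1,l1:1):1,(b1:1,b2:1):1);")
  phyB <- ape::read.tree(text = "((a1:1,b1:1):1,b2:2);")
  tA <- gene_tree(phyA, gene = "CAD")
  tB <- gene_tree(phyB, gene = "COI")
  # on gene B the species has a single specimen (a1): not evaluable
  r <- reciprocal_monophyly(tA, tB, adults = "a1", larvae_hypothesis = "l1",
                            support_threshold = 0)
  expect_equal(r$outcome, "not_evaluable")
})

test_that("monophyly honors haplotype tip maps", {
  phy <- ape::read.tree(text = "((H1:1,H2:1):1,H3:2);")
  gt <- gene_tree(phy, gene = "g",
                  tip_map = list(H1 = c("s1", "s2"), H2 = "s3", H3 = "s4"))
  r <- test_monophyly(gt, c("s1", "s2", "s3"), support_threshold = 0)
  expect_equal(r$is_monophyletic, "yes")
  expect_setequal(r$clade_members, c("s1", "s2", "s3"))
  # exclusivity is judged at tip level: s2 shares a haplotype tip with s1
  # (identical sequence) so it cannot veto, but it is reported as a member
  r2 <- test_monophyly(gt, c("s1", "s3"), support_threshold = 0)
  expect_equal(r2$is_monophyletic, "yes")
  expect_true("s2" %in% r2$clade_members)
  # a distinct-haplotype outsider still vetoes
  expect_equal(test_monophyly(gt, c("s1", "s4"),
                              support_threshold = 0)$is_monophyletic, "no")
})
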