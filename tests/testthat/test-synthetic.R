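small_cfg <- function(seed = 1, ...) {
  sim_config(n_species = 5, samples_per_species = 4, seed = seed,
             genes = list(
               CAD = list(ne = 0.02, subst_rate = 0.02, seq_length = 40,
                          missing_prob = 0, rate_jitter_cv = 0),
               COI = list(ne = 0.005, subst_rate = 0.1, seq_length = 40,
                          missing_prob = 0, rate_jitter_cv = 0)), ...)
}

test_that("simulated datasets have the declared structure", {
  ds <- simulate_dataset(small_cfg(seed = 21))
  expect_equal(nrow(ds$specimens), 20)
  for (g in c("CAD", "COI")) {
    phy <- ds$genes[[g]]$tree_time$phy
    expect_equal(sort(phy$tip.label), sort(names(ds$species_truth)))
    expect_true(is_ultrametric(phy))
    # substitution tree shares the topology at rate-scaled depth
    expect_true(ape::all.equal.phylo(phy, ds$genes[[g]]$tree_subst$phy, use.edge.length = FALSE))
    expect_equal(ds$genes[[g]]$alignment$length, 40)
    # species_truth partitions tips into 5 sets of 4
    expect_equal(sort(unname(table(ds$species_truth[phy$tip.label]))),
                 rep(4L, 5), ignore_attr = TRUE)
  }
  # adults carry labels, immatures do not
  expect_true(all(ds$specimens$species[ds$specimens$stage != "adult"] ==
                    "UNKNOWN"))
  expect_true(all(ds$specimens$species[ds$specimens$stage == "adult"] !=
                    "UNKNOWN"))
})

test_that("simulation is deterministic given the seed", {
  d1 <- simulate_dataset(small_cfg(seed = 33))
  d2 <- simulate_dataset(small_cfg(seed = 33))
  expect_identical(d1, d2)
  d3 <- simulate_dataset(small_cfg(seed = 34))
  expect_false(identical(d1$genes$COI$tree_time$phy, d3$genes$COI$tree_time$phy))
})

test_that("a single species yields a pure coalescent tree", {
  cfg <- sim_config(n_species = 1, samples_per_species = 8, seed = 3,
                    genes = list(COI = list(ne = 0.01, subst_rate = 0.1,
                                            seq_length = 20, missing_prob = 0,
                                            rate_jitter_cv = 0)))
  ds <- simulate_dataset(cfg)
  phy <- ds$genes$COI$tree_time$phy
  expect_equal(length(phy$tip.label), 8)
  expect_true(is_ultrametric(phy))
  # no between-species nodes: no support pinned at exactly 1
  expect_true(all(ds$genes$COI$tree_time$supports < 1))
})

test_that("between-species nodes carry support 1, within-species less", {
  ds <- simulate_dataset(small_cfg(seed = 8))
  gt <- ds$genes$CAD$tree_time
  spans <- stagematch:::.node_species_spans(gt$phy, ds$species_truth)
  expect_true(all(gt$supports[spans >= 2] == 1))
  expect_true(all(gt$supports[spans == 1] < 1))
  expect_true(all(gt$supports[spans == 1] >= 0.5))
})

test_that("missingness drops specimens from trees and availability columns", {
  cfg <- sim_config(n_species = 5, samples_per_species = 6, seed = 9,
                    genes = list(
                      CAD = list(ne = 0.02, subst_rate = 0.02, seq_length = 20,
                                 missing_prob = 0.3, rate_jitter_cv = 0)))
  ds <- simulate_dataset(cfg)
  have <- ds$specimens$id[ds$specimens$has_CAD]
  expect_setequal(ds$genes$CAD$tree_time$phy$tip.label, have)
  expect_lt(length(have), 30)
})

test_that("within-species divergence scales with the coalescent Ne", {
  mean_within <- function(ne, seed) {
    cfg <- sim_config(n_species = 4, samples_per_species = 6, seed = seed,
                      genes = list(g = list(ne = ne, subst_rate = 1,
                                            seq_length = 10, missing_prob = 0,
                                            rate_jitter_cv = 0)))
    ds <- simulate_dataset(cfg)
    phy <- ds$genes$g$tree_time$phy
    dd <- ape::cophenetic.phylo(phy)
    sp <- ds$species_truth[rownames(dd)]
    same <- outer(sp, sp, "==") & upper.tri(dd)
    mean(dd[same])
  }
  lo <- mean(vapply(1:8, function(s) mean_within(0.005, 100 + s), 0))
  hi <- mean(vapply(1:8, function(s) mean_within(0.02, 100 + s), 0))
  # expectation scales linearly (4x); allow generous stochastic slack
  expect_gt(hi / lo, 2)
  expect_lt(hi / lo, 8)
})

test_that("paraphyly injection breaks monophyly on the chosen gene only", {
  cfg <- small_cfg(seed = 55)
  ds <- simulate_dataset(cfg)
  sp <- c("sp01", "sp02")
  ds0 <- inject_paraphyly(ds, sp, swap_fraction = 0, gene = "COI", seed = 5)
  expect_identical(ds0, ds)

  dsx <- inject_paraphyly(ds, sp, swap_fraction = 1, gene = "COI", seed = 5,
                          cfg = cfg)
  dsx2 <- inject_paraphyly(ds, sp, swap_fraction = 1, gene = "COI", seed = 5,
                           cfg = cfg)
  expect_identical(dsx, dsx2)
  expect_true(is_ultrametric(dsx$genes$COI$tree_time$phy))

  donor_ids <- names(ds$species_truth)[ds$species_truth == "sp01"]
  r_coi <- test_monophyly(dsx$genes$COI$tree_time, donor_ids,
                          support_threshold = 0)
  r_cad <- test_monophyly(dsx$genes$CAD$tree_time, donor_ids,
                          support_threshold = 0)
  expect_equal(r_coi$is_monophyletic, "no")
  expect_equal(r_cad$is_monophyletic, "yes")
  # recipient also no longer exclusive on COI
  recip_ids <- names(ds$species_truth)[ds$species_truth == "sp02"]
  expect_equal(test_monophyly(dsx$genes$COI$tree_time, recip_ids,
                              support_threshold = 0)$is_monophyletic, "no")
})

test_that("datasets write to the formats the readers consume", {
  ds <- simulate_dataset(small_cfg(seed = 71))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  spec <- read_specimen_table(file.path(dir, "specimens.tsv"))
  expect_equal(nrow(spec), 20)
  gt <- read_gene_tree(file.path(dir, "COI_time.nwk"), gene = "COI",
                       tip_map = read_tip_map(file.path(dir, "COI_tipmap.tsv")))
  expect_true(is_ultrametric(gt))
  aln <- read_alignment(file.path(dir, "COI.fasta"), gene = "COI")
  expect_equal(length(aln$seqs), 20)
})
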