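---
title: "Life-stage association from two-locus data: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-stage association from two-locus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagematch)
```

## The problem

In many insect groups only adult males can be identified to species, so
larvae — often the stage that matters ecologically — cannot be named by
morphology. Given DNA from both adults and immatures at two loci (a slow
nuclear marker and the fast mitochondrial COI barcode), larvae can be
attached to adult morphospecies wherever both fall into the same molecular
cluster. `stagematch` implements that procedure end to end: haplotype
collapsing, two single-locus delimitation models (GMYC and PTP), a
cross-locus reciprocal-monophyly test, and a five-criterion consensus vote
that assembles OTUs and species complexes.

## The GMYC model

The single-threshold GMYC treats an ultrametric gene tree as a Yule
diversification process older than a threshold age $T$ and independent
single-population coalescents younger than $T$. Branches crossing $T$
define the delimited entities. Sorting node ages into inter-event
intervals $i$ of duration $x_i$, the total event rate in interval $i$ is

$$r_i = \lambda_\mathrm{div}\, k_i^{p_\mathrm{div}} +
        \lambda_\mathrm{coal} \sum_j \big[n_{ij}(n_{ij}-1)\big]^{p_\mathrm{coal}},$$

where $k_i$ counts between-species lineages (the number of entities once
the process is younger than $T$) and $n_{ij}$ the lineages of coalescent
cluster $j$. The exponents $p$ relax the pure Yule ($p=1$) and Kingman
($p=1$) forms toward population growth or decline.

Two constructions of the event terms appear in the branching-process
literature; they differ in whether the term for an observed branching uses
the whole rate of its process class or only the component of the single
subprocess that fired. This package uses the **process-level** term: a
within-species node contributes
$\log \lambda_\mathrm{coal} \sum_j [n_{ij}(n_{ij}-1)]^{p_\mathrm{coal}}$,
a between-species node
$\log \lambda_\mathrm{div} k_i^{p_\mathrm{div}}$. Intervals are oriented
from the present toward the root with counts taken on the younger side of
each event, which makes the null model (threshold older than the root)
exactly the Kingman coalescent density — the test suite checks this
against the closed form. During development we also evaluated the
finer-grained per-cluster event term; it systematically favours
near-singleton partitions (a single power law $k^p$ on the lineage-through-
time curve can then mimic both timescales), while the process-level term
recovers simulated species structure, so the latter is the package's
construction.

### Fitting

For fixed exponents both rates have closed-form maximum-likelihood values
($\hat\lambda = $ events / integrated exposure), so the optimizer works on
the two exponents only, clamped to $[0, 10]$, with three fixed Nelder-Mead
starts. Candidate thresholds are midpoints between consecutive distinct
node ages plus one older than the root (which *is* the null model, so
`logL >= null_logL` holds by construction); ties break toward the older
threshold, i.e. fewer, more inclusive entities. The likelihood-ratio test
against the null uses a $\chi^2$ approximation with df = 2 by default
(df = 3 is also in circulation and is configurable); on 200 simulated
single-population trees the df = 2 test rejected at 5.5% for
$\alpha = 0.05$, which the acceptance suite re-measures. Zero-length and
tied-age internal branches are spread apart by $10^{-12}$ time units so
every interval has positive duration (the soft-polytomy convention).

GMYC expects haplotype trees: if the tip map is the identity the fit warns
that the tree does not look collapsed.

## The PTP model

PTP drops the clock: on a substitution-scaled tree, branch lengths are
modelled as exponential with one rate for between-species branches and one
for within-species branches. A candidate delimitation is an antichain of
nodes whose clades partition the tips; branches inside a delimited clade
are "within", all others "between", and each class's rate is profiled in
closed form, so scoring a partition is $O(1)$ after one tree traversal.

* `fit_ptp_exact()` enumerates every clade partition (feasible to 12 tips;
  the count is verified against an independent recursion in the tests) —
  the oracle.
* `fit_ptp_heuristic()` hill-climbs over split/merge moves on the antichain
  from the one-cluster, all-singleton and seeded random starts; it is
  deterministic given its seed and never exceeds the exact optimum.

Zero-length branches carry no information about either rate class and are
excluded from the likelihood (counted and reported). If a partition has no
within-branches (all clusters singletons) the within rate is undefined and
the model collapses to the between class only, flagged in the result. The
LRT against the single-class null uses df = 1 (one extra rate) by default.

## Monophyly and the five-criterion vote

`test_monophyly()` finds the smallest clade containing the target
specimens' tips and requires it to contain no other tips; with support
filtering on (default threshold 0.95, the conventional posterior cut-off)
the defining node must also be supported. The root counts as support 1.0.
Exclusivity is judged at tip level, so on haplotype-collapsed trees a
specimen sequence-identical to a target cannot veto. Whether the original
procedure required support on the defining node or used supports only
descriptively is ambiguous; both behaviours are available
(`support_threshold = 0` disables filtering) and reports record the
setting.

Reciprocal monophyly requires the *same* larval set with the species'
adults on both genes; specimens missing a gene are excluded from that
gene's target, and the larval hypothesis is restricted to larvae with data
on both genes. Fewer than two target specimens on either gene makes the
test not evaluable.

The five criteria per candidate species are PTP and GMYC on each gene plus
reciprocal monophyly. The cluster criterion is "yes" when larvae share a
cluster with the species' adults, no cluster holding those adults contains
another identified species, and no hypothesized larva clusters away from
the adults. Unidentified adults (e.g. females) never veto but are
recorded. `vote()` counts "yes" outcomes; association succeeds at three or
more. A criterion that cannot be evaluated counts as not fulfilled — the
published worked example's low-count rows (criteria counts 0 and 1) follow
exactly this convention. Pupae are processed as larvae throughout.

OTU assembly builds a graph over identified species (edges: adults sharing
any delimited cluster, or clade intrusion on a gene tree); components of
size > 1 become species complexes named after the alphabetically first
member — the naming rule in the source material is unstated, so
alphabetical is the package's deterministic choice. Larvae never
co-clustered with any identified adult are grouped by co-clustering into
larva-only OTUs named `sp. <smallest id> (L)`.

## The simulator and what it does (not) cover

`simulate_dataset()` draws a Yule species tree, grafts per-species Kingman
coalescent genealogies at its tips, scales branches by a per-gene
substitution rate (optionally Gamma-jittered per branch), evolves
Jukes-Cantor sequences with `phangorn::simSeq()`, labels specimens as
adults (species known) or larvae/pupae (species withheld into
`species_truth`), and drops per-gene availability at a per-gene missingness
probability. Node supports are 1.0 on true between-species nodes and
Uniform(0.5, 1) within species. Everything is deterministic given the
config seed.

Default parameters mirror the motivating study's structure: two genes of
736 and 658 bp; specimen-level missingness of 0.33 (nuclear) and 0.14
(mitochondrial), matching the fraction of specimens sequenced per locus
there; a larva fraction of 0.6 and pupa fraction of 0.015 (313 larvae and
8 pupae of 525 specimens); and a mitochondrial effective size one quarter
of the nuclear value, the standard expectation for a haploid maternally
inherited locus. The default within-species scale (nuclear `ne = 0.02`
against a Yule rate of 1) deliberately includes recently diverged species —
the regime that produces species complexes in real data.

Simplifications to keep in mind: within-species coalescence is forced to
complete inside the species' stem (a genealogy deeper than 90% of the stem
is rescaled into it), so there is no incomplete lineage sorting unless
`inject_paraphyly()` creates it explicitly by re-attaching one species'
lineages inside another's clade; there is no migration model, no rate
heterogeneity among sites, and sequences play no role downstream of the
trees (the delimiters consume trees). Passing tests therefore demonstrate
correctness of the inference machinery under the models' own assumptions,
not robustness to ILS, introgression or alignment error in field data.

## Validation design and problem sizes

The acceptance suite validates at three levels, with sizes chosen to keep
the full run in a few minutes:

* **Oracle equivalence.** GMYC fits match a dense grid search (0.05 grid
  plus a bounded PORT polish) within $10^{-4}$ on 50 trees of up to 8
  tips; heuristic PTP matches exact enumeration on at least 95 of 100
  trees of up to 10 tips and never exceeds it; monophyly verdicts match
  exhaustive clade enumeration on 200 random trees exactly.
* **Calibration.** On 200 simulated 10-species datasets (5 samples each)
  GMYC must recover exactly 10 entities in at least 80% of replicates; on
  200 single-population trees the null LRT must reject between 2% and 10%
  at $\alpha = 0.05$. The recovery simulations use a within-species
  `ne = 2e-4` against a Yule rate of 1: recovery degrades steeply once a
  species pair's divergence falls within roughly an order of magnitude of
  the coalescent mean (the classic recent-divergence failure mode), so the
  validation regime keeps essentially all Yule splits clear of that zone,
  and the residual misses are exactly the replicates whose youngest split
  is not.
* **End-to-end precision.** Across 20 deep two-gene replicates with
  missingness, every larva associated at species level must carry the
  withheld true label (precision 1.0); injecting full COI paraphyly
  between one species pair must merge exactly that pair into a single
  complex row with `success = FALSE`.

The packaged worked-example table transcribes 32 published per-OTU rows;
`vote()` rebuilds all 13 printed criteria counts and the summary yields
9 species-level and 7 OTU-level associations. One row of the published
table is internally inconsistent (its printed per-criterion cells sum to
one less than its printed count); the fixture follows the count column and
flags the discrepancy in its `note` column.

## Known limitations

* GMYC run-to-run variation reported for real COI trees stems from tree
  stochasticity; this implementation is deterministic given a fixed tree
  and seed, and makes no claim about stability across posterior trees.
* The PTP search differs from the original program's; equivalence is
  guaranteed only against this package's own exact enumerator.
* Species complexes are reported, never resolved — that requires
  multi-locus multispecies-coalescent methods outside this scope.
* The likelihood-ratio χ² approximations are approximations; the df
  defaults (2 for GMYC, 1 for PTP) are conventions, and the calibration
  test documents their realized behaviour rather than asserting exactness.
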