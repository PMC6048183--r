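Package: stagematch
Title: Molecular Life-Stage Association via GMYC, PTP and Reciprocal Monophyly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates morphologically unidentifiable immature specimens
    (larvae, pupae) with adult morphospecies using two-locus DNA data.
    Implements single-threshold GMYC (generalized mixed Yule coalescent)
    delimitation on ultrametric haplotype trees, maximum-likelihood Poisson
    tree process (PTP) delimitation on substitution-scaled trees,
    support-aware reciprocal monophyly testing across gene trees, and a
    five-criterion consensus vote that assembles operational taxonomic units
    (OTUs) and species complexes. Includes haplotype collapsing, alignment
    summary statistics, and a coalescent-within-Yule simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
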