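Package: chipreps
Title: Replicate-Aware Quality Control and Consensus Peak Analysis for ChIP-seq
Version: 0.1.0
Authors@R: person("chipreps", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing and exploiting biological replication in
    ChIP-seq experiments with three or more replicates. Implements three
    tiers of quality control (library complexity via the PCR bottleneck
    coefficient, fraction of reads in peaks, strand cross-correlation
    NSC/RSC), multi-replicate peak overlap with majority-rule consensus
    classification, four consensus-region definitions (MAX, SMT, ASF, ASW)
    with RPKM quantification, a detection-above-background (DABG) Z-test
    that rescues peaks missed by a caller in a subset of replicates, and
    pairwise concordance statistics (weighted Kappa of quintile-binned
    coverage, Spearman correlation, Bland-Altman limits of agreement,
    McNemar symmetry test). A multi-replicate simulator with known truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
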