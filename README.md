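# chipreps

Replicate-aware quality control and consensus peak analysis for ChIP-seq
experiments with three or more biological replicates.

## What it is for

ChIP-seq peak calling is noisy: independent biological replicates of the
same experiment produce visibly different peak lists, and requiring a peak
in *every* replicate (absolute consensus) discards real binding sites at a
rate that grows with the number of replicates. `chipreps` is for analysts
who have per-replicate peak calls (BED6/narrowPeak) and aligned-read
positions (BED) and want to:

* run three tiers of QC — library complexity (PBC), global enrichment
  (FRIP), strand cross-correlation (NSC/RSC), cross-replicate overlap and
  identification agreement (simple agreement, McNemar), and quantitative
  concordance (weighted Kappa, Spearman, Bland–Altman);
* call consensus regions under a **strict majority rule** — a region is
  accepted when called in more than 50 % of replicates (3 of 5, 2 of 3; not
  2 of 4) — with four region definitions (MAX, SMT, ASF, ASW);
* rescue peaks a caller missed with the **DABG** test: a one-sided Z-test of
  a region's RPKM in a dropout replicate against that replicate's own
  background (its called-peak RPKMs below their 25th percentile).

The statistical core: with per-replicate detection probability *p* and *n*
replicates, a true site survives the majority rule with probability
P(Bin(n, p) > n/2) versus pⁿ under absolute consensus — at p = 0.8, n = 5
that is 0.942 vs 0.328. A built-in simulator generates multi-replicate
experiments with known truth (detection dropout, boundary jitter, spurious
replicate-private peaks, enriched reads over uniform background) so every
claim is testable without external data.

## Worked example

```r
library(chipreps)

cfg <- sim_config(n_sites = 120, n_replicates = 5, p_detect = 0.8,
                  reads_per_replicate = 50000, seed = 42)
sim <- simulate_experiment(cfg)

groups <- classify_groups(group_peaks(sim$peak_sets))
groups$class_counts
#>        unique       partial      majority    common_all majority_rule
#>           268             7            72            42           114

cons <- build_consensus(groups, "MAX", chrom_sizes(cfg$genome))
cov  <- quantify(cons, sim$read_sets)
head(round(cov$rpkm, 2), 3)
#>              rep1    rep2    rep3    rep4    rep5
#> grp_00001  659.34  109.89  549.45  219.78  659.34
#> grp_00002 7171.05 8223.68 9144.74 7105.26 9013.16
#> grp_00003  320.86  320.86  748.66  534.76    0.00

round(concordance_report(cov)[1:3, c("kappa_weighted", "spearman_rho",
                                     "ba_bias")], 3)
#>   kappa_weighted spearman_rho ba_bias
#> 1          0.501        0.703   6.244
#> 2          0.453        0.644   9.701
#> 3          0.457        0.657   1.683

rec <- truth_recovery(sim, groups)
c(majority = rec$majority, common_all = rec$common_all)
#> 0.958, 0.358   (binomial expectations: 0.942, 0.328)

round(qc_report(sim$read_sets$rep1, sim$peak_sets$rep1, "rep1",
                read_length = 36)[c("pbc", "frip", "nsc", "rsc")], 3)
#>     pbc  frip     nsc    rsc
#> 1 0.946 0.221 106.095 67.044
```

Reading the output: 42 regions were called in all five replicates and a
further 72 in a strict majority — the majority rule nearly triples the
consensus set, and the observed fractions of true sites recovered (0.958
majority, 0.358 absolute) match the binomial tails. The 268 unique groups
are dominated by simulated spurious calls. PBC 0.95 marks a complex library
(flag level 0.7); a weighted Kappa of ~0.5 on five rank bins is moderate
agreement at this shallow simulated depth (the 0.75 "excellent" flag is
reported per pair).

The full pipeline (QC1 → overlap/QC2 → consensus → RPKM → DABG → QC3
→ optional promoter/genic features) runs from files via `run_pipeline()`,
or from the installed command-line front-end:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/chipreps.R", package="chipreps"))')" \
  simulate --out-dir sim --seed 1
Rscript .../chipreps.R run \
  --peaks sim/rep1.peaks.bed,...,sim/rep5.peaks.bed \
  --reads sim/rep1.reads.bed,...,sim/rep5.reads.bed \
  --chrom-sizes sim/genome.chrom.sizes --gff sim/genes.gff3 --out-dir out
```

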