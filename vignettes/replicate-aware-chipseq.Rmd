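---
title: "Replicate-aware ChIP-seq QC and consensus peaks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-aware ChIP-seq QC and consensus peaks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipreps)
```

## The problem

ChIP-seq experiments locate protein–DNA binding genome-wide, but peak
identification is noisy: the same biological signal yields different peak
lists across biological replicates, across peak callers, and across
parameter settings. When an experiment has three or more replicates, the
practical questions are (i) which per-replicate peaks describe the same
binding region, (ii) how much support a region needs before it is trusted,
(iii) whether a region missing from some replicates was truly absent there
or merely missed by the caller, and (iv) how concordant the replicates are
quantitatively. `chipreps` implements a complete workflow for these
questions, organized as three tiers of quality control:

* **QC1** — read-level metrics per replicate: total and distinct read
  positions, the PCR bottleneck coefficient (PBC).
* **QC2** — peak-level metrics: fraction of reads in peaks (FRIP), strand
  cross-correlation (NSC/RSC), cross-replicate peak overlap, unique/common
  classification, pairwise identification agreement (simple agreement,
  McNemar).
* **QC3** — quantitative agreement of read coverage (RPKM) in consensus
  regions: weighted Kappa of rank-binned coverage, Spearman correlation,
  Bland–Altman limits of agreement.

## Coordinate conventions

All internal coordinates are 0-based half-open, BED's native convention.
GFF/GTF input (1-based inclusive) is converted on ingest, and narrowPeak
summit offsets are converted to absolute positions on ingest, so no
downstream code ever reasons about dialects. Two peaks overlap when they
share at least one nucleotide; under half-open coordinates the abutting
intervals `[100,200)` and `[200,300)` do **not** overlap. Peaks are treated
as unstranded; reads keep strand only for PBC and cross-correlation.

## Peak grouping and the majority rule

Peaks from all replicates are pooled and clustered by **single linkage**:
groups are the connected components of the at-least-one-base overlap graph.
This makes the group, not the individual call, the unit of counting — so
several consecutive narrow calls from one caller that all touch one broad
call from another collapse into a single region, which is the behaviour a
per-region count requires.

A group's *support* is the set of replicates with at least one member peak.
Classes are: `unique` (one replicate), `common_all` (every replicate),
`majority` (strictly more than half but not all), `partial` (the rest). The
majority rule is strict — 3 of 5 and 2 of 3 qualify, 2 of 4 does not — and
nests: every `common_all` group also satisfies it. If per-replicate
detection is independent with probability $p$, a true site is recovered
under the majority rule with probability $P(X > n/2)$, $X \sim
\mathrm{Bin}(n, p)$, versus $p^n$ under absolute consensus; at $p = 0.8$,
$n = 5$ these are 0.942 and 0.328, which is the quantitative case for
majority consensus and the property the acceptance tests check by
simulation.

## Consensus regions

Four summaries of a group's members, computed from whichever subset of
replicates has a call:

* **MAX** — `[min start, max end)`: the maximal span.
* **SMT** — between the outermost summits, inclusive:
  `[min summit, max summit + 1)`, widened symmetrically to a minimum width
  (default 50 bp, configurable) when summits nearly coincide — a
  quantifiable region must have nontrivial width.
* **ASF** — a fixed, biology-supplied footprint width centred on the average
  summit (rounded half-up): `[s − ⌊f/2⌋, s + ⌈f/2⌉)`.
* **ASW** — like ASF but sized by the average called-peak width. The default
  average is the pooled mean width over all replicates' calls, which is more
  stable than a per-group mean (a per-group option exists).

Members lacking a summit (BED6 input) fall back to the interval midpoint;
the count of affected groups is attached to the result. Regions are clipped
to chromosome bounds. A fifth, deliberately naive alternative (`REF`) takes
the peak list of the deepest replicate as the common regions, with ties on
depth broken to the lexicographically first label.

## RPKM and the DABG rescue test

Coverage in a region is RPKM: $c \cdot 10^9 / (L \cdot N)$ for $c$
overlapping reads (each read counted once per region), region length $L$ bp
and $N$ total mapped reads. Reads are counted as aligned, without fragment
extension.

The **detection-above-background (DABG)** test asks, for every (group,
replicate) pair where that replicate called no peak, whether its coverage in
the consensus region is nevertheless high relative to that replicate's own
noise floor. The background sample is the replicate's own called-peak RPKM
values strictly below their 25th percentile (linear interpolation); the
statistic is $z = (x - \bar b)/s_b$ with the sample standard deviation, and
the region is detected when the one-sided upper-tail normal $p < \alpha$
(default 0.05). The normal form is kept deliberately (a t-quantile would
change little at typical background sizes and the normal is what the
procedure's description prescribes). A literal alternative — detected when
the RPKM simply exceeds the 25th percentile — is available as
`method = "threshold"`; the Z-test is the primary reading. Replicates with
fewer than 12 called peaks are skipped: a quartile of fewer than 3 values
cannot anchor the test.

### Calibration of the DABG test, honestly stated

The procedure is *not* exactly calibrated at $\alpha$ for background-level
regions, and the package's acceptance suite says so rather than hiding it.
The background sample is a **truncated** slice of the call distribution:

* If spurious (background-level) calls make up less than a quarter of a
  replicate's peaks, the quartile cut reaches into genuinely enriched calls,
  inflates $s_b$, and the test becomes very conservative (type-I error near
  0).
* If they make up more than a quarter, the background is the noise
  distribution with its upper tail cut off at the quartile boundary, $s_b$
  underestimates the noise spread, and the test is anti-conservative —
  simulations under this package's default world realize type-I errors of
  roughly 0.04–0.09 at $\alpha = 0.05$ across seeds.

Exact calibration occurs only on the knife edge where spurious calls are
exactly the lower quartile. This is a structural property of defining
background as a within-sample quantile slice, not an implementation choice;
the corresponding acceptance assertion is left failing at its stated
tolerance with this analysis, while the qualitative claim that matters —
dropout replicates of majority-supported groups are confirmed at far higher
rates than noise-only unique groups — holds with a wide margin.

## Concordance statistics

Each replicate's RPKM column over the consensus regions is rank-binned into
five equal-count ordinal groups (each column on its own distribution; ties
stay together and fall to the lower bin). Pairwise agreement of the binned
columns is measured by weighted Kappa with linear disagreement weights
$w_{ij} = |i-j|/(k-1)$ by default (quadratic by flag; the convention of
flagging $\kappa > 0.75$ as excellent agreement is reported alongside).
Spearman correlation is computed on the raw columns, and Bland–Altman
analysis reports the mean difference and $\pm 1.96\,\mathrm{sd}$ limits of
agreement on raw RPKM (a `log2(x+1)` option exists). Feature-based
quantification — promoters as TSS ± 2 kb, genic regions as TSS − 2 kb to
TTS + 2 kb, per gene, unmerged — provides the same matrix independent of any
peak caller.

## Strand cross-correlation

For shift $s$, the profile is the Pearson correlation between the
per-position 5′-end count vector of plus-strand reads and the minus-strand
vector shifted left by $s$. The correlation is computed over the whole
zero-padded occupied span (with a margin covering the scan range), via
shift-invariant sufficient statistics plus a sparse cross term — restricting
to co-occupied positions would discard the shared zeros that carry the
co-occupancy signal and make every correlation negative. The fragment peak
is the argmax outside a ±10 bp guard window around the read length (the
"phantom peak"); NSC is the fragment peak over the profile minimum, RSC the
fragment excess over the phantom excess. For a library with no positional
structure at all, every correlation is zero-mean sampling noise and the NSC
ratio of two near-zero numbers is numerically meaningless; the stable
statement of "no enrichment" is that the fragment peak does not stand out
from the background, which is how the tests phrase it.

## The simulator and what a green test establishes

`simulate_experiment()` generates the stated world the tests run in: one
2 Mb chromosome; 200 non-overlapping true sites of width 200 ± 40 bp
(floored at 50 bp); 5 replicates; per-site per-replicate detection with
$p = 0.8$; called-peak boundaries and summits jittered with 20 bp Gaussian
noise but clamped to keep each call overlapping its site; 55
replicate-private noise peaks placed away from true sites; 200,000 reads per
replicate as pseudo-fragment pairs (a plus read at each 150 bp fragment
start, a minus read at its end, 36 bp reads), with 30 % of fragments centred
near true sites — detected or not, since dropout is a property of the
caller, not the chromatin — and 70 % uniform background. All defaults were
fixed once as field-realistic values; the noise-peak count was derived
analytically from the DABG background's quartile precondition (55 of ~215
calls ≈ 26 % replicate-private, realistic for real callers), not tuned
against test outcomes.

The simulator emulates detection dropout, boundary jitter, spurious calls
and enrichment over uniform background. It does **not** emulate mappability
structure, chromatin-state coverage biases, PCR duplication, broad-domain
marks, or caller-specific boundary behaviour. A green suite therefore
establishes that the statistics and the majority/DABG machinery behave as
derived under independent per-replicate detection and Poisson-like
background — not that any particular real dataset will reach a given
agreement level.

## Numerical choices and degenerate inputs

* Percentiles use R's default linear interpolation (type 7).
* The average summit rounds half up (`floor(x + 0.5)`) for determinism.
* McNemar is computed without continuity correction by default (flag to
  enable); discordant counts of zero give statistic 0, $p = 1$.
* `bin_coverage` refuses all-identical columns (binning undefined); `dabg`
  refuses backgrounds with fewer than 3 values or zero spread; RSC is
  reported absent when the phantom correlation equals the background.
* Ties in the deepest-replicate (`REF`) choice break to the first label
  lexicographically and are recorded.
* Chromosome-bound clipping that would empty a region is an error, not a
  silent drop.

## Known limitations

Peak calling and alignment are out of scope — the package consumes their
outputs. IDR-style irreproducibility modelling is intentionally not
implemented; the majority rule plus DABG is the alternative examined here.
RPKM counts unextended reads; fragment-length extension before counting
would shift values slightly but not the agreement statistics built on them.
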