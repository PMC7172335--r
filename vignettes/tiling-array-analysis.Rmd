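---
title: "Methods: tiling-array ChIP-chip analysis with tileChIP"
author: "tileChIP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-array ChIP-chip analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tileChIP)
```

# The data model

A tiling array measures one log2 intensity per oligonucleotide probe per
sample. `tileChIP` represents a mark as a `ProbeTrack` — a
`RangedSummarizedExperiment` whose rows are probes (constant length,
strictly increasing starts per chromosome) and whose columns are samples
labelled by condition and replicate. Probe identity is (chromosome, start)
and every distance rule in the package is measured start-to-start; the
probe start is also the probe's "position" when deciding whether it falls
inside a region. Stages that need one value per probe per condition use
the replicate mean. The package treats the intensity as an opaque,
already-normalized real value; whether it is an IP/input log-ratio or a
single-channel quantity does not enter any formula.

Coordinates are 1-based closed `GRanges` throughout, the Bioconductor
convention; BED (0-based half-open) and wiggle/GFF (1-based) are converted
exactly once at the I/O boundary by `rtracklayer`. This keeps every
overlap and distance rule expressible in one convention with no internal
conversions.

# Peak calling

The neighborhood model has two stages, both exposed:

1. **Probe significance** (`significantProbes`): probe $i$ is significant
   iff at least one *adjacent* probe $j$ lies within `neighborMaxGap`
   (1000 bp) and $\tfrac{1}{2}(p_i + p_j) < \alpha$ with
   $\alpha$ = `probeAlpha` = 0.05, strict inequality. The 1000 bp clause is
   read as defining which adjacent probes count as neighbors — the weakest
   reading consistent with an "averaged p with at least one neighbor"
   rule — and it is isolated behind this one predicate so an alternative
   reading is a one-function change.
2. **Peak assembly** (`callPeaks`): maximal runs of significant probes in
   which consecutive significant probes are at most `peakProbeGap`
   (300 bp) apart; runs with at least `minSigProbes` (4) significant
   probes become peaks spanning from the first significant probe's start
   through the last probe's footprint (start + probe length − 1). The peak
   edge definition (significant-probe footprint) is a package choice; peak
   callers of this family do not agree on edges and nothing downstream
   depends on more than ±1 probe of edge placement.

Per-probe p-values are accepted from any upstream source; when none exist,
`probeSignificance` supplies a robust one-sided upper-tail test against
the array's empirical null, $p_i = 1 - \Phi\!\big((x_i - \mathrm{med}\,x)
/ (1.4826\,\mathrm{MAD}\,x)\big)$, computed genome-wide per sample. The
median/MAD pair is insensitive to the small fraction of truly bound
probes, so the null location and scale come from the unbound bulk. A MAD
of zero (constant array) is an error instructing the caller to supply
p-values directly rather than a silent degenerate result.

Under a uniform null the probability that two adjacent probes average
below 0.05 is $P(U_1 + U_2 < 0.1) = 0.005$, so isolated false significant
probes are common but false *peaks* (four such probes within 300 bp) are
rare — about $1.5\times10^{-4}$ per probe empirically. Precision of the
caller on real or simulated data is therefore governed by true-peak
density; see the generator section.

# Annotation rules

*Promoters* are the `promoterUpstream` (200 bp) immediately 5' of the TSS,
mirrored in genome coordinates for minus-strand genes. A peak receives the
first feature in the rank order promoter ≻ exon ≻ intron ≻ intergenic that
it overlaps by ≥ 1 bp; "intron" means inside some gene span without
matching any promoter or exon. Every "within ± N bp" rule in the package
is implemented as symmetric expansion by N followed by the same ≥ 1 bp
overlap predicate, so boundary cases are decided once, inclusively.

*Divergently paired genes* (DPGs) are (−, +) gene pairs in divergent
orientation — the minus gene's TSS at or left of the plus gene's TSS, so
the transcribed bodies point away — with TSS gap ≤ `dpgMaxTssGap`
(1000 bp), inclusive; a zero gap (coincident TSSs) is allowed, a gene may
appear in several pairs, and ids on a configurable exclusion list
(intended for histone-cluster genes, whose tandem repeats make pairing
meaningless) are skipped. A pair is *bound* when a peak overlaps the union
of 500 bp downstream of either TSS and the inter-TSS span — for a
divergent pair, the single interval [TSS− − 500, TSS+ + 500]. TAD
boundaries count as occupied within `tadBoundarySlack` (5 kb);
`domainBoundaryBinding` reports per-domain whether one or both edges are
hit.

# Permutation enrichment

`shuffleIntervals` re-places each interval independently and uniformly on
its own chromosome, keeping its length and staying in bounds; shuffled
intervals may overlap one another (the procedure has no exclusion clause,
and adding one would bias the null for dense sets). `permutationEnrichment`
counts query intervals with ≥ 1 bp overlap of the slack-expanded subject
set (each query counted once; slack is applied to the subject, matching
"a peak within ±500 bp of an element" counted from the peak), builds the
null from `nPerm` (default 1000) shuffles, and reports
$z = (\mathrm{obs} - \bar{n})/s_n$ with the $n-1$ denominator in $s_n$, a
two-sided normal p (one-sided available), and fold = obs/mean. A null with
zero variance is flagged degenerate and the p-value is `NA`, never a
fabricated zero. Fisher's exact test (two-sided, minimum-likelihood
summation) and the upper-tail hypergeometric test take their count
parameters explicitly — in particular the hypergeometric universe N is
never assumed.

The z-test is an approximation twice over: the null counts are discrete,
and mean/sd are estimated from `nPerm` draws (a t-flavored inflation of
about $P(|t_{n-1}|>1.96)$ instead of 0.05). The calibration test in the
suite measures the realized type-I rate at |z| > 1.96 over 500 independent
null data sets and requires it inside the 99% binomial band around 0.05;
with `nPerm` = 120 the expected rate is ≈ 0.053.

# Profiles, pausing, and per-gene tests

`anchoredProfile` places probe values at anchor-relative coordinates
(reflected for minus-strand anchors and for domain end-boundaries, so
positive positions always point into the gene or domain), computes the
windowed statistic over the centered window $[p - w/2,\, p + w/2)$ (length
exactly $w$, step 1 bp), and aggregates across anchors with the same
statistic, *ignoring empty windows* — zero-filling would imprint the probe
spacing on the aggregate. Default windows: 10 bp for domain profiles over
boundary ± 10 kb and center ± 5 kb; 100 bp for Pol II profiles over
TSS − 2 kb..+ 5 kb, with a 900 bp moving-average smoother
(`smoothProfile`, shrinking windows at the edges so length is preserved).

`domainSignalTest` pools every probe value inside any domain per condition
and applies a two-sample t test. Welch's unequal-variance form is the
default wherever a "Student's t test" is called for — it is never worse
than the pooled form and costs nothing; the pooled form is a flag away.

`classifyPolII` compares the per-gene *median* signal over probes in the
strand-oriented paused region (TSS−30..+300) between mutant and control:
mutant lower → category 1, higher → category 2. Genes shorter than
`minGeneLen` (1000 bp), genes with no probes in the paused region, and
exact ties are excluded with a recorded reason — a binary higher/lower
rule leaves ties undefined, and at float precision they essentially only
arise when the two conditions are byte-identical. Gene-body medians
(TSS+1000..TES) are reported alongside; a gene whose TES is within
1000 bp of its TSS has no body region and body medians of `NA`.

`regionTest` runs a per-gene two-condition test over probes in a named
region — paused, body, H3K4me3 (TSS..+2000) or H3K27me3 (TSS+200..+2200)
— using the Mann-Whitney U (exact for small tie-free samples, normal
approximation with tie correction otherwise) or Welch t, then
Benjamini-Hochberg across all tested genes. The unit of replication is the
probe, matching the pooled-probe wording of the domain test; treating
replicate arrays as the unit instead would need more replicates than these
designs have. `foldCategory` bins expression ratios as none (< 2),
moderate (2–5), high (> 5–10), maximal (> 10), closed on the right; and
`chromatinChangeClass` combines the H3K27me3 and H3K4me3 per-gene results
into K27depletedOnly / K4enrichedOnly / both / unchanged (a significant
change in the "wrong" direction maps to unchanged, per the three-way
scheme).

# Motif scanning

`fitBackground` counts (k+1)-mers over the literal text (optionally
augmented with the reverse complement) with a pseudocount (default 0.1)
per transition. The order is a parameter because fitting order 7 — the
order used with genome-scale promoter sets — needs far more sequence than
a test fixture; orders 0–2 behave identically in every formula. Both
readings of a "k bp" background (order k vs k-mer frequencies = order
k−1) are reachable by setting the order.

`scanPwm` scores both strands with
$s = \sum_i \log_2 \mathrm{pwm}[i, b_i] / \mathrm{bg}_0(b_i)$, using the
background's order-0 marginal in the denominator: a per-position p-value
requires a position-independent null, so higher-order structure enters
only the fit, not the scan null. The p-value of a score is the exact
probability that a random order-0 background word scores at least as high,
computed by dynamic programming over a score lattice with granularity
10⁻³ bits; sequence windows are scored on the same lattice, so DP
p-values match exhaustive word enumeration exactly rather than to within
a rounding step. Zero PWM cells score −∞ and can never be hits; their
probability mass is tracked separately so the survival function still
sums to one. Minus-strand hits are scored against the reverse-complement
matrix's own null, which matters when the background is not
complement-symmetric; fitting with `bothStrands = TRUE` makes the two
strands exactly mirror-equivalent. `scanConsensus` converts an IUPAC
string to a 0/1 acceptance matrix; its p-value is the closed-form match
probability (product of admitted-base marginals), and hits are only
reported when that probability clears the threshold — `YAACKG` under a
uniform background gives $2/4 \cdot 2/4 \cdot (1/4)^4 = 1/1024 < 0.001$.
De novo motif discovery is out of scope; matrices are user inputs.

# Pseudomedian smoothing and ΔΔCt

`pseudomedianSmooth` replaces each probe value by the one-sample
Hodges–Lehmann estimator of its `pseudomedianSpan` (3) probe window: the
median of all Walsh averages $(x_i + x_j)/2$, $i \le j$, including
$i = j$. Span is counted in probes (the smoothing tools of this family
take a probe-count span), windows shrink at chromosome ends, and span 1 is
the identity. The classical pseudomedian is used; a "modified" variant
referenced in some pipelines has no accessible definition, and the
classical estimator carries the same robustness guarantee (bounded by the
window extremes, resistant to a single outlier).

`ddctFold` implements ΔΔCt with amplification efficiency fixed at 2:
technical replicates are averaged first, then biological replicates;
$\mathrm{fold} = 2^{-\Delta\Delta C_t}$ with
$\Delta\Delta C_t = (C_t^{target} - C_t^{ref})_{sample} -
(C_t^{target} - C_t^{ref})_{calibrator}$. Per-biological-replicate folds
(each biorep's sample-side ΔCt against the calibrator-side mean) give the
SEM and a two-sided unpaired t test against the calibrator-side replicate
folds. Exactly, fold(sample, calibrator) · fold(calibrator, sample) = 1
and adding a constant to every Ct changes nothing.

# What the generator emulates — and what it does not

`simulateAnnotation` packs non-overlapping genes on both strands of a
multi-chromosome genome (default 4 × 500 kb, 200 genes of 1.5–8 kb), with
a `dpgFraction` of genes arranged head-to-head at TSS gaps uniform on
[50, 1000] bp and all other adjacencies kept ≥ 1100 bp apart, so the
planted pairs are provably the only divergent pairs — `findDPGs` recovery
is an exact-equality test, not a statistical one.

`simulateChipTracks` builds a regular probe grid (spacing 33 bp, the
median spacing of the high-density tiling design this emulates; 50-mer
probes) and three marks: a factor track of N(0, `noiseSd`²) background
plus boxcar peaks of height `peakSnr`·`noiseSd` (defaults 4 and 0.3) over
150 planted 300 bp intervals — the density, one peak per ~13 kb, mirrors
the genome-wide peak density of the mapping study this design emulates,
and at test scale it is what makes caller precision a meaningful number;
an H3K27me3-like mark with a plateau (2.0) over ~10–30 kb domains,
multiplied by `domainDepletion` (0.5) in the mutant; and a Pol II mark
with a paused-region spike (4.0) and gene-body plateau (1.0), where
regime-1 genes lose both in the mutant (×0.5, ×0.5) and regime-2 genes
gain pausing and lose body (×1.5, ×0.5). `simulateSequences` emits
promoter windows (TSS ± 500) of i.i.d. sequence at a chosen GC with
exact-consensus motif instances planted at recorded positions/strands.

Deliberately *not* emulated: dye bias and spatial artifacts, replicate
batch effects, probe affinity variation, correlated noise along the
array, repeat-induced cross-hybridization, and multi-isoform gene
structure. Passing tests therefore demonstrate the correctness of the
rules and statistics on clean signal of realistic geometry — not
robustness to array pathology, which belongs to the normalization stage
that is out of scope here. All generators are bit-reproducible under a
seed, and generated files re-read through the package's own I/O reproduce
the in-memory objects.

# Test problem sizes and numerical choices

The suite checks every operation against an independent brute-force
oracle on instances small enough to enumerate (≤ 300 probes for the peak
caller, ≤ 10 kb profiles, all 256 words for length-4 PWMs, every
placement of a 10 bp interval on a 1 kb chromosome), and the end-to-end
guarantees at the generator's default scale: 20 seeds of a 2 Mb genome
for peak recovery and domain depletion, 10 seeds of 200 genes for Pol II
regime recovery, 500 independent null data sets at `nPerm` = 120 for
z-calibration — sizes chosen so the whole suite exercises every stage in
a few minutes while leaving the statistical assertions comfortable
margins. Ties at thresholds are resolved the way each rule is printed:
p-means exactly at α are not significant, TSS gaps exactly 1000 bp are
pairs, folds exactly 5 and 10 stay in the lower band, and paused-median
ties are excluded rather than forced into a category.

# Known limitations

- The per-probe p-value construction is a declared stand-in: the original
  per-array neighborhood model presumes per-probe p-values whose exact
  construction varies between implementations, so `callPeaks` accepts
  external p-values to decouple the two.
- The permutation z-test inherits the normal approximation; for very
  sparse subject sets use more permutations or read the raw null counts
  from the `EnrichmentResult`.
- `anchoredProfile` with the median statistic recomputes each window;
  genome-scale median profiles at 1 bp steps are the slowest path in the
  package.
- One transcript model per gene id: multi-isoform TSS selection is the
  caller's responsibility.
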