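---
title: "Methods: screen hit calling, dynamic binding, and network targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen hit calling, dynamic binding, and network targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adipodyn re-implements, as a tested and reusable toolkit, the statistical
machinery used to identify and characterize pro-adipogenic transcription
factors: arrayed overexpression-screen hit calling, genomic-interval
integration with shifted-peak nulls, negative-binomial (NB) differential
binding and expression, position-weight-matrix (PWM) scanning, and
permutation tests for regulatory-network targeting. Every stage can be
exercised end-to-end on synthetic data with planted ground truth.

```{r setup, message = FALSE}
library(adipodyn)
```

## Screen hit calling

Each well of an arrayed overexpression screen yields a percentage of
differentiated cells (PDC): the number of cells with at least four lipid
droplets divided by the total cell count. Per replicate, wells are
standardized against the negative-control wells (the "normal transform"):
$z = (\mathrm{PDC} - \bar{c}) / s_c$ with $\bar c, s_c$ the control mean
and standard deviation of that replicate. Replicates are combined by
Stouffer's method, $z_\mathrm{comb} = \bar z \sqrt{R}$ over $R$
replicates, converted to a two-sided normal p-value and
Bonferroni-corrected over the number of non-control constructs. A
construct is a hit when its fold change (construct mean PDC over the
pooled control mean PDC) is at least 1.5 **and** its family-wise error is
at most 0.05.

Two points were genuinely open and are decided here:

* **Replicate combination.** The source analysis states only that three
  technical replicates were tested at a family-wise error of 0.05.
  Stouffer combination of per-replicate z-scores is the default (smooth,
  standard, and easy to reason about); the stricter "every replicate
  individually significant" rule is available via
  `call_screen_hits(..., combine = "all-significant")`.
* **Bonferroni denominator.** The number of non-control constructs tested
  (734 in the motivating screen); controls are excluded.

```{r screen}
sim <- sim_screen(screen_config(n_constructs = 200, n_planted = 5), seed = 1)
hits <- call_screen_hits(sim$table)
glance(hits)
```

The generator's defaults are the study conditions: 734 constructs, three
replicates, a mean control differentiation level of 0.479 with a
plate-level standard deviation of 0.05 (a typical well-to-well spread for
an imaging readout), 30 negative-control wells per replicate, and planted
enhancers shifted by 10 control standard deviations at a target fold
change of 2. Because the configuration carries both an effect size in
standard-deviation units and a target fold change, the planted mean is
`min(0.99, max(control_mean * planted_fc, control_mean + units * sd))`,
which realizes both under the defaults.

## Interval arithmetic and shifted-peak nulls

All coordinates are 0-based half-open (BED convention) on disk and in
memory. Peak calls from two callers are merged by coalescing overlapping
or bookended intervals; the merged summit is the summit of the
highest-scoring constituent (midpoint if no scores). Peaks are annotated
with the priority scheme TSS (within ±500 bp of a TSS), exon, intron,
proximal (within 10 kb of a gene), distal — the first matching category
wins, so the categories partition any peak set.

Background expectations use *shifted peaks*: every interval is re-placed
uniformly at random on its own chromosome with its length preserved.
Keeping peaks on their chromosome preserves per-chromosome composition;
the re-placement distribution was not specified in the source analysis
and uniform placement is the standard choice. Co-binding enrichment
reports the observed overlap count, the mean overlap over `n_shifts`
shifted copies, their ratio (fold), a two-sided Fisher exact p on the 2×2
table built from observed vs expected overlapping counts — the table
construction is a package choice, documented here, since the source does
not state one — and a permutation p-value
$(1 + \#\{\text{shifts} \ge \text{obs}\})/(n_\mathrm{shifts}+1)$, which
is always reported alongside and never smaller than
$1/(n_\mathrm{shifts}+1)$.

Summit-centered signal matrices extend each tag to 200 bp in its strand
direction, sum per-base coverage in 400 bins of 5 bp spanning 2 kb around
each summit, divide by per-sample size factors and transform with
log2(x+1); the pseudocount makes the transform defined at zero coverage
and is the only deviation from a bare log2 (which the source leaves
unspecified).

## NB differential test

Counts over regions (or genes) are normalized with median-of-ratios size
factors: the factor of a sample is the median, over features with
all-positive counts, of that sample's count divided by the feature's
geometric mean.

The differential test is an exact-style NB test authored in the package
(the original analysis used an external NB package; numerical concordance
with it is not promised — planted-truth recovery is the test surface):

1. **Dispersion.** Per feature, a method-of-moments estimate
   $\hat\alpha = (\hat v - \xi \hat m)/\hat m^2$ is formed *within each
   condition* (variance and squared mean from the same condition, pooled
   with degree-of-freedom weights; using the across-condition mean would
   structurally inflate dispersions of genuinely differential features),
   where $\xi$ is the mean reciprocal size factor. A trend
   $\alpha(m) = a_0 + a_1/m$ is fitted across features, and per-feature
   estimates are shrunk toward it on the log scale with a weight derived
   from the delta-method sampling variance of $\log\hat\alpha$ versus the
   across-feature spread in excess of sampling noise (an empirical-Bayes
   prior in the spirit of modern count-model packages). The log-scale
   combination is corrected for the downward bias of the log of a
   variance estimate, $\log(df/2) - \psi(df/2)$; without that correction
   the null far tail is anticonservative.
2. **Test.** With $q$ the pooled mean of normalized counts, the condition
   sums $K_A, K_B$ are NB with means $q S_A, q S_B$ and variances
   $qS + \alpha q^2 \sum s_j^2$. The two-sided p-value sums the
   probabilities of all allocations $a + (k - a) = K_A + K_B$ that are no
   more probable than the observed split, normalized by the total.
3. **Multiplicity.** Benjamini–Hochberg within each analysis; Bonferroni
   only in the screen, mirroring the source conventions.

Classification thresholds are inclusive and follow the published rules:
expression up means FC ≥ 1.5 and padj ≤ 0.01, down means FC ≤ 0.67 and
padj ≤ 0.01; dynamic binding (late vs early) uses FC ≥ 2 and padj ≤ 0.1
to call late-only or early-only regions, everything else static. Genes
are classified from regions overlapping the gene body plus 500 bp
upstream of the TSS: at least one early-only region makes an early-only
gene; at least one late-only and no early-only region makes a late-only
gene; only static regions make a static-only gene. A fold change on a
feature with a zero condition mean uses a pseudocount of 0.5 normalized
counts on both sides; all-zero features are reported `untested` and
excluded from multiplicity correction.

When no condition has two replicates the dispersion falls back to a
pooled estimate across all samples with a logged warning — mirroring
time-course designs where adjacent time points stand in as replicates.
The sample-to-condition map is always explicit (`condition` column), so
any such pairing is the caller's visible decision.

## PWM scanning

A PWM is a 4×L log-odds matrix; count or probability matrices are
converted against a uniform background with a +0.25 pseudocount per cell
(the source does not state its background model; uniform is the neutral
choice). A window's score fraction is
$(\mathrm{raw} - \min)/(\max - \min)$ over the attainable score range,
and scanning reports every window on both strands, in forward
coordinates, at or above the cutoff (default 0.85, the published
setting). `N` bases score the position minimum (conservative). Per-peak
statistics scan 100 bp centered on the summit; motif density profiles
count hit starts in 10-bp bins over ±400 bp and normalize to hits per bp
per peak.

## Permutation tests for network targeting

The targeting statistic is the number of network genes that are both
bound and down-regulated. The null redraws gene sets of the network's
size uniformly without replacement from a universe — by default the
expressed genes of the experiment, since the source does not name its
universe — and the permutation p is
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_\mathrm{perm} + 1)$ at
10,000 permutations. Sampling gene sets is equivalent to shuffling
labels; sets are sampled for reproducibility. "Regulated" defaults to
the down class at the pre-adipocyte thresholds, with any-change available
through the caller's choice of gene sets. The same machinery tests a
binary label among screen candidates (the Expression-Atlas-style
comparison). The shipped network fixture is a curated adipogenic
gene-regulatory-network membership assembled from the WikiPathways
adipogenesis scaffold and standard reviews, since the exact published
figure membership is not machine-readable; it is documented as curated
and used for examples.

## What the synthetic data emulate — and what they do not

The generators are pure functions of (config, seed). They emulate the
*statistical* structure the analyses assume: non-overlapping gene bodies
with 1–5 exons; i.i.d. background sequence at a configured GC content;
peak sets with exact planted fractions of early-only (bound at
timepoints 1–2), late-only (3–4) and static regions; co-binding planted
as second-factor summits within 100 bp; NB counts with
variance = mean + α·mean²; consensus motifs inserted so the full motif
lies within ±50 bp of the summit; and screen plates with truncated-normal
control wells. Every region carries a baseline occupancy (`depth_mean`,
default 50 expected tags) and dynamic regions *gain* 2^planted_log2fc
binding in their bound phase — the natural generative reading, under
which a 4-fold planted change at this depth is recoverable at ≥90%
sensitivity by any well-calibrated NB test (we verified that placing the
*depleted* phase at 12.5 expected tags instead makes that recovery
unattainable for reference implementations as well).

They do **not** emulate read-level sequence errors, fragment-length
distributions, GC- or mappability-bias, spatial plate effects, or
correlated dispersion structure. Passing the planted-truth suites
therefore demonstrates correctness of the statistical machinery under
its own model, not robustness to those real-data artifacts.

Problem sizes in the test-suite and acceptance runs (600–1000 peaks,
1000–2000 count features, 2 chromosomes of 1 Mb, 734-construct screens,
100 shifts, 10,000 permutations) were chosen as the smallest sizes at
which the Monte-Carlo error of each measured property is comfortably
below its acceptance margin.

## Numerical choices and degenerate inputs

* Ties in closest-gene assignment resolve to the lexicographically
  smallest gene id; distances are bp gaps with bookended intervals at
  distance 0.
* Fisher's exact test falls back to the permutation p alone when the
  shifted expectation is 0 with a positive observation (fold reported as
  infinite).
* Chi-square cluster enrichment uses Yates continuity correction and
  falls back to Fisher's exact test (flagged) when any expected cell is
  below 5.
* The Wilcoxon comparison of regulator sets is exact for both sets ≤ 8
  without ties, normal-approximated with tie correction otherwise.
* Score-fraction cutoffs are applied with a 1e-9 tolerance so that
  cutoff = 1 retains exact-consensus windows under floating-point
  arithmetic.
* Degenerate PWMs (min = max), empty wells, zero-variance controls,
  fewer than two control wells, all-zero count features, and intervals
  longer than their chromosome raise informative errors rather than
  propagating NaNs.

## Known limitations

* The NB test assumes a two-condition comparison; GLM designs are out of
  scope.
* Dispersion shrinkage assumes many features share a mean–dispersion
  trend; with very few features (tens) the trend fit is weak and the
  prior defaults widen.
* The exact-style allocation sum is O(total count) per feature; for very
  deep data a normal approximation would be preferable, but at the
  depths used here the exact sum is fast and was kept for fidelity.
* Shifted-peak nulls preserve lengths and chromosome assignment but not
  local chromatin context; enrichment folds against them should be read
  as genome-composition-level statements.
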