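---
title: "Methylation landscapes from probe-level enrichment data: models and design"
author: "dmrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation landscapes from probe-level enrichment data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(dmrscape)
    library(GenomicRanges)
    library(SummarizedExperiment)
})
```

# The problem

Methylated-DNA immunoprecipitation hybridized to tiling arrays (MeDIP-chip)
yields probe-level enrichment log-ratios rather than absolute methylation
levels. Between-tumor analysis of such data asks three questions this
package answers in sequence:

1. **Where does methylation vary between tumors?** Contiguous stretches of
   high-variance probes define *between-tumor differentially methylated
   regions* (DMRs) — deliberately not tumor-vs-normal contrasts.
2. **How is the variation organised?** Stable tumor subgroups are derived
   from DMR methylation, and subgroup-specific DMRs partition into a small
   number of archetypal patterns with distinct genomic contexts
   (CpG-poor/heterochromatic vs CpG-island/poised-promoter vs
   shore/regulatory).
3. **What does it do?** DMR methylation is integrated with gene expression,
   regulatory-factor occupancy, and, for a two-block HOX-like locus, a
   switch-like classification with survival stratification.

Every stage consumes objects a Bioconductor user will recognise: probes are
a `RangedSummarizedExperiment` subclass (`ProbeMatrix`), DMRs another
(`DMRSet`), annotation tracks are `GRanges` bundled in `GenomeTracks`.

# The DMR caller

The statistic for a probe is its across-sample variance (unbiased, n−1
denominator); region candidates are maximal runs of at least `minProbes`
(default 4) consecutive probes at or above the `variancePercentile` of all
probe variances (default 90th; ties at the threshold are included), with
inter-probe gaps at most `maxGapBp` (default 500) and a span of at least
`minLengthBp` (default 500 bp). The candidate statistic is the mean of
member-probe variances.

Significance is assessed against a **CpG-density-matched permutation
null**: probes are binned by local CpG density (CpG count divided by probe
length) into quantile bins computed over *all* probes (default deciles —
matching against the genome-wide probe distribution, not the candidate
set), and each candidate is compared with `nPermutations` random same-size
probe sets drawn from its density bin (the bin holding the majority of its
probes; a bin too small to supply a draw is widened to its neighbours with
a warning). The empirical p-value uses the add-one estimator
(1 + #{null ≥ observed})/(1 + B), which cannot return zero and remains
valid under Benjamini–Hochberg correction. Surviving candidates closer
than `mergeDistanceBp` (default 200) are merged; per-sample means of member
probes are attached.

Density matching matters because CpG-dense probes have systematically
different signal characteristics on enrichment platforms; an unmatched null
would convert CpG density into spurious significance.

Degenerate inputs are defined, not errors: a constant matrix yields an
empty `DMRSet`; fewer than 8 samples is refused.

## Normalization

Raw two-channel intensities are reduced to scores by a five-step scheme,
each step individually switchable through `normParams()`:

1. per-probe log2(IP/input);
2. per-array median centering (array medians are zero to 1e−9 afterwards);
3. across-array quantile normalization (`limma::normalizeQuantiles`);
4. per-array CpG-count bias removal, subtracting a loess fit of score on
   probe CpG count (span 0.75, degree 1; skipped when an array is constant
   or the design has too few distinct CpG counts);
5. a running mean over `smoothingWindow` adjacent probes (default 3) that
   never crosses inter-probe gaps above `maxGapBp`, truncating at run
   edges.

The steps are switchable because two-channel normalization pipelines vary
between labs; the order above (ratio → location → distribution → covariate
→ spatial) is the conventional one and each step is testable in isolation.

# Subgrouping and the three patterns

Samples are clustered by **bootstrap consensus hierarchical clustering**:
`B` resamples of DMR features (rows, with replacement), average linkage on
1 − Pearson correlation between samples, co-clustering frequencies recorded
at each candidate `k`. The final partition cuts the consensus matrix; `k`
is chosen by the *worst-cluster* criterion — the minimum within-cluster
consensus minus the maximum between-cluster-pair consensus. This score
plateaus under nested structure (merging two stable groups is itself
stable) and cliffs as soon as a stable group is split arbitrarily, so among
ks on the plateau the finest stable partition is selected (tolerance 0.1,
small against the observed cliff of ≥ 0.3). A plain mean-within minus
mean-between score is monotone along the plateau and cannot make this
choice, which is why the worst-case form is used. With `B = 1` no
resampling occurs and the result equals plain hierarchical clustering.

Subgroup-specific DMRs are screened by one-way ANOVA (equal-variance F,
computed vectorised over features and verified against `stats::aov` in the
test suite) with Benjamini–Hochberg correction. Significant DMRs are
clustered (1 − Pearson, Ward) into three clusters, and clusters are mapped
to the archetypes by cosine similarity of their mean subgroup profile:

* **pattern 1** — monotone decrease over subgroups 1→4 (demethylation with
  grade; CpG-poor, repeat-rich, subtelomeric, heterochromatic context);
* **pattern 2** — elevated only in subgroup 3 (CpG-island gain in
  poised-promoter context, EZH2/CTCF/RAD21-bound);
* **pattern 3** — monotone increase over subgroups 1→4 (shore/regulatory
  context, flanking transcription-machinery binding).

The mapping must be bijective and untied, otherwise an error asks for
manual inspection — a deterministic replacement for labeling heatmaps by
eye.

The top-variance preselection keeps `floor(fraction · n)` features
(default 25%); floor is used so that a quarter of 5,453 regions is 1,363.

# Genomic context

`basewiseOverlap()` counts exact covered bases per track label under
half-open on-disk semantics (tracks are reduced per label, so overlapping
same-label intervals never double-count). Consensus chromatin state is the
basewise majority, ties resolved to the lowest state number —
deterministic and rare under genuine tilings. Aggregation profiles
(`windowProfile()`) record per-anchor basewise occupancy across fixed
windows on DMR midpoints (or strand-flipped TSSs); the aggregate frequency
divides by the number of anchors covering each position, so windows
truncated at chromosome edges are handled by the denominator rather than
padding. Per-anchor rows and an occupied-bases sort key are retained for
heat-strip displays.

CGI *shores* are the 2-kb flanks of CpG islands excluding the islands
themselves; 2 kb is the community convention. Subtelomeric means within
5 Mb of a chromosome end. Repeat content is measured in a 2-kb window on
the DMR midpoint. Enrichment uses the two-sided Fisher test
(point-probability rule, the convention that reproduces the published
cohort-table p-values — verified in the acceptance tests), Mann–Whitney or
Kruskal–Wallis for continuous features, and one-sided hypergeometric tests
with BH correction for gene-set overlap.

Regulatory-factor occupancy is a binary DMR × (RF, cell line) matrix with
a ≥ 1 bp overlap rule. Co-binding has two modes: `any_cell_same_cell`
(all named RFs share at least one cell line on the DMR) and `all_cells`
(the RF set binds in every cell line); the latter implies the former,
which the suite checks as a property. The binary matrix is clustered with
Jaccard distance and average linkage (the distance for binary occupancy
data; identical columns are guaranteed adjacent).

# Expression integration

DMRs pair with every gene whose TSS lies within 10 kb (configurable;
many-to-many allowed). Rather than per-pair permutation p-values, a single
two-sided **empirical |r| threshold** is derived: expression sample labels
are permuted `nResamples` times, all pair correlations recomputed, and the
threshold is the smallest observed |r| at which (mean null exceedances) /
(observed exceedances) ≤ the nominal FDR. One global threshold matches the
practice of deriving empirical significance cutoffs for correlation
screens and is cheap enough to recompute under resampling. Pairs with
fewer than 5 shared samples are dropped with a warning; below 100
resamples the threshold is flagged unstable. Pearson is the default
(Spearman available) since enrichment scores and array expression are
approximately continuous and the planted relationship is linear.

# The locus switch

A `LocusModel` is an ordered DMR list with a boundary splitting an
anterior from a posterior block — the boundary is *input*, taken from
biology (for HOXA, between the HOXA7 and HOXA9 promoters), never inferred.
Samples are k-means clustered (k = 3, best of 50 restarts) on their locus
methylation vectors. Clusters map to labels deterministically: each
block's cluster means are dichotomized at the midrange of cluster means —
high posterior/low anterior is `posterior_only`, the reverse
`anterior_only`, both high `pan`. The cohort median was rejected as the
cut because it degenerates exactly when one state covers half the cohort
(as it does here: 62 of 98 samples carry anterior methylation). An
ambiguous mapping is an error listing the cluster profiles.

Group differences use Welch t-tests (the robust default when only
"t-test" is specified) per data level with BH correction within level; a
DMR–gene pair is *called* when both levels pass FDR < α (default 0.01),
and starburst coordinates are the signed −log10(q) per level so threshold
crossings reproduce the calls exactly. Survival stratification is the
k-group logrank test with no covariate adjustment.

# The synthetic cohort

The generator produces every input with known truth. Its defaults are the
study conditions: tumor subgroups of 18/21/24/35 samples plus 4 normals;
672/650/1375 DMRs of patterns 1/2/3; three 30-Mb chromosomes (small
enough for brute-force oracles, large enough for 5-Mb subtelomere logic);
contiguous 100-bp probes, at least 4 per DMR; per-pattern CpG densities
0.014/0.048/0.022 CpG/bp against a 0.011 background (drawn as Poisson
counts per probe). Scores are subgroup means plus Gaussian noise
(`noiseSd` 0.5); the default `effectSize` 2.5 places the planted effect at
five noise SDs, the regime in which the caller is expected to reach ≥ 0.9
recall and precision. Where the source material states no magnitudes
(noise, effect sizes, expression correlation strength), the defaults are
choices, not calibrations to any dataset.

Two design points deserve explanation:

* **Equal pattern variances.** The monotone patterns' amplitudes are
  scaled (≈ 1.15× for the default subgroup sizes, computed from those
  sizes, never hard-coded) so all three archetypes contribute equal
  between-sample variance. Without this, the subgroup-3-only pattern
  dominates every top-variance selection and the cohort collapses to a
  one-pattern problem — unlike real cohorts, where all patterns appear
  among the most variable regions. The pattern-2 step stays exactly
  `effectSize`.
* **Placement slots.** DMRs and null-probe blocks occupy disjoint slots
  with generous buffers, pattern-1 slots confined to the 5-Mb
  subtelomeres, everything else to the interior. This guarantees planted
  context (CGIs, peaks, repeats, segment states) never collides across
  patterns, making by-construction assertions exact. A chromosome too
  short for the request is an immediate sizing error.

Normals are fully methylated at pattern-1 regions (tumors lose
methylation) and unmethylated at patterns 2–3 (tumors gain), giving
tumor-minus-normal deltas their expected signs. A raw-signal mode emits
two-channel pseudo-intensities whose log-ratio is the intended score plus
a per-array offset and a CpG-linear trend, exercising normalization
steps 2 and 4. Planted expression is generated from the *measured* DMR
means (population correlation −0.8 by default for 30% of pattern-3 DMRs),
so recovery tests exercise the full path including probe noise.

What the generator does **not** emulate: realistic sequence content,
copy-number structure, batch effects beyond the array-bias model,
correlated noise between neighbouring probes, or cell-type admixture.
Passing tests therefore demonstrate the machinery's correctness and
calibration under the assumed statistical structure, not performance on
any real cohort.

# Problem sizes and determinism

The test suite and the acceptance script run the pipeline at one tenth of
the study's per-pattern DMR counts (67/65/137 planted DMRs, 30,000
background probes, full 98 + 4 sample layout) — large enough for the
recovery and calibration behaviour to be stable, small enough that
brute-force per-base oracles and permutation nulls run in seconds. Null
caller calibration uses 100 matrices of 2,000 probes × 40 samples;
empirical-FDR calibration uses 20 null expression cohorts at 300
resamples; survival power uses 100 simulations at the cohort's 36/62
group split with a hazard ratio of 3.

Every stochastic function takes an explicit seed, and generators are
byte-identical under identical configurations. Permutation p-values use
the add-one estimator; all BH corrections are `stats::p.adjust`; Fisher
tests are two-sided with the point-probability rule throughout.

# Known limitations

* The five normalization steps reconstruct a scheme whose published
  definition is not available in detail; they are conventional but not
  authoritative, hence individually switchable.
* The bootstrap consensus scheme likewise reconstructs a cited method
  from its description; B, linkage and distance are configurable.
* The empirical-FDR threshold is global across pairs; class-specific
  thresholds (e.g. by CpG density) are not implemented.
* The caller's variance statistic is exactly invariant to shifts of whole
  probes or of all samples, but a shift of a *single* sample perturbs
  every probe variance by a sample-dependent amount; calls are stable in
  practice but not algebraically invariant to that operation.
* Chromatin-state transition summaries assume consensus states, not
  basewise transitions.

# A worked example

```{r example, eval = FALSE}
cfg <- simConfig(nDmrsPerPattern = c(67L, 65L, 137L),
                 nNullProbes = 30000L, seed = 1L)
sim <- simulateProbeMatrix(cfg)
tracks <- simulateTracks(cfg, sim$truth)

dmrs <- callDmrs(sim$probes, dmrCallParams(seed = 1L))
means <- dmrMeans(dmrs)[, colData(sim$probes)$sample_type == "tumor"]

bh <- bootstrapHclust(selectTopVariance(means, 0.25), kRange = 2:8,
                      B = 500, seed = 1L)
# pattern archetypes are defined over subgroups *ordered* 1..4 (grade-like
# ordering); relabel discovered clusters accordingly before this step
subgroups <- sim$truth@subgroups[colnames(means)]
an <- anovaSubgroupDmrs(means, subgroups)
patterns <- derivePatterns(means[an$significant, ], subgroups)

cfx <- contextFeatures(rowRanges(dmrs), tracks)
table(patterns$pattern, cfx$consensus_state.H1ESC[an$significant])
```
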