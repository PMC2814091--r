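---
title: "senemeth: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{senemeth: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## 1. The measurement model

Infinium-style methylation arrays interrogate each CpG with two bead types;
the methylated-channel fluorescence $M$ and unmethylated-channel
fluorescence $U$ are summarized as a *beta value*

$$\beta = \frac{M}{M + U + \alpha}, \qquad \beta \in [0, 1),$$

the approximate fraction of methylated molecules at that CpG. The offset
$\alpha$ (default **100 fluorescence units**, the platform convention;
$\alpha = 0$ supported) regularizes low-intensity assays. `compute_beta()`
implements exactly this; assays with zero total intensity become missing
values with a warning rather than `NaN`.

Two quality steps precede analysis:

* **Detection filtering** (`filter_by_detection()`): a CpG is dropped when
  the fraction of samples whose detection p-value exceeds `alpha_det`
  (default 0.01) is greater than `max_fail_fraction` (default 0: any
  failing sample removes the CpG). The strict default reflects a regime in
  which only few sites should fail; both knobs are configurable. Surviving
  values are never altered.
* **Quantile normalization** (`quantile_normalize()`): every column is
  mapped onto the common distribution of across-column means of order
  statistics, preserving within-column ranks. The transform is idempotent
  and column-permutation-equivariant, which the tests assert directly.

Numerical choices in normalization:

* **Ties** receive the mean of the order-statistic means across their tied
  ranks, making the map deterministic and idempotent even on degenerate
  input. (For tie-free matrices the result coincides with
  `limma::normalizeQuantiles(ties = TRUE)`, which the unit tests use as an
  independent oracle.)
* **Missing values**: CpGs with any missing entry are excluded from
  normalization and reported, mirroring the policy of removing unreliable
  signals outright rather than imputing them.
* A **single-row matrix** normalizes to its row mean, the limiting case of
  the definition.
* Whether normalization should act on beta values or on channel
  intensities is ambiguous in array practice; this package normalizes
  **betas** by default (the exported quantity), and `compute_beta()` plus
  `quantile_normalize()` compose in either order if intensities are
  preferred.

## 2. Differential methylation

The study design is 8 donors (4 young, 21–50 y; 4 elderly, 53–85 y), each
with an early-passage (P2) and a late-passage (P8–P15) sample: 16 samples.
Two contrasts are defined on it:

* **culture**: early vs late passage, all donors (`culture_contrast()`);
* **aging**: young vs elderly donors at early passage only
  (`aging_contrast()`), because donor age should be compared before
  culture-acquired changes accumulate.

Per CpG, `contrast_stats()` reports the group means, the effect
$\Delta\beta = \bar\beta_B - \bar\beta_A$, the two-sided **pooled-variance
Student's t** (default) or the **paired one-sample t** on within-donor
differences, the p-value from the t distribution with the corresponding
degrees of freedom, and Benjamini–Hochberg q-values across all tested
CpGs. Unpaired equal-variance t is the default because it is the stated
method of the analysis this package re-implements; the paired option is
the statistically natural choice for the early/late same-donor design and
is exposed as a flag. Zero-variance conventions: identical groups give
$t = 0, p = 1$; a nonzero delta with zero pooled variance gives $p = 0$.

`classify_dm()` labels a CpG *hyper* when $\Delta\beta$ **strictly
exceeds** the relevance threshold (default 0.20, i.e. "more than 20%")
and, when a p-threshold is set (default $p \le 0.01$), the t-test agrees;
*hypo* symmetrically. The strict inequality matters at the boundary:
$\Delta\beta = 0.20$ exactly is *unchanged*. BH q-values are always
reported but do not gate the default labels, since the headline counts of
the original analysis were produced without an explicit multiple-testing
gate; `p_threshold = NULL` disables the significance gate entirely.

Heatmap ordering uses agglomerative clustering with **Euclidean distance
and average linkage** on either axis (`hierarchical_cluster()`),
deterministic given input order.

## 3. Cross-contrast concordance

To ask whether culture and aging move the same CpGs in the same direction,
the two contrast results are inner-joined on the CpG universe and filtered
to rows with $|\Delta\beta| > 0.15$ in **both** contrasts
(`select_shared_dm()`; the relaxed 0.15 cutoff is used because requiring
0.20 twice leaves very few CpGs). No sign constraint is applied at
selection — discordant CpGs must be able to appear, otherwise the
concordance test would be circular. No significance filter is applied at
selection either (the source analysis describes the cutoff purely in
delta terms); the joined table carries both p-values so a caller can add
one.

On the selection, `concordance_stats()` reports the Pearson correlation of
the two delta vectors and the df=1 chi-square of the 2×2 sign table in
closed form,

$$\chi^2 = \frac{N(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

**without** Yates continuity correction by default (expected counts are
large at typical selection sizes; the correction is available as a flag).
A zero margin leaves the statistic undefined (`NA` with a warning), and a
constant delta vector leaves the correlation undefined. The identity
$\chi^2/N = \phi^2$ (squared phi coefficient) is asserted as a test oracle.

Subgroup asymmetry (`subgroup_dm_counts()`) runs the culture contrast
separately within donor subgroups (young / elderly by default) and reports
the relative difference as a percentage **of the first-listed subgroup**:
$100\,(n_1 - n_2)/n_1$, the convention under which 248 vs 189 DM CpGs
reads as "24% higher" (59/248 = 23.8%).

## 4. Enrichment

`overrepresentation()` is a one-sided hypergeometric upper-tail test:
selecting $n$ genes from a universe of $N$ of which $K$ belong to the set,
$p = P[X \ge k]$. The **universe is all genes with at least one CpG
surviving preprocessing**, not the whole genome — the array constrains the
sampling frame, and using a larger universe would inflate significance.
Gene lists from CpGs are deduplicated ("nonredundant genes"); CpGs without
a symbol are dropped and counted. BH adjustment is applied across the sets
of one collection and direction, so functional sets and positional band
sets are corrected separately. Sets with no member in the universe are
skipped; `min_set_size` removes trivially small sets. `band_sets()` builds
one positional set per parseable cytogenetic band (`10q22` style), each
gene in exactly one band.

Only over-representation is tested (no depletion, no rank-based running
sums): the re-implemented analysis reports enrichment only, and its printed
enrichment p-values depend on the annotation database of the original
tools, so they are not reproduction targets.

## 5. Methylation–expression integration

Expression probe sets are kept when called present in **strictly more
than** `min_fraction` (default 0.5) of hybridizations. Matching to CpGs is
by uppercased HUGO symbol; a gene's multiple probe sets are aggregated by
the **arithmetic mean** of log2 intensities (order-free and symmetric; a
maximum-intensity alternative is provided). For the
expression-by-methylation summary the default bin edges are
$(0, 0.25, 0.75, 1)$ — nonmethylated / intermediate / methylated. No
boundary is canonical for this split; 0.25/0.75 are the conventional
"mostly unmethylated / mostly methylated" shoulders of the bimodal beta
distribution, and the edges are configurable.

`delta_vs_expression()` pairs each gene's most extreme CpG delta with its
log2 expression ratio and reports the correlation plus, for a candidate
list, the fraction of genes whose directions agree with promoter silencing
(hypermethylation with lower expression and vice versa); zero deltas or
ratios are excluded from the agreement denominator, since they have no
direction.

`compare_platforms()` evaluates pyrosequencing profiles against the array
on the fraction scale (percent/100): per-target platform offset, per-platform
group deltas, the correlation of the two delta vectors across targets
(invariant to any constant platform offset, which the tests assert), and a
neighbor-CpG similarity summary per island.

## 6. The synthetic-data generator

`generate_methylation_study()` emulates the stated world of the target
study:

* **Design**: 8 donors, 4 young (21–50 y) / 4 elderly (53–85 y), early
  (P2) and late (P8–P15) samples — 16 samples.
* **Baselines**: a three-mode beta mixture per CpG — low
  (w = 0.55, Beta(2, 18)), intermediate (0.15, Beta(5, 5)), high
  (0.30, Beta(18, 2)) — the bimodal, unmethylated-skewed distribution of
  promoter-biased arrays. No quantitative baseline distribution is stated
  anywhere for the original data; these weights were chosen once as
  realistic for a promoter array and not revisited.
* **Effects**: additive on the beta scale (the analysis thresholds are
  absolute percentage-point differences, so logit-scale effects would not
  map cleanly onto them), `|Δβ_true|` uniform in [0.15, 0.40]; per-contrast
  per-direction counts default to the published DM counts (culture 29/55,
  aging 295/349 at `n_cpgs = 27578`). A `shared_fraction` (default 0.5) of
  the smaller contrast's DM set is shared between contrasts, with the same
  sign with probability `sign_concordance` (default 0.9). Culture effects
  apply to late-passage samples, aging effects to elderly donors (both
  passages); the aging contrast at early passage is therefore unconfounded.
* **Feasible placement**: each effect is placed on a CpG whose baseline
  leaves room for it (jointly for both effects on shared CpGs). Without
  this, a +0.30 effect landing on a 0.9-methylated baseline clips at the
  bound, the realized effect shrinks arbitrarily, and the generator's own
  recovery property (sensitivity ≥ 0.95 at the stated parameters) is
  unattainable — and biologically, methylation gains can only occur where
  there is something to gain. Clipping remains the flagged fallback
  (`mean_clipped` in the truth table) when no feasible CpG is left.
* **Noise**: each observed value is Beta-distributed around its CpG- and
  sample-specific mean with concentration φ (default 200, giving a
  per-sample standard deviation of about 0.03 at mid-range betas), i.e.
  bounded support with tunable variance and no donor random effect — see
  limitations.
* **Optional passage drift**: with `passage_drift = λ`, a late sample at
  passage $P$ carries $\min(1, λ(P-2))$ of its full culture effect,
  emulating changes acquired continuously with every passage; the default
  (`NULL`) is a step effect, and the truth table always records the
  full-effect delta.
* **Expression**: per gene, log2 intensity
  $= \mathrm{intercept} + \mathrm{slope} \times \overline\beta_{gene} +
  \mathcal{N}(0, \sigma)$ with slope −4, intercept 10, σ = 0.5 — a clearly
  negative promoter-silencing coupling at realistic log2 scales; present
  calls are drawn with probability increasing logistically in intensity.
* **Pyrosequencing**: island positions share a per-sample island jitter
  (neighboring CpGs of one island co-vary), get independent position
  jitter (both sd 0.03), and a constant platform offset (default −0.05,
  pyrosequencing reading systematically lower).
* **Intensities**: `generate_intensities()` inverts the beta formula at a
  target total intensity (default 10 000) so that `compute_beta()` with the
  same α recovers the input exactly at zero noise, then applies
  multiplicative lognormal channel noise (sd 0.05).

All generators draw from child streams derived deterministically from the
master seed and a stream tag, so adding one output never perturbs another.

**What a green test does and does not establish.** The generator has no
donor random effect, no batch or chip effects, no probe-chemistry biases,
no cell-composition drift, and independent CpGs (no spatial correlation
beyond the simulated islands). Recovery results therefore certify the
*statistical machinery* — that the pipeline finds what the model plants at
the stated noise level — not performance on real arrays, where
between-donor variance and correlated probes make both sensitivity and
error control worse.

## 7. Known limitations

* The published-study count targets (29/55 and 295/349 DM CpGs, R = 0.61,
  248 vs 189) derive from the deposited 16-sample dataset (GSE17448) and
  can only be recomputed after downloading it; the README documents the
  entry point. The exact significance criterion behind the printed counts
  is not stated, so reproducing them may additionally require tuning
  `p_threshold`.
* GEO support is limited to the series-matrix dialect (header lines plus
  one data table); full SOFT parsing and IDAT decoding are out of scope.
* No moderated-variance (shrinkage) t statistics and no region-level
  calling: per-CpG Student's t is the method being re-implemented.
* Configuration files are JSON (no YAML/TOML parser is assumed available).
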