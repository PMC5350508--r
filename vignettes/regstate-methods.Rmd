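---
title: "Methods: dissecting tolerogenic and immunogenic DC maturation states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting tolerogenic and immunogenic DC maturation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(regstate.quiet = TRUE)
```

Dendritic cells mature along two functionally opposite programs: a
steady-state program that promotes regulatory T-cell induction (tolerogenic)
and a danger-signal-driven program (e.g. LPS/TLR4) that licenses effector
T-cell priming (immunogenic). `regstate` implements a computational pipeline
for dissecting these states from three kinds of data: H3K27ac ChIP-seq peak
sets for three sorted cell states (unstimulated MHCII-lo immature,
unstimulated MHCII-hi mature, LPS-stimulated MHCII-hi mature), a
multi-population expression compendium, and a 0/1/6/24-h LPS stimulation
time course. This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where the analysis
recipe was genuinely open.

## Chromatin arm: consensus regions and the Venn partition

Peak sets are consumed as BED (0-based, half-open coordinates throughout; no
1-based dialects). The unit of the common/unique partition is the
**consensus region**: a maximal merged run of peaks, pooled over the three
states, where two peaks merge if and only if they share at least one base
pair. Bookended intervals (`a.end == b.start`) share no base and stay
separate. Each consensus region's membership signature is the set of states
with at least one peak overlapping it by >= 1 bp, giving the seven possible
signatures of a three-set Venn diagram; "unique to state X" means signature
exactly `{X}`.

Counting merged regions — rather than raw peaks — is a deliberate choice:
raw-peak counting double-counts overlapping peaks and cannot assign a single
"common" number per genomic location. A consequence is that published
per-peak Venn tallies from other toolchains are not directly comparable, so
the package treats such counts as qualitative context, not as targets.

## Motif scanning and enrichment

Motifs are position probability matrices (rows over A, C, G, T) with a
log-odds detection threshold in bits, read from a HOMER-style text dialect
in which the three-field header (consensus, id, threshold) is mandatory —
the enrichment statistic depends on the threshold, so it must be explicit.
Probabilities below 0.001 are floored to 0.001 with the remaining mass
rescaled over the other entries; this keeps every log-odds score finite and
every entry at or above the floor (plain row renormalization would push
floored entries back below it).

A window of length $L$ at offset $i$ scores
$\sum_j \log_2\left(p_j[b_{i+j}] / q[b_{i+j}]\right)$ against a background
composition $q$ (uniform by default; composition effects are absorbed by
the shuffled background at the enrichment step). Both strands are scanned —
the minus strand by scoring the reverse complement of each window — and all
windows at or above threshold are reported. A self-reverse-complementary
window therefore legitimately appears once per strand. Windows containing N
are skipped rather than scored with a neutral base, avoiding threshold
artifacts. The scanner's inner loop is compiled (Rcpp), and the test suite
holds it equal to an exhaustive enumerate-every-window oracle.

Enrichment uses the per-sequence presence indicator (a sequence counts once
per motif, however many windows hit), matching known-motif counting
practice and keeping the model exact: with $N = n_t + n_b$ sequences of
which $K$ contain the motif, the p-value is the upper hypergeometric tail
$P(X \ge k_t)$, $X \sim \mathrm{Hypergeometric}(N, K, n_t)$ —
over-representation only. Tails are computed on the log scale, so the
reported $-\log_{10} p$ is exact even where the linear p-value underflows
double precision. The default background is two dinucleotide-preserving
(Altschul–Erikson Eulerian-walk) shuffles of each target sequence, seeded;
a user-supplied background FASTA (for example, the other states' unique
regions) can be substituted.

## The differential statistic: Deming residuals

The pipeline's core statistic compares motif enrichment between two states.
For motif-aligned vectors $x, y$ of $-\log_{10} p$ values, a Deming
(errors-in-variables) regression with error-variance ratio $\lambda$ has
the closed-form slope

$$\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
\sqrt{(s_{yy} - \lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}},$$

with intercept $\bar y - \hat\beta \bar x$. Both axes come from the same
enrichment procedure, so equal error variances ($\lambda = 1$, orthogonal
regression) is the natural default; $\lambda$ is exposed as an argument.
The per-motif residual is the signed perpendicular distance to the line,
$(y_i - \hat\beta x_i - \hat\alpha) / \sqrt{1 + \hat\beta^2}$, positive
toward the y-state, normalized by the sample SD of the residuals (all-zero
when every point is on the line). Motifs are ranked by **absolute**
normalized residual — sign kept for display — and the top
$\lceil 0.10\, n \rceil$ per comparison are selected, with ties broken by
motif id for determinism. Ranking by absolute value rather than signed
value admits motifs enriched toward either state; taking the decile per
comparison (rather than pooled) keeps the three comparisons symmetric. Both
choices are configurable.

The three comparisons are built in a fixed order (lo vs hi, lo vs LPS, hi
vs LPS), and the union of selected motifs forms a residual heatmap
clustered with Euclidean distance and average (mean) linkage. The 90%
confidence band drawn around each fit is a leave-one-out jackknife of the
predicted line ($\pm 1.645 \times$ jackknife SE on a 100-point grid):
no distributional assumptions beyond exchangeability, at the price of
$n$ refits.

An important structural property of this statistic, visible in its geometry:
the orthogonal fit accommodates any single dominant point, so a lone
extreme motif in an otherwise signal-free library lands *on* the line and
gets a near-zero residual. The statistic detects motifs that deviate from a
trend established by many motifs — which is exactly the situation in real
chromatin data, where regulatory regions are motif-dense and most motifs'
enrichment co-varies strongly between related cell states. The synthetic
benchmark is designed accordingly (below).

## Expression arm: seed-gene modules and cross-platform comparison

Compendium processing follows the conventional microarray order: log2
intensities in, duplicate probe ids collapsed by element-wise median,
biological replicates averaged into population means, and only then
correlation. Every non-constant gene is correlated with the seed gene
(e.g. *Aldh1a2*) across populations; the two-sided p-value comes from the
$t = r\sqrt{(n-2)/(1-r^2)}$ transform on $n-2$ degrees of freedom, and
Benjamini–Hochberg adjustment runs over all tested genes. The module is
the set of genes with $q \le \alpha$ (default $\alpha = 5\times 10^{-4}$).
Constant genes are recorded as skipped and excluded from the BH family; the
seed is excluded from its own module. Two-sided testing means negatively
correlated genes may enter; the sign is reported per member. At least four
populations are required — below three residual degrees of freedom the
correlation p-value is undefined.

Quantile normalization (shared with the time-course stage) forces every
column onto the common rank-mean distribution, averaging tied values; it is
idempotent and delegates to `limma::normalizeQuantiles`. Cross-platform
comparison restricts two platforms to shared gene symbols
(case-insensitive), Z-scores each gene within each platform — which removes
any per-gene affine distortion that is uniform within a platform — then
correlates and average-linkage clusters the pooled samples.

## Kinetic arm: responsive genes and archetype clustering

The time course is 4 time points (0, 1, 6, 24 h) with 3 replicates. Each
gene is tested with a plain one-way ANOVA F across the time groups on log2
values, $p$ from $F(3, N-4)$, BH-adjusted. This is a deliberate
substitution for a moderated (empirical-Bayes) linear-model fit: with three
replicates per group the moderation mainly stabilizes variance estimates of
borderline genes, while every property this package asserts (null
calibration, FDR control, planted recovery) is statistic-agnostic. A gene
is called responsive when $q < 0.001$ **and** the largest absolute log2
difference of any stimulated time point versus t = 0 reaches
$\log_2 1.5 \approx 0.585$ — a linear 1.5-fold gate with the unstimulated
baseline as reference. Constant genes get $F = 0, p = 1$.

Selected genes' time-point mean profiles are standardized to mean 0, SD 1
across the four time points (clusters should group kinetic *shape*, not
amplitude or baseline; constant profiles cannot pass the fold gate) and
clustered by k-means with $k = 12$ by default, 50 restarts keeping the best
inertia. Restarts are seeded with k-means++ (D²) centers: covered profiles
have essentially zero re-pick probability, so clean data with exactly $k$
distinct shapes is recovered exactly — plain random-row seeding almost
never draws $k$ distinct centers from heavily duplicated rows. Given the
seed, the whole procedure is deterministic and invariant to gene order up
to cluster relabeling.

## What the generators emulate — and what they do not

The three generators define the study conditions under which every claim in
the test suite is computed.

**Peak sequences** (`gen_motif_peak_data`): each state's peaks split into a
consensus block shared identically by all states (default common fraction
0.45, a roughly balanced common/unique split as observed in three-state
H3K27ac comparisons) and mutually disjoint state-unique blocks; sequences
are i.i.d. uniform-background DNA (200 bp default). Motifs are planted as
exact consensus strings at per-(state, motif) rates — `round(rate ×
n_unique)` peaks get exactly one insertion each, at a random interior
offset and strand, never overlapping another insertion or the peak edge, so
every planted site stays intact and the truth table is exact. Exact
consensus planting gives a deterministic lower bound on detectability;
PWM-sampled planting would be a natural extension.

**The differential-motif benchmark** (`simulate_motif_benchmark`): a
50-motif library of sharp consensus PWMs (0.97/0.01 rows; detection
threshold at 85% of the maximum score, which makes one mismatch — a ~6.6
bit penalty — already sub-threshold). Every motif receives a
state-*independent* base plant rate drawn once from U(0, 0.30), and one
focal motif is planted differentially (30% in LPS-unique peaks, 5%
elsewhere). The base rates are what give the per-state $-\log_{10} p$
vectors a strong shared trend (fitted R values around 0.9 and above) from
which the focal motif deviates — the regime the Deming-residual statistic
is built for. Without them (a lone planted motif), the orthogonal fit would
pass through the single outlier and its residual would vanish; that is a
property of the statistic, not an artifact of this implementation.

**Co-expression compendium** (`gen_coexpression_data`): the seed gene is
standard normal across populations; each of the 50 module genes is
$\rho\,\mathrm{seed} + \sqrt{1-\rho^2}\,\sigma_\varepsilon\,\varepsilon$
(default $\rho = 0.9$, $\sigma_\varepsilon = 1$, so the expected
correlation with the seed is exactly $\rho$); other genes are independent
normals. 27 populations mirror a compendium-scale design.

**Time course** (`gen_timecourse_data`): 12 default archetypes at amplitude
2 log2 units — early/mid/late transient, fast/delayed/late sustained,
gradual, and their repression mirrors — on top of N(6, 1) baselines, with
N(0, 0.25²) replicate noise by default; null genes have constant means.

None of the generators model platform-specific probe effects, GC or
repeat structure, dinucleotide background, peak-width variation, or
correlated replicate noise. Passing tests on these conditions therefore
demonstrate correctness of the algorithms and calibration of the statistics
under their own assumptions — not robustness to everything real chromatin
and array data can do.

## Numerical choices and degenerate inputs

* Hypergeometric tails on the log scale; `neg_log10_p` stays exact when the
  linear p underflows (p is reported as 0 there).
* Deming fit requires $n \ge 3$ and non-constant input; `s_xy = 0` with
  `s_yy = λ s_xx` is reported as undefined, `s_xy = 0` with
  `s_yy > λ s_xx` as a vertical-line degeneracy.
* All residuals zero → normalized residuals defined as all zero.
* Tie-breaks everywhere are lexicographic (motif ids) or
  smallest-original-index (dendrogram leaves), so outputs are reproducible
  byte for byte under a fixed seed.
* PWM rows must sum to 1 within 0.01 (warn + renormalize beyond 1e-2 is an
  error at parse time); after flooring, rows sum to 1 within 1e-9.
* BH is `stats::p.adjust(method = "BH")`; quantile normalization is
  `limma::normalizeQuantiles(ties = TRUE)`; interval algebra is
  IRanges/GenomicRanges with `min.gapwidth = 0` so bookended intervals stay
  distinct; FASTA IO is Biostrings. The Deming fit, orthogonal residuals,
  decile selection, HOMER-dialect parser, scanner, shuffle, and generators
  are implemented here.

## Problem sizes used in the shipped checks

The acceptance script and test suite run the benchmark at 500 peaks/state ×
200 bp × 50 motifs × 20 seeds, the module recovery at 5,000 genes × 27
populations × 20 seeds, null calibration at 20,000 genes, and kinetic
recovery at 600 genes × 20 seeds — sizes chosen so the full pipeline
exercises every stage end to end in a few minutes on one CPU while keeping
Monte-Carlo standard errors well inside the asserted margins.

## Known limitations

* Exact reproduction of published motif lists or p-values from any specific
  known-motif database release is out of scope; the motif library is user
  input.
* The hypergeometric model assumes exchangeable sequences; strong
  composition differences between target and a user-supplied background are
  not corrected beyond the scoring background.
* The jackknife band is a pointwise band, not a simultaneous one.
* One-way ANOVA treats time as categorical; trends across time points are
  not modeled.
* `p_value` fields can be 0.0 by underflow at extreme enrichment — use
  `neg_log10_p` for arithmetic.
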