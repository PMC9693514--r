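---
title: "Inferring epiphytic bromeliad functional groups from leaf traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring epiphytic bromeliad functional groups from leaf traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibrom)
```

`epibrom` turns a species-by-trait compilation for epiphytic Bromeliaceae
into a five-group functional classification — nebulophytes (`NEB`),
pseudobulbs (`BULB`), shallow tanks (`SHALLOW_T`), C3 tanks (`C3_T`) and
CAM tanks (`CAM_T`) — and quantifies how the groups differ in traits and
climate. This vignette is the package's own account of the models and the
numerical choices behind each stage; the README shows the user-facing
workflow.

## The data model

A trait table is a tibble of species rows against a 25-trait registry
(`default_registry()`), 16 of which form the clustering set. Missing cells
are `NA` — never sentinel values — and every non-missing cell carries a
provenance tag (`measured`, `literature`, `herbarium`, `derived`,
`imputed_phylo`, `imputed_genus`). Keeping provenance per cell is what
later lets the out-of-range check distinguish data from model output, and
lets reports separate measured values from estimates.

Two morphological facts enter as explicit flags rather than inferences:
`tankless` (a species that cannot impound water gets tank capacity
`TC = 0` mL by morphology, not by formula) and `acicular` (needle-like
leaves). Both are statements about the plant that no trait arithmetic can
recover reliably; in particular some well-documented fog-intercepting
species have leaf indices as low as 15–19, so leaf index alone cannot
define the nebulophytes.

## Derived traits

Three estimators fill gaps deterministically, in a fixed order, tagging
every filled cell `derived`:

* **Leaf index** `LI = LL / LW` (dimensionless), from the stored cells.
* **Leaf area** `LA = LW · LL / 1.5` (cm²). Bromeliad leaves sit between a
  triangle (`LW·LL/2`) and a rectangle (`LW·LL`); the 1/1.5 factor is the
  intermediate shape constant.
* **Tank capacity** `TC = 0.0041·LA² + 1.929·LA − 22.285` (mL). The raw
  quadratic is negative for `LA` below about 11.4 cm²; predictions are
  clamped to 0 mL because a volume cannot be negative — this is how we
  read "forcing the fit through a zero origin" physically. The clamp means
  small-leaved species get 0 mL even when photographic evidence shows a
  tiny tank; the rule engine's C3-with-negligible-tank branch exists
  partly to absorb this known bias.
* **Pathway**: CAM if δ¹³C ≥ −20 ‰, C3 below. The boundary is inclusive
  on the CAM side, and the call partitions the real line (a property the
  tests check by monotonicity).

`fill_derived_traits()` is idempotent, so re-running a pipeline never
compounds estimates.

## Gap-filling

Species observed for fewer than five traits are dropped outright. The
clustering matrix is then restricted by an iterative coverage filter:
traits covering under 70 % of species are removed first, then species
covering under 70 % of the remaining traits, repeating to a fixed point.
Trait-first ordering is a deterministic convention; on the instances we
test, the fixed point coincides with the exhaustive-search optimum of
retained cells, but that is not guaranteed in general.

Remaining gaps are filled under a multivariate Brownian-motion model on a
phylogeny. With `n` tips and `p` traits, tip values follow a matrix-normal
distribution with mean `1μᵀ`, row covariance `C` (the shared branch-length
matrix) and column covariance `R` (the trait rate matrix), i.e. the
stacked vector has covariance `C ⊗ R`. We fit `μ` and `R` by maximum
likelihood with an EM algorithm over the missing entries:

* E-step: conditional mean and covariance of missing cells given observed
  cells under the current `(μ, R)`, via a Cholesky solve of the observed
  block of `C ⊗ R`.
* M-step: GLS mean `μ = (1ᵀC⁻¹1)⁻¹ 1ᵀC⁻¹ E[X]` and
  `R = E[(X−1μᵀ)ᵀ C⁻¹ (X−1μᵀ)]/n`, including the conditional-covariance
  correction for missing–missing pairs.
* Stopping: observed-data log-likelihood improvement below 1e-8 or 500
  iterations; `R` is kept symmetric and gets `1e-8 · tr(R)/p` on the
  diagonal each iteration to stay positive definite. These are standard
  EM conventions; nothing in the data motivated anything tighter.

Missing cells of tree-member species are then set to their conditional
expectations. Two closed forms anchor the tests: on a star tree with one
trait the fill is the mean of the observed tips, and with two perfectly
correlated traits the fill equals the linear map from the observed trait
(to 1e-6, the regularization setting the attainable accuracy).

Model output is then audited against the data: any imputed value strictly
outside the observed range of its trait (min/max over non-imputed cells —
the only range the data itself defines) is reverted to missing. Those
cells, cells of species absent from the tree, and anything else still
missing fall through to genus means; a cell with no congeneric reference
stays empty and its species is dropped from the clustering set with a
warning. The imputation report exposes all counts, and gives the
genus-mean share against both denominators (all cells, and missing cells
only), since either convention is defensible.

Imputation operates on raw trait values; the transformation below happens
afterwards. The order is a genuine choice — imputing on log scale would
also be defensible — and is documented here rather than hidden.

## Transformation

Each clustering trait is transformed and rescaled to [0, 1]:

| recipe | traits | why |
|---|---|---|
| log₁₀ | all size-like traits | right-skewed, span orders of magnitude |
| +0.5 mL then log₁₀ | `TC` | tankless species have exactly 0 mL |
| absolute value then log₁₀ | `δ¹³C` | leaf values are negative; the absolute value makes the most C3-like signatures largest |
| none | `N`, `δ¹⁵N` | already adequately symmetric |
| none | `PB` | binary; min–max rescale maps {0,1} to {0,1} |

The exception list (`N`, `δ¹⁵N`) is treated as exhaustive. Min–max bounds
come from the analysis set itself, so the transform is scale-stable
(multiplying a raw column by a constant does not change the rescaled log
column) and every non-constant column attains both 0 and 1. Constant
columns map to 0 rather than erroring, which keeps degenerate fixtures
usable. `inverse_report()` retains per-trait `(recipe, min, max)` so 0–1
coordinates can be mapped back to raw units; the sign of δ¹³C is restored
as negative, the only physically occurring sign in leaves. Whether the
binary `PB` should enter the distance unweighted is not decidable from
first principles; it is included by default and can be dropped by passing
a transform table without it.

## Two-way Ward clustering

`ward_linkage()` is written from first principles: at each step it merges
the pair of clusters minimizing the increase in total within-cluster sum
of squares, maintained incrementally as
`ΔSSE(A,B) = n_A n_B/(n_A+n_B) · ‖c_A − c_B‖²` from centroids and sizes.
Heights are stored on this ΔSSE scale — two singletons merge at half
their squared distance — which makes the dendrogram's y-axis read directly
as variance absorbed. The merge sequence is identical to the
squared-Euclidean "ward.D2" criterion; `as_hclust(x, scale = "ward.D2")`
rescales heights to `sqrt(2h)` for comparison with `stats::hclust`, and
the tests verify both the height correspondence and, on 200 random small
instances, exact agreement with a brute-force agglomerator that re-derives
every candidate SSE from raw points. Ties are broken toward the
lexicographically smallest leaf indices so runs are bit-reproducible.
Ward's criterion is reducible, so heights are monotone and cutting the
tree at the `k−1` highest merges is well defined; `cut_tree()` numbers
clusters by smallest member index, making partitions nested and stably
labelled across `k`. The group count `k = 5` is a user input, not an
automated selection — the five-group structure is read off the dendrogram,
and the package does not pretend to an internal criterion it does not
have.

Traits are clustered the same way on the transposed matrix, and the
heatmap is reordered by both leaf orders.

## Discriminant validation

Group centroids and a pooled within-group covariance `Σ` (scatter divided
by `n − g`) support classification by minimal squared Mahalanobis
distance and the pairwise separation matrix
`(μᵢ−μⱼ)ᵀ Σ⁻¹ (μᵢ−μⱼ)`. With 16 traits against group sizes of order ten,
`Σ` is shrunk toward its own diagonal with weight `λ = 0.01`
(configurable). A trait with zero within-group variance — `PB` when every
cluster is pure — would make any diagonal shrinkage singular; such traits
are assigned the mean within-group variance of the remaining traits, which
keeps them informative without letting an infinite likelihood ratio
dominate the metric. With `λ = 0` the distances are affine-invariant,
symmetric and zero on the diagonal (tested); with shrinkage they are
approximately so.

## The rule engine

Cluster output defines the groups; the rule engine extends the labels to
species outside the clustered set and makes the definitions operational.
Decision order: pseudobulb first (`PB = 1` → `BULB`); then acicular
morphology → `NEB` (with an `LI ≥ 40` and negligible-tank fallback used
only when the flag is absent — 40 sits between the observed group means of
83 for nebulophytes and 15 for the rest); then tank capacity within
pathway: CAM with `TC ∈ [2, 61]` mL → `SHALLOW_T`, above → `CAM_T`; C3
with `TC > 5` mL → `C3_T`, otherwise `SHALLOW_T` (C3 species with
negligible tanks sort with the shallow group). The shallow window is
closed at both ends; the source material prints both 60 and 61 mL as the
upper bound in different places and the engine follows the explicit
threshold statement, using 61. One configuration has no published rule —
CAM, tankless, non-acicular, no pseudobulb — and the engine returns an
explicit "unclassifiable" with candidate groups rather than guessing. The
same holds when the pathway or tank capacity cannot be resolved at all:
silence is never an answer.

Two reconciliation overrides mirror how cluster output is curated: CAM
species falling in the C3-tank cluster move to `CAM_T` (the groups are
pathway-defined), and acicular species falling in the shallow-tank cluster
move to `NEB`. Both moves are logged with reasons, and the operation is
idempotent.

## Group statistics

Spearman correlations use midranks and the two-sided t approximation on
pairwise-complete cells, with no multiple-testing correction by default
(matching how such trait matrices are conventionally reported; a Holm
option exists). "Strong" correlations are filtered at `p < 0.05` and
`ρ² > 0.60`. Group contrasts use Kruskal–Wallis with tie correction and
pairwise two-sided Wilcoxon rank-sum post hocs — exact enumeration for
groups of at most 10 without ties, normal approximation with tie and
continuity correction otherwise — or one-way ANOVA with Tukey HSD for
variables treated as normal (leaf water content per area). Letters come
from a greedy insert–absorb compact letter display computed from the
pairwise p matrix; a property test checks on random matrices that groups
sharing a letter are never significantly different and groups sharing none
always are. Degenerate inputs have defined answers: all-equal values give
`H = 0`, `p = 1`, one shared letter; groups under two observations are
excluded with a warning.

Environmental contrasts run per variable (VPD, PPT, Tmin, Tmax, ET0,
aridity index, elevation) on raw occurrence records as the comparison
unit; records of one species are not independent samples of the species'
niche, so a species-mean mode exists but is deliberately non-default,
matching an analysis of raw environmental data. Ecozone summaries count
presence (distinct species per zone), never abundance, so heavily
collected species do not dominate.

## The synthetic generator

`simulate_study()` emulates the structure the analysis assumes: a
pure-birth (Yule) tree built by explicit exponential waiting times (with
`k` lineages the next event waits `Exp(kλ)`, giving expected root-to-tip
depth `Σ_{k=2..n} 1/(kλ)`, which the tests verify by Monte Carlo); trait
tables drawn as archetype mean + Brownian deviation along the tree +
independent noise (log₁₀ scale for size-like traits, additive for
isotopes and nitrogen); MCAR masking at 7.2 % of the species × trait grid
(88 cells on the default 76 × 16), never below the 5-trait floor and never
touching `PB`, since pseudobulb presence is always scorable; and per-group
Gaussian climate niches with categorical ecozone membership. Defaults are
76 species (11/7/13/25/20 across `NEB`/`BULB`/`SHALLOW_T`/`C3_T`/`CAM_T`),
50 of them on the tree so the genus-mean fallback is exercised, and eight
clade-based genera. Archetypes are calibrated to the registry's medians
and ranges and to the directional contrasts that define the groups
(nebulophytes: highest LI, smallest leaves and water content; pseudobulbs:
`PB = 1`, thickest, most succulent leaves; shallow tanks: 20 mL centre
well inside the 2–61 window; C3 tanks: δ¹³C −28 ‰, highest SLA and
stomatal density; CAM tanks: largest plants, 800 mL). Config validation
rejects archetypes that contradict the thresholds they are meant to
trigger.

What passing tests do and do not show: the generator's groups are
separable by construction, its missingness is completely at random, its
niches are Gaussian, and its tank capacities are drawn independently of
leaf area rather than through the allometry. Recovery results (ARI = 1 at
`k = 5`, ≥ 95 % rule recovery) therefore demonstrate that the pipeline's
machinery is correct and well calibrated — not that real compilations,
with opportunistic missingness, intergrading morphologies and correlated
measurement error, would be recovered as cleanly. The real compilation's
headline structure can only be checked against the deposited data, which
the pipeline consumes when supplied but never requires.

## Problem sizes and determinism

The shipped tests and the acceptance script run at the study's own scales:
76 × 16 tables (and a 204-species composition fixture), 40–50-tip trees
for imputation benchmarks, 200 random instances of at most 8 points for
the Ward oracle, and 10,000 null replicates of 5 × 15 observations for the
Kruskal–Wallis calibration. Every stochastic step takes an explicit seed,
and a pipeline run writes a machine-readable summary that is byte-identical
across repeated runs with the same inputs.

## Known limitations

* The BM fit is exact-likelihood but dense: its cost grows with
  `(n·p)³` in the observed block, comfortable at these scales but not for
  thousands of species; a pruning-based E-step would be the next step.
* No Ornstein–Uhlenbeck or multi-rate evolutionary models; no tree
  inference — the phylogeny is an input.
* The clamped tank-capacity allometry under-predicts small tanks (known
  from field evidence); treat small predicted `TC` as "negligible", not
  as literally zero.
* The compact letter display is the greedy insert–absorb construction; it
  is consistent by construction but not guaranteed letter-minimal.
* Dendrogram heights are comparable within a run only; cophenetic scales
  from other software differ by monotone transforms of the Ward height
  convention.
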