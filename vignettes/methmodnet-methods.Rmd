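---
title: "Methylation module networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation module networks: models, parameters and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(methModNet)
```

This vignette documents the statistical models behind each pipeline stage,
the tunable parameters and their defaults, the design of the synthetic
cohort generator, and the numerical decisions that were genuinely open.
All code chunks are illustrative (`eval = FALSE`); the package's test
suite and `scripts/acceptance.R` execute every claim made here.

## The pipeline and its assumptions

**β and M values.** A gene's methylation level is the β value, the
methylated fraction in [0, 1], obtained by averaging its promoter probes
on the β scale (averaging precedes the transform). Analyses run on the M
value, `M = log2(β/(1−β))`, which is approximately variance-stabilised
and unbounded. β is clipped to `[ε, 1−ε]` with `ε = 1e-6` before the
transform so M stays finite at the boundaries; the transform is strictly
increasing and exactly invertible inside the clip range. The choice of
`ε` is presentational: it only affects probes that are fully methylated
or fully unmethylated in some sample, and any `ε ∈ (0, 0.5)` preserves
the ranking of values.

**Probe filtering.** Probes are removed in a fixed order — missing β in
any sample, X/Y chromosome, SNP-affected, cross-reactive, non-promoter —
so the per-criterion removal counts are reproducible; a probe matching
several criteria is counted under the first. SNP-affected and
cross-reactive flags are *inputs* (annotation columns), not bundled
lists. Which 450K annotation categories count as "promoter" is a
configuration choice; the default (`TSS200`, `TSS1500`, `5'UTR`,
`1stExon`) is the conventional promoter-associated set.

**Rank-based network.** Each gene is connected to its `k = 4` most
correlated partners by absolute Pearson correlation. The rank-based rule
adapts to pathway-specific correlation scales where a single global
threshold cannot. Two conventions coexist deliberately: the *selection*
view (each qualifying gene contributes exactly `k` directed edges, so the
reported network size is `k·n` — the only convention consistent with a
16,850-gene network having 67,400 edges) and the deduplicated *simple*
graph used by every downstream algorithm. Ranking by `|r|` rather than
signed `r` captures co-methylation in either direction and is
configurable (`ranking = "signed"`). Ties in `|r|` break by gene id, so
construction is deterministic. Degree distributions are summarised by a
least-squares line on (log10 degree, log10 frequency); the fit is refused
below three distinct degree values.

**MCODE modules.** The molecular-complex-detection algorithm is
reimplemented: a vertex's weight is `k × density` of the highest k-core
(k ≥ 2) of its closed neighbourhood; complexes grow breadth-first from
the highest-weight unused vertex, including neighbours whose weight is at
least `seedWeight × (1 − nodeScoreCutoff)`; the haircut reduces a
finished complex to its 2-core; complexes under five genes are dropped.
Defaults follow the published plug-in defaults (node score cutoff 0.2,
degree cutoff 2, haircut on, fluff off), all configurable. One behaviour
is not pinned down by the published algorithm description, because the
five-gene retention rule sits *on top of* MCODE: what happens to the
vertices of a complex that ends below the size floor. This package
*releases* them — they may be absorbed into complexes grown later but may
not seed new ones (the seed itself stays consumed, which guarantees
termination). The motivation is robustness: in noisy graphs, a background
vertex that happens to attach to three mutually linked module genes forms
a small, locally dense complex that is discarded anyway; consuming its
members would punch holes into genuine modules. Returned modules are
vertex-disjoint and connected, and equal weights resolve by gene id, so
detection is deterministic.

**Module cross-talk.** For a module pair, the observed number of
connecting edges in the simple graph is compared with the counts between
`nPerm = 1000` pairs of random disjoint vertex sets of the same sizes.
The p-value uses the add-one estimator `(r + 1)/(nPerm + 1)`, which is a
valid p-value and never exactly zero. Random sets are drawn from all
network vertices (they may intersect real modules — no exclusion is
applied beyond mutual disjointness, mirroring the disjointness of real
modules). No multiple-testing correction is applied across pairs; the
module network keeps raw `p < α` edges, which users should treat as a
screening threshold, not a family-wise guarantee. Because the cross-edge
count is an integer, the p-value lives on a lattice and is slightly
conservative; the calibration test in the acceptance suite therefore
checks exact uniformity on the *randomized* probability integral
transform of the same permutation null (the tallies are exposed as
attributes of the returned p-value) and separately checks that the
reported p-value is valid and non-degenerate.

**K-shell core.** Shell indices come from standard iterative pruning
(equivalently, graph coreness); isolated modules sit in shell 0. The
"core" is every module in the maximal shell — the definition that matches
reported core sizes of two to four modules — and may span disconnected
components. Ties are never broken: all maximal-shell modules are kept.

**Risk scoring.** Each core module is summarised per sample by the mean M
value of its genes. On a random half of the cohort (training), a
univariate Cox model per module assigns the module to the risk-increasing
or risk-decreasing set by the sign of its coefficient; zero coefficients
go to the positive set with a warning. The test-half risk score is the
plain signed sum of module statistics — not standardised, exactly as the
score is defined; a multivariate variant was considered and rejected
because only the coefficient *signs* enter the score. Equal-size
High/Low groups are formed by the risk ranking (odd cohorts put the
median sample in the Low group; boundary ties resolve by sample id to
keep the groups equal), compared by the two-sample log-rank test, with
the hazard ratio estimated from a Cox fit on the group indicator. Cox
fits use Breslow tie handling throughout.

**Typing.** Core-module statistics (one feature per module — the
module-mean convention, chosen over per-gene features for parsimony; a
per-gene mode is available by passing a gene-level matrix) are min–max
normalised per feature and clustered by K-means for `k ∈ [2, 8]`, with
k-means++ initialisation and 50 restarts keeping the lowest
within-cluster sum of squares. Euclidean distance is K-means' native
metric and is used for the silhouette as well. The mean silhouette
selects `k` (ties to the smaller `k`); singleton-cluster points
contribute S = 0, the standard convention where `a(i)` is undefined.

**Stability comparison.** Cohorts are split into equal halves (the same
random split reused for both data types within a replicate, which pairs
the comparison and reduces variance); each half is screened by univariate
Cox at `α = 0.05`; the overlap of the two selections is scored by the
upper-tail hypergeometric test with the data type's full gene count as
the universe; `−log10 p` is the per-replicate stability indicator, and
the two indicator vectors are compared by a two-sided
Mann–Whitney–Wilcoxon test. The logarithm base is presentational — only
ranks enter the MWW test.

## The synthetic cohort generator

`generateCohort()` draws a cohort in which every downstream claim is
checkable against ground truth. Defaults encode the study conditions used
by the end-to-end tests: 500 genes × 300 samples, five planted 15-gene
modules with loading 0.9 and residual SD 0.3 on the M scale, one
cross-talk pair (modules 1–2, factor correlation 0.8), hazard weights +1
and −1 on modules 3 and 4, exponential survival with 30% censoring
(events on a day scale with baseline hazard 0.002), and expression
repressed by promoter methylation (slope −1 plus unit noise). β values
are the logistic transform of M and therefore always lie strictly inside
(0, 1).

**Why modules are structured, not single-factor.** The obvious generator —
one latent factor per module, every member loading on it equally — cannot
exercise this pipeline, for two provable reasons. First, in a top-k
network a gene links to its k strongest partners; with ≥ k+1
equally-loaded siblings, *every* pick is within-module, so correlating
two module factors at ρ < 1 produces exactly zero between-module edges
and planted cross-talk would be invisible by construction. Second,
MCODE's seed-relative weight threshold fragments flat modules: in a
15-gene single-factor module the top-4 graph is effectively a random
4-out union in which only about a third of members reach 0.8× the
maximum vertex weight. The generator therefore plants *structured*
modules:

- **Block modules** (the default): five-gene blocks share a block
  subfactor, so each block appears as a near-clique (within-block
  correlation ≈ 0.9) whose members all carry the maximal MCODE weight;
  one *connector* gene per block additionally loads (weight 0.8) on a
  module-wide backbone factor, which links the connectors of a module to
  each other and lets module detection walk from block to block. A
  module-wide common factor (variance share `c²/(1+c²)` with `c² = 0.4`)
  keeps all members of a module correlated above background and carries
  the module's survival effect.
- **Cross-talk pairs**: the pair's common factors are correlated at the
  requested ρ, and the second module is planted as a smooth circular
  correlation gradient (a "ring") plus *coupling genes* — private noise
  plus loadings spread over up to three of the partner's blocks. The
  coupling genes are what turn planted cross-talk into actual
  between-module edges; their weight (`bridgeMix = 0.5`, split across
  targets) is chosen so they attach to the partner's blocks without
  displacing the partner's own connectors or being absorbed as module
  members.

Survival: the log hazard is the weighted sum of the module common
factors; event times are exponential; censoring times are uniform on
`[0, T]` with `T` solved numerically so the expected censored fraction
matches the target.

**What the generator does and does not emulate.** It reproduces the
statistical structure each stage assumes — block-correlated promoter
methylation, module-level cross-talk, proportional-hazards survival
driven by module methylation, methylation-repressed expression, and
probe-level expansion with known filter violations
(`generateProbeLevel()`). It does not emulate 450K array noise
characteristics, batch effects, tumour purity, or the messy partial
overlap of real co-methylation modules; passing the recovery suite shows
the pipeline is implemented correctly, not that real cohorts will yield
modules this clean. Real 450K-derived networks are also far larger
(≈17,000 genes); the test cohorts use 500 genes so the whole suite runs
in seconds, and the acceptance script additionally builds one
16,850-gene network to verify the structural identities at full scale.

**What recovery means here.** Module recovery is scored by best-match
Jaccard between each planted module and the detected modules; the
end-to-end suite requires at least 4 of 5 planted modules at Jaccard
≥ 0.8 (the ring half of the cross-talk pair deliberately sacrifices
detection-level recovery — its coupling genes are module members that do
not sit in any dense block, which is exactly what makes the cross-talk
visible). The planted cross-talk edge is tested by the permutation stage
on the planted memberships; detected-module cross-talk is structurally
weaker because MCODE's consume-first semantics exclude coupling genes
from both complexes — a genuine property of the method worth knowing
when interpreting real module networks.

## Numerical choices and degenerate inputs

- Correlations are computed on full sample vectors (missing values are
  removed upstream by the probe filter, never imputed).
- Constant genes cannot be correlated, screened by Cox, or min–max
  normalised; they are dropped with a warning (network), skipped and
  never selected (Cox screen), or an error (normalisation), respectively.
- Degenerate survival inputs error early: fewer than two observed
  events, identical risk scores, constant biomarker genes, empty groups.
- All writers emit full-precision (`%.17g`) numbers so write/read round
  trips are exact.
- Every stochastic stage draws from a substream derived from the global
  seed and the stage name (`deriveSeed()`), so stages can be re-ordered
  or re-run in isolation without perturbing each other, and `run-all`
  equals the stage-by-stage composition byte for byte.

## Problem sizes

The test suite uses cohorts of 120–500 genes and 40–300 samples,
permutation counts of 99–999, and 20-seed replication for the end-to-end
recovery suite; the acceptance script uses the full 16,850-gene scale for
the network identities and 1000 permutations for the module network.
These sizes were chosen so each property is measured with comfortable
statistical margins while the whole suite stays quick to run.

## Known limitations

- Module-pair p-values are not corrected for multiple testing (by
  design, matching the raw `p < 0.05` rule); downstream interpretation
  should account for the number of pairs tested.
- The MCODE parameter defaults are a documented assumption; the
  algorithm's output on real data is sensitive to the node score cutoff,
  and the vertex-weighting scheme is intrinsically jittery on noisy
  graphs (a single stray edge can change a neighbourhood's highest
  k-core).
- The K-shell core of a sparse module network can be as small as a
  single edge's endpoints; with no significant cross-talk at all the
  core is empty and downstream stages refuse to run rather than guess.
- Risk-score standardisation across modules is deliberately not applied;
  modules with larger statistic scales contribute proportionally more.
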