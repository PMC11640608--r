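---
title: "STP activity scoring and cell-line matching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STP activity scoring and cell-line matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpmatch)
```

`stpmatch` infers signal transduction pathway (STP) activity from the
expression of each pathway's direct target genes, and uses the resulting
profiles to cluster cancer cell lines and to match patient tumor samples
to their most similar cell line. This vignette documents the models, the
tunable parameters, the synthetic-data generator, and the design choices
made where the problem left the design genuinely open.

## The two-layer scoring model

Each pathway is modelled as a two-layer Bayesian network. The root is a
latent binary node $T$: the pathway's terminal transcription factor is
active or not, with prior $\pi = P(T = \text{active})$ (default 0.5,
uninformative, configurable per pathway). The leaves are the pathway's
target genes; gene $g$ carries a regulation direction (up if the active
factor induces it, down if it represses it) and a literature-evidence
weight $w_g \in (0, 1]$.

**Observation layer.** Raw log2 intensity $x_{gs}$ of gene $g$ in sample
$s$ becomes soft evidence that the gene is in its up-expressed state:
$$e_{gs} = \frac{1}{1 + \exp(-\lambda\,(x_{gs} - t_g))}.$$
The threshold $t_g$ defaults to the cohort median of gene $g$ — a
scale-robust choice that requires no platform-specific calibration — and
can be overridden with per-gene reference thresholds. The slope
$\lambda$ (default 1 per log2 unit) sets how sharply expression away
from the threshold commits the gene to a state. A zero-variance gene has
its threshold at the constant, evidence 0.5 everywhere, and is thereby
uninformative.

**Gene layer.** The conditional probability that gene $g$ is
up-expressed given the pathway state is symmetric and weight-scaled:
$p_a = 0.5 + \kappa w_g$ when the state agrees with the gene's direction
and $p_i = 0.5 - \kappa w_g$ otherwise. The bound $\kappa \in (0, 0.5)$
(default 0.45) keeps every conditional probability away from 0 and 1,
so single genes can never contribute infinite likelihood ratios. Each
gene then contributes
$$LR_g = \frac{e_g\,p_a + (1 - e_g)(1 - p_a)}
              {e_g\,p_i + (1 - e_g)(1 - p_i)},$$
and the posterior log2-odds of activity are
$L = \log_2 \frac{\pi}{1-\pi} + \sum_g \log_2 LR_g$. Because the gene
layer is conditionally independent given $T$, this product form equals
the exhaustive sum over all $2^m$ joint gene-state configurations; the
test suite checks the equality against a brute-force enumeration oracle
to $10^{-9}$ on pathways of up to eight genes.

**Missing genes.** A target absent from the expression matrix is skipped
with a warning and contributes $LR = 1$ exactly; gene coverage differs
across platforms and a hard failure would make cross-platform use
impractical. If no target is present the prior log2-odds are returned.

## The 0–100 activity scale

Scores are presented on a normalized scale in which 0 corresponds to the
odds of an inactive pathway and 100 to the odds of an active one:
$$\text{score} = \mathrm{clip}\!\left(100 \cdot
  \frac{L - L_0}{L_{100} - L_0},\; 0,\; 100\right).$$
In the default `"extremes"` calibration the anchors $L_0, L_{100}$ are
the log2-odds of the two evidence configurations consistent with the
target directions: every up-target at evidence 1 and every down-target
at 0 for the active anchor, and the mirror image for the inactive one.
With the symmetric conditional table these are
$\log_2\frac{\pi}{1-\pi} \pm \sum_g \log_2\frac{0.5+\kappa w_g}{0.5-\kappa w_g}$.
We anchor on the direction-aware extremes rather than on "all evidence
high" / "all evidence low" because with down-regulated targets the
latter do not bound the reachable odds and can even invert (the active
anchor must exceed the inactive one); the direction-aware pair are the
true extremes of the likelihood, so the invariant holds for any mix of
directions and clipping only ever trims measurement overshoot. Explicit
anchors from reference samples are supported via the `"explicit"`
calibration mode.

Each pathway has its own anchor span, so scores of different pathways
are not directly comparable: a pathway with a narrow empirical activity
range can carry meaning in small score differences that would be noise
for a wide-range pathway. The package therefore reports per-cohort
empirical ranges rather than hard-coding any pathway-specific range.

## Cohort handling

Eligibility filtering removes treated, contaminated and non-ovarian
samples; the rules are applied independently so the result is
order-free and idempotent, and a per-rule exclusion log is emitted.
Replicate samples of the same entity within one dataset are averaged
*after* scoring — aggregation operates on STP activity scores, not on
expression — while the same entity profiled in different datasets keeps
one row per dataset (suffixed `_1`, `_2`, … in dataset order), which is
what makes cross-laboratory comparison of a cell line possible. The
growth-factor pathways MAPK, PI3K and JAK-STAT3 respond to culture
conditions (e.g. serum concentration), so they are excluded from
cell-line analyses by default, leaving the seven-pathway analysis set
AR, ER, HH, NF-κB, Notch, TGF-β, Wnt.

## Clustering and characterization

Profiles are clustered agglomeratively on their score vectors. The
method is not dictated by the problem, so it is configuration: the
defaults are Euclidean distance with Ward linkage (`ward.D2`), the
standard pairing for compact, roughly spherical profile clusters, with
`k = 7` as the default cut. Dendrograms export as Newick with merge
heights as branch lengths.

Groups (clusters, or histological subtypes) are characterized per
pathway with a Kruskal–Wallis omnibus test followed by pairwise
two-sided Mann–Whitney tests at $\alpha = 0.05$, starred at
0.05/0.01/0.001/0.0001. Pairwise p-values are uncorrected by default —
a Holm option exists but is off, since the characterization is
descriptive labelling rather than confirmatory inference — and both
choices are surfaced in the result object. A subtype is labelled High
(Low) on a pathway only when it differs significantly from at least
three other subtypes, all in the same direction; significant differences
against fewer groups or in mixed directions yield CNBD ("cannot be
determined"), and single-member groups yield no labels because a
rank-sum test against one observation is not interpretable. Degenerate
all-tied comparisons are reported as $p = 1$ rather than `NaN`.

Assignment to predefined reference clusters (externally defined
molecular subtypes with known per-pathway centroids) minimizes the sum
of squared score differences; ties break to the lowest centroid index
and are flagged.

## Tumor–cell-line matching

Each tumor sample is matched to the cell line minimizing
$\sum_{p \in S} (s_{t,p} - s_{c,p})^2$. The default subset
$S = \{\mathrm{AR, ER, HH, NOTCH, TGFB}\}$ is the five-pathway panel
used for radar-map comparison of matched pairs; it is narrower than the
seven-pathway clustering set and always recorded in the match table, and
any other subset can be requested explicitly. Ties break
lexicographically by cell-line id and are flagged.

Composition summaries count matched tumors per histology for each cell
line and report integer percentages (half-up rounding, matching how such
tables are conventionally printed). Coverage expresses the same counts
as shares of each histology's whole cohort. Ranking of representative
cell lines uses a two-tier rule, `majority-then-count`: cell lines whose
matches are mostly (> 50%) of the target histology come first, ordered
by matched count of that histology, followed by the remaining matched
lines in the same order; exact ties share a rank and are flagged. No
single statistic reproduces every published ranking convention, so the
rule identifier is attached to every ranking for transparency, and the
rule is replaceable.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth. It emulates a log2-intensity expression cohort:

* **Pathway definitions**: 25–35 synthetic targets per pathway, weights
  $\sim U(0.3, 1)$, ~20% down-regulated — the make-up of curated
  target panels.
* **Archetypes**: seven qualitative activity templates (high/low flags
  become latent levels 0.9/0.1, unmentioned pathways 0.5) covering
  hormonally active, hormonally low, HH-high, Wnt/HH-high and
  developmentally quiet patterns. They are test fixtures, not claims
  about real tumor biology.
* **Expression**: gene baseline $\sim N(8, 1)$ log2 units (typical
  microarray intensity scale); an entity with activity $a$ on pathway
  $P$ shifts each up-target by $a \cdot \text{effect} \cdot w_g$ (down-
  targets subtract), with effect = 3 log2 units for a weight-1 target —
  a strong but realistic direct-target response. Every sample adds
  i.i.d. $N(0, \sigma)$ noise with $\sigma = 1$ by default, a typical
  between-replicate spread at this scale. Replicates share the latent
  state and differ only by noise.
* **Matched cohorts**: cell lines and tumors drawn from the same
  archetypes with independent noise; the ground-truth correct match is
  any cell line of the tumor's archetype.

The generator never emits scores — only expression — so recovery tests
exercise the full scoring path. All generators are deterministic per
seed, and because noise is drawn as scaled standard normals, runs at
different noise levels under the same seed share their noise pattern,
which makes the monotone-degradation property (recovery quality
non-increasing in $\sigma$) checkable without Monte Carlo averaging.

One structural caveat: archetypes C4 (HH-high, NF-κB-low) and C5
(Wnt/HH-high) coincide exactly on the default five-pathway matching
subset, because NF-κB and Wnt are not in it. Matched-cohort recovery
experiments therefore use the six separable archetypes; using all seven
would make "same-archetype" matching undefined between C4 and C5 rather
than hard.

**Verification problem sizes.** The shipped tests run cluster recovery
at 7 archetypes × 8 entities (ARI ≥ 0.8 at $\sigma = 0.3$ against the
planted archetypes), matching recovery at 6 archetypes × 2 cell lines ×
6 tumors (≥ 90% same-archetype at $\sigma = 0.3$), monotone degradation
at $\sigma \in \{0.3, 1.5, 4\}$, and the type-I error of the omnibus
characterization test over 1000 null cohorts of 4 groups × 8 samples
(empirical rejection within ±2% of the nominal 5%).

**What passing these tests does and does not show.** The generator
draws independent Gaussian noise per gene and sample. It does not
emulate probe-level artifacts, batch effects between datasets,
correlated noise across co-regulated genes, partial archetype mixtures,
or clonal drift of cultured lines. Recovery on synthetic cohorts
demonstrates that the chain is implemented correctly and is stable under
the stated noise, not that real cohorts will cluster this cleanly.

## Numerical choices and degenerate inputs

* $\kappa < 0.5$ strictly, so likelihood ratios are finite; $\kappa$ and
  the prior are validated at construction.
* Scores are clipped to $[0, 100]$ after the linear map; with
  `"extremes"` calibration the map cannot overshoot, with explicit
  anchors it may.
* Squared distances are computed via the expanded quadratic form and
  floored at 0 to absorb rounding; distance ties use a $10^{-9}$
  absolute tolerance.
* Duplicate gene rows in input TSVs collapse to their mean with a
  warning; ragged rows and non-numeric cells fail with coordinates.
* An all-identical profile clusters with zero merge heights and a
  warning rather than an error.

## Limitations

The scorer is a deliberately parameter-light reconstruction of the
two-layer target-gene approach: evidence weights, priors and the CPT
bound are configurable inputs, not trained values, and the bundled
definitions are synthetic. Results on real cohorts depend on supplying
curated target-gene panels and, ideally, reference-calibrated anchors.
Matching quality is bounded by the pathway subset used — pathways
excluded for culture-sensitivity may still matter in vivo — and
least-squares nearest-neighbor matching returns exactly one cell line
per tumor even when several are nearly equidistant; inspect the
distances, not just the identities.
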