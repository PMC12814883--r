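---
title: "Comparative analysis of multiple CRISPR arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of multiple CRISPR arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprarrays)
```

## The problem

Prokaryotic genomes frequently carry several CRISPR arrays and several
CRISPR-Cas systems at once. Which arrays actually acquire new spacers, how
arrays are positioned and oriented around their Cas loci, and whether
co-occurring Cas types interact are comparative questions: they are answered
by contrasting observed annotation tables against explicit null models.
`crisprarrays` implements that comparison layer. It consumes per-genome
annotation tables (arrays with ordered spacers and a consensus repeat; Cas
loci with a subtype label) as produced by upstream detection tools, and
provides five analyses plus a synthetic cohort generator used to validate
every one of them against known ground truth.

## Array-to-locus assignment

Every array is assigned to the Cas locus minimising the gap between the
nearest feature ends, `max(0, max(start_a, start_l) - min(end_a, end_l))`,
with overlapping intervals at distance 0 ("overlap" side). Arrays in genomes
without any Cas locus are orphans, labelled `"no cas type"`, and are excluded
from co-occurrence, geometry, and weight analyses. An array is "close" when
its gap is below 10 kb — the threshold under which positional and
orientational biases around Cas loci are concentrated; it is a parameter
(`close_threshold_bp`) everywhere it matters.

Coordinates are 0-based half-open in files and memory (the upstream tools do
not share one convention, so the package pins one). Distances are only
computed within one replicon (`seq_id`): a gap across contigs is
meaningless. This creates one edge case the input contract cannot avoid: an
array on a replicon with no Cas in a genome that has Cas elsewhere has no
defensible distance, and is reported as an orphan. Ties between equidistant
loci go to the smaller start coordinate, then the lexicographically smaller
locus id, making assignment deterministic.

## Co-occurrence of Cas types

With `n` genomes and type counts `j` and `k`, independent reshuffling of
presence labels gives an expected co-occurrence count of `j k / n`, and an
expected solo count for type `t` of `j_t * prod_{s != t}(1 - j_s / n)`.
Observed counts are contrasted with these expectations through a signed
fold-change: `observed/expected` when observed is larger, `-(expected /
observed)` otherwise, so the magnitude is always at least 1 and the sign
carries the direction. The degenerate cell `observed = 0` has no finite
ratio; the package reports `-expected` flagged as a lower bound, because the
cell still says "depleted at least `expected`-fold".

Solo counts are tested with a two-sided exact binomial test of
`observed_solo` out of `n` trials at `p = expected_solo / n`
(`stats::binom.test`, minimum-likelihood opposite tail). Sidedness is a
choice the package pins explicitly; one-sided variants halve the p-values
but do not change which cells clear the default gate in practice. Cells are
reported when observed or expected reaches `min_count` (default 50 — below
that, fold-changes are dominated by shot noise); solo cells additionally
require `p < alpha` (default 1e-4). Pair cells are gated by count only;
their binomial p-values are computed and exposed but do not gate. No
multiple-testing correction is applied: the gate is a fixed stringent alpha,
not an FDR procedure.

## Insertion-rate weights under the independent deletion model

The turnover model behind the weight analysis assumes each array gains
spacers at rate `theta` and loses each spacer independently at rate `rho`,
which makes the stationary array length Poisson with mean `theta / rho`.
Deletion is driven by replication-scale processes and is taken as constant
within a genome, so for the `k` arrays of one genome the length `n_i` is a
proxy for the insertion rate `theta_i = n_i * rho`, and the relative
insertion-rate weight is

```
w_i = theta_i / theta = n_i / (n_1 + ... + n_k)
```

— `rho` cancels and never needs a numeric value outside the generator. The
analysis keeps genomes with exactly 2, 3, or 4 in-scope arrays (larger `k`
mixes too many configurations; genomes containing any orphan array are
excluded entirely), and optionally restricts each genome to its arrays
sharing one consensus repeat. When a genome has several identical-repeat
groups the largest is taken, ties broken by total spacer count
(`all_groups = TRUE` emits every group of size two or more instead).

The neutral reference: if every new spacer lands in any of the `k` arrays
with probability `1/k`, then conditional on the total `n` the lengths are
`Multinomial(n, 1/k, ..., 1/k)`. For each observed record one matched draw
is taken at its `(k, n)`, so the null has exactly the sample size of the
data. Under this null each weight has mean `1/k` and variance
`(1/k)(1 - 1/k)/n`; the observed/null variance ratio reported by
`weight_summary()` is the package's measure of per-array acquisition-rate
heterogeneity, and the close-vs-far mean weights measure proximity bias.

## Repeat space

Consensus repeats are compared by Levenshtein distance (`edit_distance()` is
a two-row dynamic programme; `distance_matrix()` uses the C implementation
in `utils::adist`, and the two are cross-checked in the tests). Distances
can be normalized by the maximum repeat length within a genome or across
the whole input; normalization over "the full input scope passed in" is the
package's reading of a globally-normalized analysis — callers control the
scope by controlling the input. Uppercasing is applied first;
reverse-complement folding is available in the census but off by default,
as repeats are compared as reported.

The 2-D embedding minimises raw stress (the residual sum of squares between
input dissimilarities and embedded Euclidean distances) with the SMACOF
majorization algorithm: the Guttman transform is applied until the stress
decrease falls below `tol`, from `n_init` random starts, keeping the best.
The Guttman step never increases stress, which the tests assert on the
per-iteration trace. Defaults (`n_init = 4`, `max_iter = 300`,
`tol = 1e-4`) are pinned explicitly; exact recovery tests tighten `tol`
because stress converges linearly near an exact embedding. Degenerate
inputs are defined rather than errors: a single point embeds at the origin
with stress 0, and an all-zero dissimilarity matrix collapses to a point.
A full-cohort embedding is quadratic in the number of arrays, so the
pipeline subsamples (stratified by assigned type, seeded) above
`subsample_cap` arrays, 1000 by default.

Marginal densities of embedding coordinates use a plain Gaussian KDE with
Scott's-rule bandwidth (`stats::bw.nrd`), exposed as a parameter. A
constant sample has bandwidth 0 and is rejected with guidance rather than
returning a degenerate density.

## The synthetic cohort generator

`generate_cohort()` emulates the annotation tables the analyses consume,
with every structural knob the analyses are sensitive to: per-genome type
presence with exact marginals and optional pairwise dependence (sequential
conditional Bernoulli sampling — the analysis null is fully independent,
only the generator needs dependence); one locus per present type;
arrays-per-locus counts; Poisson(`theta/rho`) lengths with an optional
`acquisition_bias` multiplier on close arrays; per-type placement
(side/orientation/closeness probabilities, near gaps exponential with mean
1.5 kb truncated at 10 kb, far gaps uniform on 100 kb–1 Mb); per-type
ancestral repeats diverged by per-site substitution; locus-level
duplications copying the repeat and a leader-distal spacer suffix; and
orphan arrays. Defaults describe a plausible cohort — seven common types at
frequencies 0.05–0.25, ~1.5 arrays per locus, stationary length 15, 80%
close placement, 2% per-site repeat divergence, 10% duplication and orphan
rates — chosen once as field-realistic values.

Deliberate simplifications: spacers are random 32-mers (identity is all the
analyses use — no PAM or secondary structure), genomes are single 4-Mb
replicons, and genomes are phylogenetically independent. Zero-length
Poisson draws are redrawn to one spacer or more (an annotated array holds
at least one spacer) and flagged in the ground-truth table. Consequently,
passing recovery tests demonstrate that the analyses measure what they
claim on data with this statistical structure; they cannot speak to
detector artefacts, taxonomic correlation, or repeat-sequence realism in
real annotation tables.

## Problem sizes and test design

The validation suite pins its own scales: 20,000-genome presence tables for
co-occurrence recovery (a 5x joint enrichment on a 0.05/0.05 pair is
recovered with fold-change in [4, 6], and an independent cohort keeps ≥95%
of reported pair fold-changes inside [-1.5, 1.5]); 2,500-genome two-array
cohorts for acquisition-bias detection (bias 3 shifts close-array weights
above 1/2 by more than 3 standard errors, and the same-repeat restriction
at bias 1 shows no shift); 10,000 draws for Poisson stationarity and
neutral-mean checks at 3 Monte Carlo standard errors; exhaustive
edit-distance enumeration over binary strings up to length 6 against an
independent memoised recursion; and a five-genome hand fixture whose census
fractions are asserted exactly, with a quadratic brute-force pair scan as
oracle on 200-genome cohorts.

## Known limitations

Census denominators follow the nested reading (spacer-overlap, identical
multiset, and last-spacer fractions are all fractions of *all* arrays, and
therefore sub-fractions of the identical-repeat fraction). Identical
repeats mean byte-identical strings; near-identical repeat clustering is
out of scope. The fold-change sentinel for empty cells is a reporting
convention, not an estimate. SMACOF finds local optima; `n_init` trades
runtime against the risk of a poor start, and configurations that are not
exactly 2-D-embeddable retain positive stress by necessity. The weight
analysis pools arrays across Cas types within a genome unless a per-type
filter is requested; whether pooling is appropriate depends on the
question.
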