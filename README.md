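# crisprarrays

Comparative analysis of prokaryotic genomes carrying **multiple CRISPR
arrays** and **multiple (co-occurring) CRISPR-Cas systems**.

Upstream detection tools answer *where* arrays and Cas loci are; the open
questions are comparative. Which of a genome's arrays actually acquire new
spacers? Are arrays near the Cas locus favoured, or is sharing the consensus
repeat what matters? Do certain Cas types co-occur more (or less) often than
chance? `crisprarrays` is for computational microbiologists who have
per-genome annotation tables (arrays with ordered spacers and a consensus
repeat; Cas loci with subtype labels) and want those questions answered
against explicit null models, with every analysis validated on synthetic
cohorts with known ground truth.

## What it computes

Given arrays/loci TSVs (or a simulated cohort), after assigning each array
to the Cas locus minimising the end-to-end gap (arrays with gap < 10 kb are
"close"; genomes without Cas yield orphans labelled `no cas type`):

- **Cas-type co-occurrence.** With type counts *j*, *k* among *n* genomes,
  independence predicts *jk/n* joint occurrences and
  *j<sub>t</sub>* ∏<sub>s≠t</sub>(1 − *j<sub>s</sub>*/n) solo occurrences.
  Deviations are reported as a signed fold-change (obs/exp if obs ≥ exp,
  −exp/obs otherwise; magnitude always ≥ 1) with two-sided exact binomial
  p-values, gated at ≥ 50 observed-or-expected counts.
- **Locus geometry.** Signed distance to Cas (negative = before, positive =
  after, 0 = overlap), orientation, binned distance histograms, and
  side/orientation configurations of two-array single-type genomes.
- **Redundancy census.** Fractions of arrays that co-occur in a genome with
  an identical consensus repeat, share spacers, have identical spacer
  multisets, or share the leader-distal (oldest) spacer; arrays per locus;
  array length by type and proximity.
- **Insertion-rate weights.** Under an independent deletion model (insertion
  rate θ, constant deletion rate ρ, stationary array length Poisson(θ/ρ)),
  array *i*'s share of its genome's total insertion rate is
  *w<sub>i</sub>* = θ<sub>i</sub>/θ = *n<sub>i</sub>*/*n* — pure length
  proportions. Each genome with *k* ∈ {2,3,4} arrays is matched with one
  draw from Multinomial(*n*, 1/*k*, …, 1/*k*)/*n*, the neutral
  every-array-equal null; the observed/null variance ratio and close-vs-far
  mean weights quantify acquisition biases.
- **Repeat space.** Levenshtein distances between consensus repeats
  (normalized per genome or globally), 2-D metric MDS via the SMACOF
  majorization algorithm (raw-stress minimisation, monotone per iteration),
  and Gaussian-KDE marginals of the embedding coordinates.

A generator (`cohort_spec()` / `generate_cohort()`) simulates cohorts with
all of the structure above — configurable type frequencies and pairwise
dependence, Poisson(θ/ρ) lengths with an optional acquisition bias for
close arrays, placement/orientation biases, repeat divergence from per-type
ancestors, duplications, orphans — and returns the ground truth for
recovery tests.

## Worked example

Simulate 5000 genomes with a 4× co-occurrence enrichment injected for the
II-C/III-A pair, then recover it:

```r
library(crisprarrays)

spec <- cohort_spec(
  n_genomes = 5000,
  pair_enrichment = data.frame(type_a = "II-C", type_b = "III-A", multiplier = 4),
  seed = 1)
gen <- generate_cohort(spec)
asn <- assign_cohort(gen$cohort)

tab <- cooccurrence_table(gen$cohort)
tab[tab$reported, ]
#> Cas-type co-occurrence over 5000 genomes (2 solo, 10 pair cells; 12 reported)
#>  kind type_a type_b observed expected fold_change ...  p_value reported
#>  solo   II-C   II-C      180   246.03       -1.37 ... 7.31e-06     TRUE
#>  solo  III-A  III-A      109   178.59       -1.64 ... 1.56e-08     TRUE
#>  pair    I-C    I-E      108   100.02        1.08 ... 4.19e-01     TRUE
#>  ...
#>  pair   II-C  III-A      149    38.08        3.91 ... 9.75e-43     TRUE
```

The injected pair stands out at fold-change **+3.91** (149 observed vs 38.1
expected, p ≈ 1e-42) while the ten un-enriched pairs sit between −1.30 and
+1.17; the two enriched types are correspondingly *depleted* as solo
systems (−1.37, −1.64), since they now co-occur more often than chance.

```r
repeat_spacer_census(gen$cohort, asn)
#> Redundancy census over 6660 arrays: 29.5% share a repeat in-genome;
#> 12.0% spacer overlap; 0.0% identical spacers; 12.0% same last spacer
```

About 30% of simulated arrays have an identical-repeat partner in their
genome (driven by the generator's 10% duplication rate plus same-type
multi-array loci at 2% per-site repeat divergence), 12% still share
spacers, and none are full clones — duplicated arrays immediately diverge
by fresh leader-proximal acquisitions.

```r
rec  <- select_weight_genomes(gen$cohort, asn)
null <- neutral_distribution(rec, seed = 2)
weight_summary(rec, null)[, c("k", "n_records", "mean_weight",
                              "var_weight", "null_var", "var_ratio")]
#>   k n_records mean_weight var_weight null_var var_ratio
#> 1 2       765      0.5000     0.0085   0.0089    0.9600
#> 2 3       462      0.3333     0.0053   0.0053    1.0116
#> 3 4       278      0.2500     0.0030   0.0034    0.8996
```

Mean weights are exactly 1/k (a bookkeeping identity), and — because this
cohort was generated *without* acquisition bias — the observed weight
variance matches the matched multinomial null (ratio ≈ 1). Regenerating
with `acquisition_bias = 3` shifts close-array weights above 1/k and
inflates the ratio; the test suite asserts both directions.

## Layout

- `R/` — annotation I/O and assignment, generator, co-occurrence, geometry,
  census, weights + null, repeat space, pipeline driver.
- `vignettes/multi-array-analysis.Rmd` — models, assumptions, parameter
  defaults, numerical choices, limitations.
- `inst/cli/crisprarrays.R` — thin command-line driver;
  `read_spec_config()` parses its key/value + `[type ...]` config format.
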