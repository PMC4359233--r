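---
title: "Calling poised POL II promoters and their tissue-dependent expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling poised POL II promoters and their tissue-dependent expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pol2regulon)
```

## The model

A gene promoter tiled by probes every ~200 nt across −5000..+2500 nt of
the TSS yields a vector of log2 IP/WCE ratios per array. The analysis
asks three questions in sequence: where does POL II sit (binding), what
is transcribed (expression), and how do the two relate across biological
contexts (concordance and the classification cascade).

**Binding.** Each probe's log-ratio is standardized against the whole
array (median center, 1.4826·MAD scale) and converted to a one-sided
upper-tail p-value; this stands in for the array vendor's proprietary
error model and is exactly probability-integral-transform uniform on a
null array, which the test suite verifies by Kolmogorov–Smirnov. Probe
triples within 1100 nt are combined by an equal-weight Stouffer sum —
the composite statistic the neighborhood model needs but never defines;
Stouffer was chosen over Fisher here because it is symmetric, monotone
and two-sided-extendable, and it is isolated in `composite_triple_p()`
so it can be swapped. A central probe is a bound site when the
composite `p_x_bar < 0.05` and a neighbor clause holds. Note the two
published clauses are nested: "center and one neighbor < 0.05" implies
"one neighbor < 0.1", so the rule reduces to
`p_x_bar < 0.05 AND min(p_left, p_right) < 0.1`; both clauses are still
implemented literally.

**Gene-level calls.** Over the bound sites of a gene, Fisher's method
gives the joint `p_jt` (χ², 2n df) and the geometric-average transform
gives `p_gav`, which equals the geometric mean of the inputs exactly —
an identity the suite asserts to 1e−12. A subtlety forced a design
decision: every bound site has `p_x_bar < 0.05` by construction, so a
geometric mean over *bound sites only* is always below 0.05 and a
"loose" class on 0.05 ≤ p < 0.13 could never be populated; moreover,
with uniform null probe p-values the triple rule produces at least one
chance site in roughly two thirds of null promoters, so "bound gene =
has a site" would be useless. The gene-level *call* therefore uses the
promoter-wide geometric-average p (`p_gene`, over all eligible triples)
with tight < 0.05 and loose < 0.13, and additionally requires at least
one bound site. On null promoters `p_gene` concentrates around 0.4 and
essentially never reaches 0.13, while planted peaks drive it far below
0.05 — this is, as far as we can tell, the only reading under which
tight and loose binder classes both exist.

**Stalling index.** `max` linear enrichment over (−300, +300) divided by
`mean` linear enrichment over (+300, +2500]. The windows follow the
traveling-ratio literature and are configuration-exposed
(`binding_config()`), since the published "slight modification" of the
index is not recoverable; a flag switches to log-scale enrichment. A
promoter with no probe in either window returns an `NA` sentinel rather
than an error.

**Expression.** Quantile normalization equalizes the column
distributions (ties receive the mean of the tied targets; verified
against limma's implementation). The moderated t shrinks gene-wise
pooled variances toward a prior, `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, with
`(d₀, s₀²)` estimated by moment matching of `log s²` via
digamma/trigamma (Newton inversion of the trigamma function); `d₀ = 0`
reproduces the ordinary pooled t to 1e−10 and `d₀ = ∞` pins every
variance at `s₀²`. Tumor cohorts are standardized per gene (sample sd
by default; the population-sd convention is a switch) *within* each
cohort, merged on the uppercased intersection of gene identifiers, and
stratified by the top and bottom `q = 0.35` quantiles of the marker
gene's expression — `floor(q·n)` samples per stratum, middle discarded,
ties broken by stable sample-id order. Unadjusted `p < 0.05` is the
default significance rule to mirror the analysis being reproduced;
Benjamini–Hochberg and top-k selection are configuration switches, and
under the global null top-k at the observed `p < α` count reproduces
the `p < α` set exactly.

**Concordance.** Two DE analyses restricted to significant genes with a
direction are crossed into a 2×2 table; Cohen's kappa is reported with
the Fleiss *null-hypothesis* standard error as the primary `se` (because
`z = κ/se` is used as a test statistic) and Cohen's large-sample SE as
`se_alt` — the published SE convention is not recoverable from the
printed values, so both are exposed. The permutation null draws random
gene sets, assigns directions by fair coin (a permutation mode is
available) and recomputes kappa per round; rounds with empty overlap are
recorded as missing, never silently dropped. The overlap test reports
the add-one empirical tail probability as primary and the historical
"null mean over observed" ratio estimator flagged as non-standard.

**The cascade.** regulon = tight-or-loose in every HER2-positive line
and unbound in every control; regulated = regulon ∩ significant in at
least one cell-line comparison (a switch demands all three); concordant
= significant with one shared direction in *all* comparisons; poised =
regulon ∖ concordant (so a gene significant everywhere but discordant
counts as poised, which is what makes the published counts add up);
tissue-dependent = poised ∩ tumor-significant, partitioned by direction;
poised genes absent from the tumor universe are flagged not-assayed
rather than dropped. All five structural invariants are asserted on
every construction.

## The synthetic world

The generator states one world and the tests live in it; none of its
parameters were revisited after seeing test outcomes.

| parameter | default | why |
|---|---|---|
| probe spacing / window | 200 nt, −5000..+2500 | the tiling design being emulated (38 probes/gene) |
| cell lines | 3 HER2⁺ + 1 control, 3 replicates | the panel structure being emulated; ≥2 replicates are required, 3 gives the moderated t realistic df |
| cohorts | 197/173/115/247/80 samples | the five published tumor cohort sizes (812 total) |
| fraction bound | 0.15 | scaled-up analogue of ~737/17000 so sets stay testable at n = 600 |
| fraction regulated of bound | 0.15 | ≈ 93/737 |
| fraction tissue-dependent of poised | 0.16 | ≈ 113/686 |
| peak height / width | 2 log2 / 500 nt FWHM | a strong promoter peak a few noise-sd high |
| chip noise sd | 0.25 log2 | typical tiling-array residual spread |
| expression effect | 4 noise-sd | engineered overexpression lines show large fold changes; gives ~97% per-comparison power at 3v3 so planted concordant genes are recovered |
| expression noise sd | 0.5 log2 | typical replicate-level array noise |

Stalled genes concentrate their peak at the TSS (Gaussian); elongating
bound genes carry a uniform 0.6·peak elevation across the window — the
probe-level signal shape is not described anywhere, so both profiles are
labelled stand-ins. Cohort heterogeneity is a per-cohort, per-gene
affine distortion (scale `exp(U(−0.3, 0.3))`, shift `N(0, 0.5)`), which
makes the per-gene standardization step consequential: skipping it
visibly breaks the merged analysis. The planted tumor effect is
calibrated so that `effect_size_de` is the *expected standardized
difference between the top-35% and bottom-35% HER2 strata* (the gap
between stratum means of a standard normal gradient is
`2φ(Φ⁻¹(0.65))/0.35 ≈ 2.12` sd). Randomness is confined to one seeded
generator per dataset, with sub-stream seeds derived deterministically,
so identical configurations are byte-identical on disk.

What a green test does *not* establish: real arrays have correlated
probe noise, dye and spatial artifacts, non-normal error tails, and
gene-identifier ambiguity across platforms; none of that is modelled,
so recovery rates here are upper bounds on real-data performance.

## Numerical choices and degenerate inputs

* p-values are floored at 1e−300 before logs and probit transforms, and
  the composite p is floored after combination — extreme planted peaks
  otherwise underflow `pnorm` to an invalid exact 0.
* A MAD of zero (constant array) is an error by contract, so the
  "noiseless" acceptance world keeps a tiny chip noise (sd 0.05) while
  setting expression noise exactly to 0; with zero expression noise,
  unregulated tumor rows are constant, are excluded by
  `standardize_genes()` with a warning, and surface as not-assayed —
  the moderated-t prior is fixed (`d₀ = 4, s₀² = 0.01`) in that world
  because the variance moments are degenerate.
* `direction` maps |logFC| < 1e−12 to "zero" and such genes leave the
  direction tables.
* Kappa with `pe = 1` returns an undefined-kappa sentinel; the inner
  term of the null SE is clamped against tiny-table rounding.
* Edge probes cannot be central probes (the rule needs two neighbors);
  fewer than three probes yield an empty call list, not an error.
* One documented deviation from an obvious-looking invariant: quantile
  normalization followed by row standardization is **not** idempotent as
  a composition (standardizing rows breaks the equal-column property
  again); each operation is idempotent on its own, and that is what the
  suite asserts.

## Known limitations

The composite-p choice (Stouffer) and the stalling windows are defensible
stand-ins for unpublished details, not reconstructions. The pipeline's
concordance stage floors the top-k comparison size at a quarter of the
gene universe so small simulations keep a populated direction table; at
published scale (3350 of ~7300 genes) the floor is inactive. Gene
identifiers are matched by uppercase string equality only — no alias
resolution. Long genes extending past +2500 nt are outside the window by
design, as they are for the array being emulated.
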