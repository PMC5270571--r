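---
title: "Characterizing a defined gut consortium: coverage analysis and the spent-media screen"
author: "asfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a defined gut consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asfscreen)
```

# The scientific problem

Defined microbial communities — the motivating system is the eight-member
altered Schaedler flora (ASF) used to standardize gnotobiotic mice — are only
useful as model microbiomes to the extent that we understand two things:
how much of a wild microbiome's functional gene content the consortium
represents, and how its members interact metabolically. `asfscreen`
implements both analyses as a tested pipeline over plain-text inputs, plus a
seeded synthetic-data generator so that every stage can be exercised with
known ground truth.

# Functional coverage of wild metagenomes

Gene function is counted in units of non-supervised orthologous groups
(NOGs). Each gene call receives at most one NOG: the hit with the lowest
E-value, provided it is strictly below $10^{-10}$
(`selectBestAnnotation()`), with equal-E-value ties broken by
lexicographic NOG id so annotation is reproducible. NOGs annotated in more
than one functional category are ambiguous functional units and are
discarded at the entry of every analysis (`discardMulticategory()`); they
remain in the catalog so the filtering decision is visible and reversible.

Against a reference collection of 15 wild-mouse fecal metagenomes, every
observed NOG has a *sample frequency* in $1..15$; the *core* is the set at
frequency 15. Coverage of each frequency bin by a consortium is

$$\mathrm{cov}(f) = 100 \cdot
  \frac{|\{\text{NOGs at frequency } f\} \cap \bigcup_i A_i|}
       {|\{\text{NOGs at frequency } f\}|}$$

where $A_i$ are the members' annotation sets. Bins containing no NOGs are
reported as absent rather than 0%, which keeps the per-bin conservation
identity (covered + uncovered = bin size) exact and testable.

The null model draws random consortia from phylum pools (989 Firmicutes and
176 Bacteroidetes candidates) in a 6:2 ratio, mirroring the dominant phyla
of the mouse gut. Three design choices were genuinely open and are fixed as
follows:

* **Sampling is without replacement within a draw** and independent across
  draws — a community cannot contain the same species twice.
* **The 6:2 ratio scales proportionally** with consortium size: 8 → 6+2,
  16 → 12+4, 32 → 24+8. Only the ratio, not per-size counts, is inherent
  to the design.
* **Percentile bands** over draws (median, 5th/95th) use the
  linear-interpolation convention (`quantile` type 7); the convention is
  recorded in the output's metadata because different conventions move the
  band edges at small draw counts.

`substituteMember()` supports the substitution variant of the null model
(replacing one Bacteroidetes member with a Deferribacteres species), and
`uniqueContributions()` attributes core NOGs held by exactly one member to
that member, per functional category — the statistic that identifies which
species carries the consortium's non-redundant coverage.

# Growth curves

Optical density is tracked at 870 nm for 70 h inside the anaerobic chamber,
while inoculation (OD600 = 0.001) and endpoint densities are measured on a
bench-top reader at 600 nm. `normalizeToEndpoints()` applies the affine map
anchoring the first raw reading to the inoculation OD600 and the last to
the endpoint OD600 — the minimal transform consistent with normalizing a
curve to two endpoint calibrations. A flat raw series with distinct
calibrations has no such map and is an error. Negative normalized values
(possible when noise at the baseline is mapped through a steep affine
slope) are retained: clipping would bias the integral.

The four LED channels of a well are averaged pointwise
(`averageChannels()`), the area under the curve is computed by trapezoidal
integration on the stored grid (`curveAuc()`, no extrapolation), and
growth is called per condition as AUC relative to the same species'
fresh-media AUC (`callGrowth()`):

$$\mathrm{relAUC} = 100 \cdot \frac{\mathrm{AUC}_{\text{condition}}}
 {\mathrm{AUC}_{\text{fresh}}}, \qquad
 \text{grew} \iff \mathrm{relAUC} \ge 10\%.$$

The 10% threshold is configurable and recorded in the output; the boundary
is inclusive (exactly 10% is growth). Replicate wells are integrated
individually and their AUCs averaged afterwards — integrating first keeps a
noisy well from distorting the shared curve, and the per-condition SD is
reported alongside.

# Metabolite profiles

The screen's metabolic readout is a table of 85 NMR peak integrals (36
mapped to named metabolites, the rest first-class `"Unknown NN"` peaks that
are never filtered) for fresh media, each species' spent medium, and every
double-spent medium. Each condition's replicate integrals are averaged
first, then converted to z-scores against the fresh-media reference
(`referenceStats()`, `zscoreProfile()`):

$$z = \frac{x - \mu_{\text{fresh}}}{s_{\text{fresh}}}$$

with the sample SD ($n-1$ denominator; the convention is recorded in the
output metadata). Calls use strict inequalities: High for $z > 2$, Low for
$z < -2$, Medium otherwise, so $z = \pm 2$ exactly is Medium. Consumed and
produced sets are the Low and High peaks of a profile. A peak with zero SD
across fresh replicates makes z undefined and is an error naming the peak,
never a silent infinity. Display clipping at $\pm 6$ (`clipForDisplay()`)
is cosmetic and never feeds a call. Double-spent conditions are z-scored
against the *fresh* reference, exactly like single-spent ones; transitions
are comparisons of the resulting calls.

One boundary statement in the source protocol is internally inconsistent —
taken literally, "consumed ($z < 2$)" would label an unchanged metabolite
($z = 0$) as consumed. The package implements consumed as $z < -2$,
symmetric with produced ($z > 2$) and consistent with the ±2 SD
significance rule used everywhere else.

# The interaction classifier

The atom of the interaction analysis is a `ComparisonRecord`: one
(donor, grower, peak) triple carrying the peak's call in the donor's spent
medium, its call in the double-spent medium, and the grower's growth flag —
which comes exclusively from the growth stage, never inferred from
metabolite data. Nine call transitions (grouped NoChange / Lower / Higher)
crossed with growth give 18 scenarios; `tabulateTransitions()` asserts the
marginal identities of the scenario table on every call. "Changed" means
the *call* changed, not the raw z — this call-level definition is what
makes the 9-pair structure of the scenario table exact.

Two interaction patterns are flagged, both requiring growth:

* **Cross-feeding** (`detectCrossFeeding()`): the donor produced a
  metabolite (High in spent) and it decreased (Medium or Low) after the
  grower grew in that medium.
* **Emergent metabolism** (`detectEmergent()`): the grower shows a
  production (transition Higher, own fresh-media call not High) or
  consumption (transition Lower, own fresh-media call not Low) behavior it
  does not show in fresh media. The exact published procedure for this
  classification lives in supplementary material that the package does not
  reproduce; the rule implemented here is reconstructed from the worked
  examples in the main text, is isolated behind one function so an
  alternative rule can be swapped in, and is recorded in the run manifest.

No-growth records are classified and tabulated but excluded from
interaction calls, matching the separate no-growth column of the scenario
table. `competitionMarkers()` lists peaks consumed by both members of a
pair — candidate competition substrates in co-culture.

# Genetic versus metabolic distance

`pairwiseDistances()` computes, for all unordered species pairs, the
Jaccard distance $1 - |A \cap B| / |A \cup B|$ between NOG annotation sets
and between metabolic profiles. Metabolic profiles are *tagged* sets of
(peak, consumed) and (peak, produced) elements: one species consuming and
another producing the same peak must count as different behaviors, or
closely related species with opposite metabolism would appear identical.

`nogMetaboliteCorrelation()` correlates each NOG's presence/absence vector
across species with each peak's response vector, using Spearman rank
correlation with midranks. The response is the species' z-score for the
peak in its own spent medium — z-scores rather than discrete calls, because
ranks of z carry strictly more information and the correlation is
rank-based anyway. P-values use the t approximation by default; an exact
permutation option exists for $n \le 8$ and is what the test suite's
brute-force oracle checks against. Bonferroni correction uses an
*explicit* test count: the published analysis corrected with
$n = 160{,}746$, a number not derivable from the stated dimensions, so the
count is configuration, never hard-coded; the default is the number of
pairs actually tested. Constant vectors (a NOG in all or no species) have
undefined correlation, reported `NA` and excluded from significance
counts. `filterInformative()` then removes pairs driven by a
single-species NOG or a single-species metabolite — with few species these
dominate the significant set without being informative.

# The synthetic-data generator

`syntheticScenario()` fixes the study conditions: 15 metagenome samples,
pools of 989 + 176 candidates, 8 species of which 7 grow (one member, like
*Mucispirillum* in the motivating screen, does not grow in the defined
medium and so donates no spent medium), 85 peaks, 70 h curves on 4 channels
from OD600 0.001, planted effects of at least 4 fresh-SD units, and a
spent-media growth probability of 12/42 — the growth rate realized in the
motivating screen. Values the source protocol does not state were chosen
once as field-realistic defaults and are not tuned: the NOG universe is
5000 orthologs (large enough for stable frequency structure, small enough
that the full null model runs in seconds; the frequency distribution is
geometric with a core mass calibrated to the ~2.7% core fraction observed
in real surveys), fresh media has 5 replicate rows and non-fresh conditions
3, integral noise is additive Gaussian with SD 0.05 truncated at zero (the
simplest noise model consistent with z-score methodology), and logistic
growth uses rate 0.3 h⁻¹ with midpoint 15 h.

The generator plants ground truth: a designated large-genome species holds
29% of the core set exclusively (the share the top contributor held in the
motivating screen); donors produce and consume disjoint peak pools (so a
cross-feeding signature cannot arise from coincidental overlap of one
species' production with another's consumption — only planted cross-feeding
triples place a grower's uptake on a donor-produced peak); and emergent
events sit on peaks untouched by either species' fresh-media behavior.
Double-spent conditions compose the donor's spent profile with the grower's
fresh-media behavior when growth occurred, so unplanted records exercise
realistic NoChange/Lower/Higher transitions.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: peak alignment and integration error upstream of
the integral table, correlated (matrix-effect) noise across peaks,
metabolically active but non-dividing cells (the real screen saw hundreds
of changed metabolites without growth; synthetic no-growth conditions
reproduce the spent profile up to noise), instrument drift in OD, and any
relationship between a species' NOG content and its metabolic behavior —
genotype and phenotype are generated independently, so the correlation
stage is exercised for correctness, not for effect-size realism.

A known artifact the generator *shares* with the real method: with few
fresh replicates the SD estimate is noisy, occasionally inflating z-scores
of unaffected peaks past the threshold. This produces a small false-call
rate concentrated on unlucky peaks — visible in the calibration tests,
which bound it (FPR ≤ 0.05 over 20 seeds) rather than pretend it away. The
strict recovery property (100% sensitivity, zero false positives for
planted cross-feeding) is asserted under a tight-reference configuration
(40 fresh replicates, 12 condition replicates, noise SD 0.01), where the
reference estimate is sharp.

# Problem sizes used by tests and the acceptance script

The test suite and `scripts/acceptance.R` run the screen at its native
cardinality (7 growers × 6 donors × 85 peaks = 3570 comparisons) but scale
the surrounding simulations down — NOG universes of 50–400 for
oracle-checked coverage, pools of 15 + 6 rather than 989 + 176, null models
of tens rather than 10,000 draws, and coarser growth-curve grids — sizes at
which exhaustive brute-force oracles are feasible and the whole suite runs
in about a minute. The statistics being checked (coverage arithmetic,
marginal conservation, call boundaries, metric axioms, rank correlations)
are size-free, and the full-dimension null model is a single
`runPipeline()` call away for users who want it.

# Known limitations

* The emergent-metabolism rule is a reconstruction (see above); counts of
  emergent instances in real data depend on the exact published procedure
  and the deposited integrals, neither of which ships here.
* The Bonferroni test universe of the published correlation analysis is
  unrecoverable from the text; results depend on the supplied `n_tests`.
* Growth calling reduces a curve to one number; lag, rate and capacity are
  deliberately out of scope (the screen's published analysis used AUC
  only).
* z-scoring assumes fresh-media replicate noise is representative of
  condition noise; heteroscedastic peaks will mis-calibrate calls in
  either direction.
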