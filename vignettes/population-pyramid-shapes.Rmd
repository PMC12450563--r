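---
title: "Classifying population pyramid shapes from studbook data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying population pyramid shapes from studbook data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popshape)
```

## The problem

Managed animal populations — zoo breeding programmes above all — are
monitored through studbooks: one record per individual with sex, birth and
death dates, and parentage. A population pyramid (counts per age class,
split by sex, for one calendar year) summarises such a population at a
glance, but a time series of pyramids across hundreds of populations
cannot be inspected visually. `popshape` implements a deterministic
pipeline that reduces each yearly, sex-specific pyramid to five age
buckets and classifies the result into one of eleven shape categories
(pyramid, inverted pyramid, bell, inverted bell, plunger, inverted
plunger, lower/middle/upper diamond, column, hourglass). Sequences of
shapes then support simple demographic key figures: transition
frequencies, the population change associated with each transition,
age-group proportions per shape, and the shape at each population's peak
size.

## Pipeline overview

1. **Curation** (`run_curation()`): parentage plausibility rules
   (probability below 100%, same-sex parent pairs, self-parentage,
   exchanged dam/sire, underage parents), litter grouping (same-dam
   births within 3 days become one litter at the median date; litters
   above the species maximum are halved at random under a seed),
   implausible interbirth intervals (below 90% of effective gestation;
   the later litter loses its dam), and the maximum-longevity record
   (oldest zoo-born dead individual).
2. **Life stages** (`estimate_life_stages()`): the age of first
   reproduction (AFR) is the floored minimum parent age; the onset of
   reproductive senescence comes from a gamma curve fitted to the
   proportion of proven breeders reproducing per age class, taken where
   the curve falls to 75% of its maximum on the right tail.
3. **Reduction** (`build_pyramid()`, `reduce_to_buckets()`): ages are
   floored on December 31 (an individual aged 363 days is in class 0);
   the classes are partitioned into juvenile `[0, afr)`, three adult
   blocks covering `[afr, onset)`, and senior `[onset, max_longevity]`.
   Each bucket carries the mean individuals per class and its SEM.
4. **Classification** (`classify_shape()`): consecutive buckets are
   compared with the mean ± 0.5·SEM overlap test, giving a step sequence
   of four values in {−1, 0, +1}; an 81-row decision table maps the
   sequence (plus, where needed, a comparison of two non-consecutive
   buckets) to a shape. Populations of 10 or fewer individuals of the
   sex in question are `not_ascribed`.
5. **Dynamics** (`transitions()`, `aggregate_transitions()`,
   `age_group_proportions()`, `peak_analysis()`).

## The decision table

The published material fixes the table only partially: the four
monotone/flat archetypes, the bell and plunger families, the diamond
rule ("depending on the broadest part") and one worked tie-break — the
sequence (−1, −1, −1, +1) is an hourglass when the top bucket has
recovered to at least the level of bucket 3, and a pyramid otherwise.
The remaining rows are a constrained reconstruction, computed (not
hand-written) in `decision_table()` and shipped for review as
`inst/extdata/shape_decision_table.csv` with a provenance column. The
construction principles:

* Patterns are grouped by their compressed sign sequence (runs of
  increases and decreases, zeros dropped): non-increasing patterns split
  into pyramid / bell (stationary base) / plunger (stationary top);
  single-peak patterns are diamonds; single-valley patterns are guarded
  hourglasses; peak-after-valley patterns are guarded diamonds.
* **Mirror anti-symmetry is enforced by construction**: for every
  pattern, the rule for its reversed-and-negated partner is derived
  mechanically (bucket indices reflected, shapes mirrored), so
  classifying an upside-down pyramid always yields the mirrored shape.
  Self-mirror valley patterns consequently need a symmetric three-way
  guard on the valley's two shoulders; the asymmetric "top bucket vs
  pre-valley" guard is used for all other valleys, generalising the
  worked tie-break.
* A multi-bucket interior maximum (e.g. steps (+1, 0, 0, −1)) does not
  name its broadest bucket; the table resolves lower vs middle vs upper
  diamond by directly comparing adult buckets 2 and 4. This follows the
  "broadest part" wording rather than the chain of consecutive
  equalities, which is not transitive.
* Where the published text leaves genuine freedom, rarer shapes take
  precedence over the default pyramid (column > hourglass > diamonds >
  plunger > bell > pyramid).

A startup self-check validates totality (81 patterns exactly once),
guard sanity (non-consecutive buckets only), the anchored rows, and
exact mirror anti-symmetry; construction fails loudly if any constraint
is violated.

## Numerical and convention choices

* **Ages**: floored `days / 365.25`. 363 days → class 0; 365 days →
  class 0; 366 days → class 1. "Alive on Dec 31" means born on or
  before and death strictly after; a death on December 31 counts as
  dead.
* **SEM**: sample (n−1) standard deviation of the per-class counts over
  the bucket, divided by √n; zero for single-class buckets, so
  single-class comparisons reduce to mean comparisons. The equality
  notion from interval overlap is deliberately not transitive; the
  classifier only ever uses pairwise comparisons.
* **Gamma fit**: least squares of `A·dgamma(age + 0.5, k, θ)` against
  the age-class probabilities, amplitude profiled out in closed form, a
  deterministic grid multistart (k in 0.5–16 by 0.5, θ in 0.25–8 by
  0.25) followed by L-BFGS-B refinement in log-parameters. The
  denominator of each age-class probability counts only proven breeders
  alive during that class, so mortality is not conflated with
  reproductive decline.
* **Senescence onset**: root finding on the right tail of the fitted
  density, then ceiling — an individual is senior only once past the
  threshold. For shape k ≤ 1 the rule is undefined (monotone curve) and
  the fit refuses with a pointer to manual thresholds.
* **Adult blocks**: the adult span must cover at least three years;
  when it is not divisible by three, the extra years go to the lower
  blocks (fixed, documented tie-break). An even-sized litter's median
  date is the earlier central date. The later birth of an implausibly
  short interbirth interval is the one invalidated.
* **Curation order**: litters are grouped before interbirth intervals
  are checked — litter mates would otherwise always violate the
  interval rule. The underage-parent rule runs once, after a
  provisional AFR is estimated from the links surviving the other
  rules; since that AFR is itself the minimum surviving parent age, the
  rule only bites when an AFR override is configured.

## The simulator and what it does (not) emulate

`simulate_studbook()` is a seeded individual-based model in yearly
steps: each female produces a litter with her age-specific probability,
the sire is drawn uniformly among living reproductive-age males, and
each individual survives each year with its age-specific probability.
Litters are dated July 1 plus a jitter of at most the litter window,
with one date per litter, so a clean simulated studbook passes curation
untouched. Founders are wild-born with ages from the
survivorship-implied stable age distribution, which also exercises the
rule that wild-born individuals never hold the longevity record.

The default species is zebra-like and chosen once: gestation 360 days,
litters of 1 (90%) or 2, fertility following a gamma(k = 5, θ = 2 y)
schedule from age 3 — peak reproduction around age 8 and a true
senescence onset of 12 years under the 75% rule, giving a 9-year adult
span that the bucketing splits evenly — and annual survival of 0.78 in
the first year followed by a senescent decline 0.96 − 0.006·age. The
fertility peak is calibrated in closed form so the net reproductive
rate is 1 (a stationary population). The senescent survival decline
matters: the shape interpretations presume that juvenile and old-age
mortality are the norm, and it is this gradient that makes the
stationary population classify as a pyramid.

Scenario presets (`scenario_library()`) start from 500 founders per
sex. The regimes are defined by the deterministic expectation of the
age structure — halting reproduction, for instance, moves the last
juvenile cohorts upward through the buckets, so the expected shape path
is exactly lower → middle → upper diamond — and at this size the
Poisson noise of the bucket comparisons is small against those
structural differences. With smaller populations the same mechanism
operates, but single-year misclassifications (a half-emptied bucket has
a large SEM and compares equal to almost anything) can reorder the
first occurrences.

The simulator does not emulate: transfers between institutions,
density dependence, pair bonds or mate fidelity, genetics, sub-year
demography, or recording habits that vary by institution. Passing
tests on simulated data therefore validate the algorithmic pipeline,
not the data quality of any real studbook.

## Problem sizes used in the test suite

The suite runs simulations of 80–500 founders per sex over 25–65 years,
1,000-draw classifier property checks, 24 gamma-recovery fits at 2,000
breeders per age class, and a 20-seed replication of the
reproduction-halt scenario; the whole suite completes in a few minutes
on one CPU.

## Known limitations

* The reconstructed decision-table rows may differ from the original
  supplementary mapping on patterns the published text never discusses;
  they are marked `reconstructed` in the shipped CSV and can be
  replaced wholesale if the original mapping becomes available.
* Species whose adult span is shorter than three years cannot be
  bucketed; sub-year age resolution is out of scope.
* Lost-to-follow-up individuals are treated as alive (their records
  carry no death date); only the longevity record guards against
  "immortal" records. A last-seen cutoff would be a natural extension.
* Male life stages under the simulator's uniform sire assignment are
  biologically flat: every reproductive-age male breeds at the same
  rate, so the estimated male senescence onset is late. This is a
  property of the mating model, not of the estimator.
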