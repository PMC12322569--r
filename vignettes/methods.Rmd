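---
title: "Methods: scoring, classification and overlap estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, classification and overlap estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrioverlap)
```

`nutrioverlap` measures how far two different definitions of "less
healthy" food coincide in consumption data: the nutrient-based HFSS flag
produced by the UK Nutrient Profiling Model (NPM), and the
processing-based ultra-processed food (UPF) flag produced by the Nova
classification. This vignette is the package's own account of the
methods: the models, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, the numerical conventions,
and the design choices that were genuinely open.

## The NPM score

The NPM scores a food per 100 g in three steps: "A" points for energy
(kJ), saturated fat (g), sugars (g) and sodium; "C" points for
fruit/vegetable/nut content (% by weight), fibre (g) and protein (g);
and the subtraction `score = A − C`. Each component is a banded lookup
against an ordered cutpoint list; a value must *strictly* exceed a
cutpoint to enter the next band ("more than X g"), a convention encoded
once, in `band_points()`, and enforced by boundary tests at every
configured cutpoint. A points run 0–10 per nutrient, C points 0–5 per
component, with the fruit/veg/nut bands awarding the sparse 1, 2, 5.

The protein cap: when `A ≥ 11`, protein points are not counted unless
the fruit/veg/nut component scored its maximum 5 points. This prevents
protein fortification from rescuing energy-dense products. Foods are
HFSS at `score ≥ 4`, drinks at `score ≥ 1`.

Threshold tables are configuration, not code (`inst/models/*.yaml`),
because the algorithm's skeleton is stable across variants while the
band values are not. `NPM2004` transcribes the 2004/05 technical-guidance
tables. `NPM2018` is shipped **provisional**: the public record states
the deltas (free sugars for total sugars, salt for sodium, fibre
component rescaled from a 24 g to a 30 g AOAC reference, energy from
8950 kJ to 8400 kJ) but we have not transcribed the consultation's own
band lists, so the config scales the 2004/05 energy cutpoints by
8400/8950 (rounded to a 315 kJ step), the AOAC fibre cutpoints by 30/24,
carries the sugar cutpoints over to free sugars unchanged, and expresses
the sodium cutpoints as salt. Anyone using the 2018 variant beyond
sensitivity analysis should replace that file with transcribed tables;
its `status: provisional` field says so.

Unit conventions: energy is kJ, with a kcal column converted at
4.184 kJ/kcal; salt and sodium interconvert as
`salt g = sodium mg × 2.5 / 1000`, applied only when the model's
required field is absent, and logged. NSP and AOAC fibre are *not*
interconverted — they are different laboratory quantities with separate
band lists — so a profile on a basis the model lacks is an error.
Missing free sugars under `NPM2018` fail loudly per item (collected into
an exceptions report) rather than being imputed, since silent imputation
would bias HFSS prevalence.

## Nova assignment

The Nova group of an item is resolved by precedence: override predicates
first, then the most specific rule in a user-supplied table (item →
subgroup → main food group). The overrides mirror the special-case
conventions for survey coding: toddler foods are group 4; home-prepared
dishes are group 1 *unless* they contain purchased/retailed/frozen
pastry, breadcrumbs or margarine, in which case group 4. They are
predicates over catalog flags, in that fixed order, rather than
hard-coded item lists.

The package deliberately ships no reconstruction of any survey's full
item-level Nova coding — that mapping is unpublished research data — so
real-data users must supply their own rule table, and the generated
synthetic catalog carries one of its own. An item covered by no rule
aborts the analysis (`validate_rule_coverage()` is the non-throwing
companion): defaulting an unclassified item to "not UPF" would
understate every overlap statistic, which is the one error mode the
design refuses. Alcohol-containing products and dietary supplements are
excluded before classification, with counts by reason.

## The overlap pipeline

Every diary row becomes exactly one event (`build_event_stream()`
guarantees join conservation), so foods reported repeatedly count
repeatedly — consumption-frequency weighting. Event energy is imputed
from `grams × energy density` only when the diary leaves it blank; a
recorded value disagreeing with the nutrient table by more than 0.5 kcal
is flagged but kept, since such inconsistencies occur in real survey
files and should be visible, not fatal.

Shares are computed on three bases: event count, energy (kcal) and food
weight (g). The four categories partition each basis exactly:
`neither = 100 − (HFSS + UPF − both)` and
`both ≤ min(HFSS, UPF)` are tested as invariants, and
`partition_from_marginals()` exposes the same arithmetic for desk checks
of published Venn figures. Food-level shares apply no survey weights by
design; weighting enters only at person level.

**Person level.** Each participant's shares are computed over their
pooled diary (all days summed) rather than as a mean of daily shares:
"per-capita daily" percentages of a 3–4-day diary are scale-invariant to
pooling, and pooling avoids undefined shares on zero-intake days. The
estimate across participants is the survey-weighted (Hájek) mean with
Taylor-linearised variance

$$\widehat{V} = \frac{\sum_i w_i^2 (x_i - \hat\mu)^2}{(\sum_i w_i)^2},$$

and normal quantiles for the two-sided 95% interval. No primary-sampling
-unit clustering or finite-population correction is applied — cluster
identifiers are outside the package's input schema — so intervals on
clustered survey data will be somewhat anti-conservative; this is a
documented limitation, not an option. The "UPF that is also HFSS" row is
a within-person ratio (share of the person's UPF mass that is HFSS);
participants consuming no UPF are undefined on it and drop out of that
row only. Subgroup tables split by the five age bands crossed with sex,
rescaling weights within each subgroup to sum to the subgroup sample
size, which preserves relative weights and leaves the point estimate of
the weighted mean unchanged (the estimator is scale-free in the
weights).

Age bands are read as whole completed years and encoded closed–open on
integer boundaries: [1.5, 4), [4, 11), [11, 19), [19, 65), [65, ∞). So
age 10.9 is "4–10" and exact 11 is "11–18".

**Rounding.** Reported percentages round to one decimal place, half away
from zero (`round_half_up()`), matching published-table convention.
Derived ratios are computed from unrounded masses and only then rounded;
this is why a ratio recomputed from already-rounded marginal percentages
can differ in the last digit from the published value (on the food-count
basis, 20.1/36.2 rounds to 55.5 while the value computed from unrounded
masses prints as 55.6 — an input-rounding artefact the acceptance suite
documents rather than hides).

## The synthetic generator

`generate_diet_data()` emulates the *structure* of an NDNS-style survey:
a catalog of main food groups (default 10), subgroups (20) and items
(50, scalable to the full 56/136/4555 shape); per-100 g nutrient
profiles; participants (default 200) with log-normal survey weights,
sexes at 46% male and ages spread over the five analysis bands roughly
as in the real survey's subgroup sizes; and 3–4 diary days of about 30
events per day, the intensity implied by ~1.7 million foods reported by
~15.7 thousand people over 3–4 days. Defaults of 50 items and 200
participants keep a full pipeline run in seconds; they are the package's
standing test conditions, stated here as its own choice of scale.

Classification structure is known by construction. Each item's HFSS
status is drawn first (default probability 0.33, near the observed
food-level share), then nutrients are sampled *inside* the band tables:
a target score is drawn on the correct side of the item's cutoff, a
consistent (A, C) point decomposition is chosen by enumerating the
feasible fruit/veg/nut–fibre–protein point grid (respecting the protein
cap), the A total is split across the four nutrients, and each
component's value is drawn uniformly within its band. This inversion
guarantees that scoring the emitted nutrients reproduces the intended
flags without rejection loops. Nova groups are drawn per main group at a
random resolution level (main group / subgroup / item) with group-4
probability `upf_prob` (default 0.36), and the emitted rule table plus
override flags reproduce the intended assignment exactly. The ground
truth record carries both the per-item flags and the exact food-level
shares implied by the emitted event stream, accumulated with plain base
R independently of the pipeline functions.

What the generator does **not** emulate: real marginal nutrient
distributions, food names, correlated food choices within a person,
seasonal or wave effects, energy under-reporting, or cluster sampling.
Passing tests therefore demonstrate the pipeline's *correctness*
(agreement with ground truth and with brute-force oracles), and the
estimator's *sampling behaviour* under clean conditions — not that any
particular real-world percentage is right.

## Numerical and testing choices

* All randomness flows from a single integer seed; the generator
  restores the caller's RNG state, and identical seeds give
  byte-identical CSV output.
* Boundary behaviour at every configured cutpoint (value equal vs just
  above) is asserted for every band list of both models.
* The scorer is checked for exact agreement against an independent
  linear band-scan oracle on 10,000 random profiles; partitions and
  contributor tables are checked against brute-force accumulators.
* Estimator behaviour is measured over 500 simulated populations of 100
  participants × 20 events with known category probabilities, where the
  person-level estimand is exact; bias is compared with Monte-Carlo
  precision (within two standard errors) and 95% CI coverage is
  required to land in [92%, 98%].
* Contribution tables break ties by group name ascending, so output
  ordering is deterministic; empty categories yield empty tables rather
  than errors; a partition with no UPF mass reports the UPF-also-HFSS
  ratio as missing rather than dividing by zero.

## Known limitations

* CIs ignore clustered sampling designs (no PSU input), and subgroup
  reweighting uses simple within-cell rescaling rather than any
  survey-specific reweighting recipe.
* The fruit/vegetable/nut percentage is a required input column; survey
  nutrient databases typically do not ship it directly, and the package
  takes no position on how it was derived.
* Which items count as "beverages" for the drink cutoff is
  catalog-supplied (`is_drink`); no default mapping is asserted.
* The `NPM2018` bands are provisional, as described above.
* Full-survey percentages require the survey deposit plus an
  analyst-supplied Nova rule table; without them the pipeline
  deliberately refuses to run rather than producing biased numbers.
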