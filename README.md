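# nutrioverlap

How much of the ultra-processed food supply does the UK's "high in fat,
salt or sugar" (HFSS) regulation actually touch? `nutrioverlap` answers
that question for diet-diary survey data: it classifies every food two
ways — by the UK Nutrient Profiling Model (NPM) into HFSS / not HFSS, and
by the Nova framework into processing groups 1–4 (group 4 = ultra-processed
food, UPF) — and quantifies the overlap of the two classifications in what
people actually eat. It is aimed at nutritional epidemiologists working
with NDNS-style food diaries (a food catalog, per-100 g nutrient
composition, consumption events, participants with survey weights).

## The model

**NPM score.** For each food, per 100 g:

```
A = pts(energy kJ) + pts(saturated fat g) + pts(sugars g) + pts(sodium)
C = pts(fruit/veg/nuts %) + pts(fibre g) + pts(protein g)
score = A − C*
```

Each `pts()` is a banded lookup: one point per cutpoint *strictly*
exceeded (A components: up to 10 points; C components: up to 5; the
fruit/veg/nut bands award 1, 2, 5). `C*` applies the protein cap: when
`A ≥ 11`, protein points are not counted unless the fruit/veg/nut
component scored its maximum 5 points. A **food** is HFSS when
`score ≥ 4`; a **drink** when `score ≥ 1`. Threshold tables are data, not
code: the bundled `NPM2004` model is the 2004/05 Ofcom model (total
sugars, sodium) and `NPM2018` is a provisional encoding of the 2018
consultation deltas (free sugars, salt, rescaled energy and fibre bands).

**Nova group.** Assigned hierarchically from a user-supplied rule table —
main food group, then subgroup, then item — preceded by override
predicates: toddler foods are ultra-processed; home-prepared dishes are
minimally processed unless they contain purchased/retailed/frozen pastry,
breadcrumbs or margarine, which makes them ultra-processed. Items covered
by no rule abort the analysis (a silent default would bias every overlap
statistic). Alcohol-containing products and supplements are excluded.

**Overlap.** Every consumption event (repeat consumptions counted every
time) falls in one of four categories — HFSS only, UPF only, both,
neither — and shares are computed on three bases: event count, energy
(kcal) and food weight (g). Food-level shares are unweighted by design;
person-level analysis computes each participant's within-person shares
(diary days pooled) and returns the survey-weighted mean with a two-sided
95% CI (Taylor-linearised variance, no clustering), overall and by the
five age bands (1.5–3, 4–10, 11–18, 19–64, 65+) crossed with sex. The
partition obeys `neither = 100 − (HFSS + UPF − both)` and the headline
ratio `UPF also HFSS = 100 × both / UPF`.

## Worked example

A synthetic NDNS-like survey with known ground truth (no microdata
needed):

```r
library(nutrioverlap)

sim <- generate_diet_data(generator_config(seed = 42))
an  <- analyze_diet(sim$catalog, sim$nutrients, sim$diary, sim$participants,
                    nova_rules = sim$nova_rules, subgroups = FALSE)
an
#> <overlap_analysis> model NPM2004, 19865 events, 200 participants
#> Food-level partition (% of basis mass):
#>         basis pct_hfss_only pct_upf_only pct_both pct_neither pct_all_hfss
#> 1       count          9.77         43.3     17.0        30.0         26.7
#> 2 energy_kcal         18.55         32.3     31.3        17.9         49.9
#> 3    weight_g          7.84         50.8     20.6        20.8         28.4
#>   pct_all_upf pct_upf_also_hfss
#> 1        60.2              28.2
#> 2        63.6              49.2
#> 3        71.4              28.8
```

Reading: in this simulated population 60.2% of all foods consumed are
UPF, 26.7% are HFSS, and only 28.2% of UPF foods would be caught by an
HFSS-based policy. Because the generator fixes each item's classification
up front, `an$partitions` matches `sim$ground_truth$shares` exactly —
that is the package's core self-check.

Survey-weighted person-level estimates on the energy basis:

```r
person_level_estimates(an$events, sim$participants, "energy_kcal")
#>         measure       basis point ci_low ci_high   n
#> 1       neither energy_kcal  18.2   17.5    19.0 200
#> 2       all_upf energy_kcal  63.5   62.5    64.6 200
#> ...
#> 7 upf_also_hfss energy_kcal  47.7   46.1    49.4 200
```

Each row is the weighted mean across participants of that participant's
own percentage (e.g. 63.5% of the average person's energy intake is UPF,
95% CI 62.5–64.6). The same arithmetic applied to a published Venn
figure's marginals recovers its derived values:

```r
partition_from_marginals(47.4, 59.8, 35.1, basis = "energy_kcal")
#>   ... pct_neither 27.9 ... pct_upf_also_hfss 58.7
```

File-based workflows use `read_catalog()` / `read_nutrients()` /
`read_diary()` / `read_participants()` / `read_nova_rules()` (a toy CSV
set ships under `inst/extdata/toy/`), and the same pipeline is scriptable
via the CLI launcher `inst/cli/nutrioverlap.R` with subcommands
`score`, `classify-nova`, `analyze` and `simulate`.

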