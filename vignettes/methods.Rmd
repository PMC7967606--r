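---
title: "Methods: parcel-level lead paint hazard scoring and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parcel-level lead paint hazard scoring and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadhazard)
```

## The hazard model

Lead-based residential paint was banned in 1978, so the population of
potentially hazardous dwellings is exactly the pre-1979 stock, and the
hazard that remains is governed by deterioration: paint peels where
maintenance has been deferred, and maintenance is deferred where
disinvestment is concentrated. The package operationalizes this with three
auditor attributes available for essentially every taxed parcel:

* **year built** — three tiers (pre-1940 / 1940–1959 / 1960–1978 scoring
  3/2/1) tracking the declining lead content and prevalence of paint over
  the century; post-1978 parcels are retained with score 0;
* **appraised value** — three tiers (< \$100k / \$100k–\$200k / > \$200k
  scoring 3/2/1) as a proxy for neighborhood disinvestment;
* **building grade** — the appraiser's ordinal construction-quality label,
  mapped to a multiplicative modifier (see below).

The final parcel score is `(age tier + value tier) × modifier(grade)`,
ranging from near 0 (a renovated A-grade home) to 7.8 (a pre-1940, cheap,
E−− dwelling under the default table). The model is deliberately a scoring
rule, not a fitted regression: no blood-lead outcome data were available to
estimate weights, so the tiers encode prior knowledge and the package keeps
every threshold overridable.

### Boundary conventions

The tier prose ("before 1940", "after 1940 but before 1960", "after 1960")
leaves the years 1940 and 1960 ambiguous. The package uses half-open bins
`[<1940)`, `[1940, 1960)`, `[1960, 1978]`, which is the only resolution
consistent with the worked examples (a 1961 build scoring 1, a 1955 build
scoring 2). Year 1978 itself is scored — only parcels built *after* 1978
are excluded. On the value axis, both \$100,000 and \$200,000 fall in the
moderate tier, matching the printed inclusive range. `tier_rules()`
exposes all five constants.

### The grade modifier table

Nine modifiers are anchored exactly by the worked examples, as the ratio of
the final to the cumulative score per row: B 0.1, B− 0.2, C++ 0.3, C 0.5,
C− 0.6, C−− 0.7, D+ 0.9, D 1.0 and A− 0.025. The remaining grades are not
documented in the available source material, so the default table completes
them monotonically — A++ 0.01, A+ 0.015, A 0.02, B+ 0.05, C+ 0.4, and E
grades stepped upward from 1.1 — keeping the whole table strictly
non-increasing in grade quality. The completion is explicit, validated
(`grade_modifier_table()` rejects non-monotone tables) and swappable; a
grade missing from the table is a lookup *error*, never a silent default.
The alternative reading that C should be "normalized to 0" contradicts the
anchored C ratio of 0.5 and was not adopted.

## Aggregation and classification

An area's score is the parcel-count-weighted mean including post-1978
zeros: `sum(final_score) / n_parcels`. This makes county-wide score totals
conserved across aggregation levels (a tested invariant) and means a
neighborhood's score reflects its whole residential fabric, not just its
old houses.

The published category ranges contain two defects the package resolves
once: the Moderate range is printed as "1.00–2.99" in one table but
"1.000–1.999" in the next (a typo; Moderate = [1, 2) is used), and the
printed ranges leave (0, 0.01) unassigned. The implemented partition is
exact and total: {0} → Very Low, (0, 1) → Low, [1, 2) → Moderate,
[2, 3) → High, [3, ∞) → Very High, verified by a dense sweep test. "No
Data" is reserved for units that have resident children but no
auditor-classified residential parcels (large apartment complexes,
dormitories); parcel-less, child-less units are dropped.

Childcare centers use the same partition with the top label "Highest", over
the parcels within a **closed** half-mile Euclidean disc in the projected
mile-unit plane (the boundary rule and projection are not documented in the
source; a closed disc is the conventional choice and is pinned by a test at
exactly 0.5 mi). Centers with an empty buffer are flagged No Data rather
than erroring, mirroring the area convention.

## Equity analyses

* `exposure_table()` cross-tabulates under-5 and under-18 counts against
  the risk category of their geography, with the combined High + Very High
  share as the headline figure. Shares are exact ratios of the count
  columns; No Data units are tallied separately.
* `race_risk_distribution()` uses the tract-level race decomposition (race
  counts exist only at tract level in the source surveys) for per-race
  category shares, each race's high-risk share, and each race's share of
  all high-risk children.
* "Non-white" is defined as `under5_total − white`; the source does not
  state its construction, and this is the simplest one consistent with a
  five-category race table (White, Black, Asian, Hispanic, Other).
* `nonwhite_crosstab()` bands tracts by non-white share within risk
  strata. The default bands (≤10%, 10–50%, >50%, >75%) nest — >75% is a
  subset of >50% — and the nesting is declared in an output attribute
  rather than resolved away, because the source reports both bands.
* `opportunity_association()` is simple OLS of each tract-level opportunity
  index on the tract mean risk score, reporting slope, intercept and R².
  R² is computed as the squared Pearson correlation (identical to the OLS
  R² with an intercept, and stable for noiseless inputs). No multivariable
  adjustment is attempted: the analysis mirrors a scatter-plot comparison,
  not a causal model.
* The package's own summary of the risk–race gradient is a Spearman rank
  correlation between tract score and non-white share
  (`nonwhite_association()`): monotone, outlier-robust, and the natural
  target for the permutation-null test in the suite.

## The synthetic county

Real auditor and survey extracts are not redistributable, so the package
generates a county with the structure the analysis assumes
(`synthetic_config()` / `simulate_county()`):

* **Geometry.** A rows × cols grid of 1-mile-square census blocks, pooled
  row-major into block groups and tracts (defaults 20 × 20, 4 blocks per
  group, 2 groups per tract: 400/100/50 units). Square planar geographies
  are sufficient for every operation the method defines — mean aggregation
  and half-mile buffers — and remove any shapefile/projection dependency
  from the tests.
* **Disinvestment gradient.** A radial field `1 − exp(−d / center_decay)`
  (default decay 5 miles) shifts mean year built (≈1915 at the center to
  ≈1970 at the edge, SD 15 years, clamped to [1850, 1978]) and the value
  distribution's log-mean (±0.45 around `log(140000)`, log-SD 0.7, which
  puts roughly a third of pre-ban parcels in each value tier). Setting
  `center_decay = Inf` switches the gradient off exactly.
* **Exclusion share.** The post-1978 probability is logistic in the
  standardized gradient with its intercept solved numerically so the
  *marginal* share equals `frac_post1978` (default 0.474, the share in the
  county that motivated the method) while newer stock still concentrates
  outward.
* **Grades.** Drawn conditional on value tier from a 3 × 17 probability
  matrix (cheap → C−/D/E-heavy, expensive → A/B-heavy), encoding the link
  between disinvestment and disrepair. The matrix is a config field.
* **Children.** Block-group under-5 counts are Poisson with mean
  proportional to housing stock; under-18 counts add an independent
  Poisson excess so `under5 ≤ under18` by construction; tract totals are
  sums over member block groups. The tract non-white share is logistic in
  standardized tract housing age with slope `race_gradient` (default 1.5
  on the log-odds; 0 decouples race from risk), and race counts are one
  multinomial draw per tract, so they sum exactly to the tract total.
* **Childcare.** 250 centers with the program-type mix of a real county
  registry (licensed centers modal), placed preferentially toward the
  center.
* **Opportunity indices.** Each index is a negative linear function of
  tract risk plus Gaussian noise whose SD is calibrated in closed form,
  `sd = sqrt(var(signal) (1 − R²) / R²)`, to hit a target regression R²
  (defaults 0.62 and 0.53, the associations the generator emulates). An
  explicit `opp_index_noise_sd` overrides the calibration; 0 gives an
  exact line.
* **Seeding.** One integer seed fans out to fixed per-generator substreams
  (`seed + k·1000003 mod 2³¹−1`), so adding a generator never perturbs
  earlier draws and every run is bit-for-bit reproducible.

What the generator does *not* emulate: street networks and address
geocoding, realistic parcel densities, irregular census geography,
multiracial/group-quarters detail, within-tract race segregation, and any
spatial autocorrelation beyond the single radial gradient. Passing tests
on synthetic data therefore demonstrate that the pipeline's arithmetic,
accounting and statistical machinery are correct under the assumed
structure — not that the scoring rule predicts blood-lead outcomes, which
would require validation data no one has published for this method.

## Numerical choices and degenerate inputs

* Malformed parcel rows (unparseable year, negative value, missing grade)
  go to a rejects report with row numbers; valid + rejected always equals
  input. Currency strings ("\$1,234") are tolerated on value columns.
* Zero-parcel buffers and zero-parcel-with-children units are No Data
  flags, not exceptions; empty inputs yield empty (all-zero) tables.
* The opportunity fit refuses fewer than 3 paired tracts and zero-variance
  scores rather than returning a degenerate R².
* Point-in-polygon (used only to verify the generator's containment
  invariant) is even-odd ray casting; edge-exact points are not relied on.
* Test problem sizes — 10,000-parcel oracles, a 200-tract × 50-seed
  calibration check, 100-shuffle permutation nulls — were chosen as the
  smallest sizes at which the Monte-Carlo tolerances (3 SDs, ±0.05 on mean
  R²) are comfortably discriminating; the full suite runs in well under a
  minute.

## Known limitations

The scoring rule inherits its source's limitations: paint is the only
exposure pathway modeled; large apartment communities are invisible to
auditor "residential" classifications (hence No Data units); grades are
appraiser judgments; and the method is unvalidated against child
blood-lead measurements. The equity analysis is descriptive — shares and
rank correlations — and supports targeting, not causal claims.
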