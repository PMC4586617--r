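---
title: "Probabilistic cumulative risk for dietary goitrogens: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic cumulative risk for dietary goitrogens: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goitrisk)
```

## The model

Perchlorate, nitrate and thiocyanate all suppress thyroid function the same
way — by competing with iodide at the sodium-iodide symporter — so their
intakes add on a common potency scale. `goitrisk` simulates the
inter-subject variability of that combined intake and asks the regulatory
question: what fraction of a population exceeds a Hazard Index of 1?

For one individual, one agent and one route (drinking water or food), the
average daily rate of intake is the product

\[ \mathrm{ADRI} = C \times EF , \]

where \(C\) is the concentration in the medium (µg/L for water, µg/kg for
food) and \(EF\) is the exposure factor — the intake of the medium per kg
of body mass per day (L/kg-day or kg/kg-day). Intake rate and body mass are
folded into one factor because they are correlated. Each agent's intake is
converted to perchlorate-equivalent (PEC) units by dividing by a potency
divisor, a toxicity-equivalence weighting with two published bases:

* serum-concentration basis — perchlorate : thiocyanate : nitrate potencies
  in the ratio 1 : 8.8 : 150 (divisors 1, 8.8, 150);
* serum-half-life-corrected ingested-mass basis — 1 : 0.5 : 240.

The six PEC components (3 agents × 2 routes) are summed per individual, and
with a single reference dose (RfD) for the shared mode of action the Hazard
Index is simply the composite PEC intake over the RfD:

\[ HI_i = \frac{\sum_{g,r} EF_{r,i}\, C_{g,r,i} / d_g}{\mathrm{RfD}} . \]

Three alternative RfDs are carried as constants (µg/kg-day PEC, without /
with half-life correction): a no-observed-effect-level approach A3
(13.5 / 22.9), an exposure-response approach with a 50% inhibition
threshold A4 (29.5 / 38.9), and the same curve with a 0–5% threshold A4b
(14.5 / 23.9).

## Distributions

Concentrations and exposure factors are lognormal — described by a
population median and a geometric standard deviation (GSD) — truncated
symmetrically in log space at ±`trunc` GSDs (default 3), because survey
data show no values beyond roughly three GSDs from the median. The
truncation is implemented by restricting the underlying standard normal to
\([-t, t]\) and renormalising; sampling is inverse-CDF on the restricted
range, so bounds hold for every draw with no rejection loop. Two degenerate
limits are first-class: a zero median (absent component — thiocyanate in
drinking water) and GSD 1 (point mass), which the arithmetic examples and
degenerate scenarios rely on.

Within an individual, the water EF draw is shared by all three agents (one
person drinks one amount of water), and likewise the food EF draw.
Concentration draws are independent across agents and routes, and are held
fixed across days within an individual — a deliberately health-protective
choice that over-disperses the composite distribution, since real diets
average food concentrations across sources over an exposure window.
Endogenous nitrate production is a deterministic multiplier: effective
nitrate intake is exogenous × (1 + `endo_nitrate_coeff`), with default
coefficient 0 because calibration absorbs any constant multiplier into the
nitrate medians.

## Monte Carlo procedure

`simulate_adri()` draws `n` individuals (default 50,000) for one age group
and basis, using child random streams derived deterministically per
(age group, component) so results are reproducible and independent of
evaluation order. The published production size of 50,000 draws comes from
a stability rule — doubling the sample until the 95th-percentile estimate
moves by less than 1% — implemented in `stability_n()`. Empirical
percentiles use the inclusive linear-interpolation definition
(`quantile(..., type = 7)`); the reporting grid is the nine percentiles
1, 5, 10, 30, 50, 70, 90, 95, 99.

Exceedance is the percentage of individuals with HI strictly above 1.
Attribution partitions the exceeders: each is assigned to the agent with
the largest summed (water + food) PEC contribution, so per-agent
percentages sum exactly to the total exceedance. The alternative "would
this agent alone push HI above 1" reading is available as
`rule = "single_agent"` for sensitivity exploration; it is not a partition
and does not reproduce the published sum property.

## Contribution to variance

`contribution_to_variance()` scores each of eight input factors — six raw
concentration streams and the two exposure factors — by the square of its
Spearman rank correlation with the composite intake, normalised to
percentages. This is the estimator used by the commercial Monte Carlo
tooling the published tables came from; it sums to 100 exactly before
rounding and gives structurally degenerate factors (zero spread) exactly 0.
A first-order moment estimator (component variance over total variance for
the additive part) is provided as a cross-check, not the default.

## The synthetic scenario generator

No raw survey inputs ship with the package, so `synthetic_scenario()`
emulates their structure: water concentrations around 1.5 µg/L
(perchlorate), 4 mg/L (nitrate) and zero (thiocyanate); a five-category
food basket collapsing to effective concentrations around 23 µg/kg,
42 mg/kg and 0.9 mg/kg for the three agents; age-group exposure factors
declining from 0.10 L/kg-day (1–3 months) to 0.016 L/kg-day (adults) for
water, and 0.09 to 0.024 kg/kg-day for food. Concentration GSDs default to
1.5, the measured spread of the goitrogen distributions; EF GSDs are
1.25–1.35. Every individual consumes the same basket composition — only
total food mass varies — because survey data do not resolve between-food
correlations within individuals. Seeded lognormal jitter (GSD 1.15) makes
each seed a distinct but structurally identical population. What the
generator does *not* emulate: between-category correlation, temporal
averaging of diets, regional mixture structure in water sources, and
measurement error — so green tests demonstrate the pipeline's correctness
on lognormal-product populations, not fidelity to any particular survey.

## Calibration

The published surfaces are composite: percentile rows of total PEC intake
per age group and basis, variance shares, and two route-share constants
(4% of mean perchlorate intake via water, 6% for nitrate, 0% for
thiocyanate). The component inputs behind them were never printed.
`calibrate()` inverts this: it recovers one food-route PEC median per
agent, the two EF GSDs and a shared food-concentration GSD by minimising a
weighted least-squares objective evaluated with common random numbers (one
fixed truncated-normal draw matrix reused across evaluations, making the
Monte Carlo objective deterministic and smooth), via Nelder-Mead from ten
jittered starts plus a coordinate-wise Brent polish.

Design choices that were genuinely open, and how they were settled:

* **Identifiability.** Percentile rows identify only the composite
  distribution. The route shares pin the water/food split within each
  agent analytically (a hard constraint on the mean split, using
  truncated-mean factors). The variance shares identify the split between
  exposure-factor and concentration spread and between agents; they enter
  the objective as a scale-free pattern (one common factor is fitted
  first), because some printed water-factor shares are unattainable under
  the printed route shares and would otherwise inflate every other share
  through renormalisation. A target with neither surface is refused.
* **Percentile weights.** Every downstream metric — exceedance at any of
  the six RfDs — is a functional of the body and upper tail, and the
  A3 construction places the RfD at the median of the child rows. The
  default weights are therefore 16 at the median, 6 at the 70th (where the
  adult rows' A3 RfD sits), 1 above, and 0.05 below the median. A uniform
  fit is one argument away, and demonstrably mis-centres the distribution.
* **Free food-concentration GSD.** The measured GSD of 1.5 belongs to the
  water distributions; food-category spreads come from unpublished survey
  fits. With everything pinned at 1.5 the printed body width (composite
  GSD ≈ 1.8) is unreachable. The shared food GSD is fitted in [1.2, 3.5];
  it lands near 1.7 for every published row.
* **EF GSD range.** Exposure-factor spreads are bounded to [1.05, 2.5]:
  per-body-mass intake distributions outside that range do not occur in
  exposure surveys, and unconstrained fits escape to degenerate solutions
  that caricature one tail of the target row.
* **Perchlorate prior.** The published surfaces disagree about perchlorate
  by an order of magnitude: the variance table implies a perchlorate food
  median near 2 µg/kg-day PEC, while the attribution table, the route-share
  text and the conclusions all require well under 1% of exceedance to be
  perchlorate-driven. A weak lognormal prior centres the perchlorate food
  median at the biomonitoring scale of U.S. perchlorate intake
  (0.15 µg/kg-day), which is consistent with the attribution surface; the
  resulting variance-share residuals (−3 to −5 points on the perchlorate
  factors) are reported, not hidden. Setting the prior weight to 0
  restores the variance-table reading.
* **Anchored normalisation.** After the shape fit, all component medians
  are rescaled by one common factor so that the A3 RfD sits at the
  population quantile the printed percentile row itself implies (monotone
  spline through the row; for rows whose median equals the RfD this is an
  exact median normalisation). The factor preserves shape, variance shares
  and route split, and pins the single quantity every exceedance surface
  pivots on. It uses only fitting inputs — the percentile row and the RfD
  constants; the exceedance and attribution tables remain held out for
  `verify_calibration()`.

Self-consistency: on targets generated from a known synthetic scenario the
calibration recovers component medians within 5% and reproduces the
percentile row within 1% (see the test suite), provided each component
carries an identifiable variance share — sub-percent shares sit below the
rank-correlation identifiability floor at any practical sample size.

## Numerical choices and degenerate inputs

Truncation default 3 GSDs everywhere, configurable per distribution.
Quantile type 7 throughout. Exceedance uses a strict inequality (ties have
probability zero for continuous inputs). Attribution ties break to the
first agent in roster order (probability zero). Calibration uses 8,000
common-random-number individuals, 10 starts, 300 Nelder-Mead iterations
per start and a 4× polish, then the anchored normalisation against a
200,000-draw set; these sizes were chosen so a full 12-cell calibration
runs in a few minutes on one core while keeping the median anchored well
inside the published rounding. Zero-median components propagate exactly
(no epsilon floors), and the scenario validator rejects GSDs below 1,
negative medians and basket shares not summing to 1, naming the offending
key.

## Known limitations

* The printed composite rows have a shape (wide body, both tails pinched
  at ≈ ±1.1× the adjacent percentile) that no sum of independent truncated
  lognormal products can reproduce exactly; residuals of +10–15% at the
  99th and +25–60% below the 10th percentile remain after fitting, and are
  reported per row. In particular the exceedance implied at the A4 serum
  RfD (29.5 µg/kg-day) by the printed 95th/99th percentiles is ≈ 2.9%, not
  the published 1.1% — the package reproduces the percentile-row-implied
  value.
* The two variance tables (with and without half-life correction) are not
  jointly consistent with any single divisor re-weighting, and the
  half-life percentile rows are a constant ×1.696 rescaling of the serum
  rows; each row is therefore calibrated per basis, and the joint
  two-basis mode documents the tension through its residuals.
* Attribution between nitrate and thiocyanate within an exceeding
  individual depends on spread assumptions the published tables only
  partially pin down; the perchlorate level rests on the documented prior.
* Inter-subject variability only: no uncertainty analysis is layered on
  top, no temporal correlation of concentrations, no bromide/chlorate.
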