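---
title: "Methods: replacing dairy nutrients by linear programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replacing dairy nutrients by linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairylp)
```

## The model

The question the package answers is: which combination of non-dairy food
categories can supply the protein and the ten shortfall nutrients (Ca,
choline, fibre, Fe, Mg, K, vitamins A, C, D and E) found in one USDA
cup-equivalent serving of the dairy group, at the least cost, the least
energy, or the least food weight?

This is a Stigler-type diet problem. With $x_i \ge 0$ the grams selected
from category $i$, $a_{ij}$ the amount of nutrient $j$ per gram of category
$i$, $b_j$ the per-serving dairy-reference amount of nutrient $j$, and
$c_i$ the objective coefficient (US\$/g for cost, kJ/g for energy, 1 for
weight):

$$\min_x \sum_i c_i x_i \quad \text{s.t.}\quad \sum_i a_{ij} x_i \ge b_j
\;\; (j = 1,\dots,11), \qquad 0 \le x_i \le u_i,$$

with $x_i = 0$ fixed for excluded categories and $u_i$ either infinite
("no constraints") or the survey-weighted 90th percentile of current
intake ("p90 caps"). The constraints are inequalities: where the solution
delivers *exactly* the target amount the nutrient is called *limiting* —
that is an outcome of the optimisation (a binding constraint), not an
equality imposed on it. Energy, sodium, added sugars and saturated fat are
deliberately unconstrained and only reported, matching standard
"nutrients to limit" reporting.

The analysis grid is 2 exclusion phases × 3 objectives × 2 cap modes.
Phase 1 excludes only the 15 dairy category codes (milk, yogurt, cheese,
cheese sandwiches); phase 2 additionally excludes 16 codes that are not
reasonable population-level substitutes — baby foods, infant formulas,
nutrition powders and beverages, and near-zero-energy beverages (coffee,
tap water, bottled water, diet drinks). Phase 1 exists largely to
demonstrate *why* phase 2 is needed: with water allowed, the cheapest and
least-energetic sources of Ca and Mg are litres of water.

## The dairy reference

The right-hand side $b$ is one cup-equivalent of the dairy composite
(53 % fat-free milk, 45 % low-fat cheese, 2 % yogurt by serving
fraction). `build_dairy_reference()` combines any three component profiles
linearly; `dairy_fixture()` ships a labelled stand-in because the real
per-serving target table is not publicly recoverable. Three composite
values *are* pinned down by published worked examples and the fixture
reproduces them exactly: energy 435 kJ, cost US\$0.41 and sodium 133 mg
per serving (the cheese component's energy, cost and sodium are derived in
code so the composite is exact; all other fields are plausible USDA-style
values and are documented as fixtures). Every analysis function accepts
any `dairy_reference`, so real targets can be substituted without touching
code.

## Units and conventions

* Nutrient profiles are stored per 100 g edible portion; the LP works per
  gram (÷100), avoiding mixed bases.
* Energy is carried in kJ; `kcal_to_kj()` converts at 4.184 kJ/kcal for
  display only.
* Vitamin D is in µg, vitamin A in µg RAE.
* Added sugars convert to teaspoons at 4.2 g/tsp (labelling convention).
* Beverage prices quoted per litre convert to per-100 g at density
  1 g/ml; this is documented per category and can be overridden.

## The solver and its independent anchor

No LP-solver package is assumed: the backend (`solve_lp()`) is a dense
two-phase primal simplex with Bland's anti-cycling rule, entirely adequate
for 11 constraint rows and ~150 columns. Its correctness anchor is
`brute_force_oracle()`, a genuinely independent method: it enumerates all
basic solutions (every choice of $n$ active constraints among nutrient
rows, lower bounds and caps), keeps the feasible ones, and returns the
best vertex. Since $x \ge 0$ makes the feasible region pointed, a nonempty
region has a vertex, so the oracle also decides feasibility; with the
nonnegative objectives used here the optimum is attained at a vertex. The
test suite requires solver/oracle agreement to 1e-6 relative on hundreds
of random small instances and on planted-optimum instances whose solution
is known by construction.

Numerical choices:

* Constraint rows are scaled by $b_j$ (when $b_j > 0$) so a single
  feasibility tolerance (default 1e-9) works across mg/µg/g units.
* A nutrient is *binding* when its target-scaled slack is ≤ 1e-6.
  Nutrients with a zero target (e.g. fibre in a dairy reference, which
  contains none) are never reported as binding: their constraint is
  vacuous, and reporting them would confuse "limiting nutrient" readings.
* Degenerate or multiple optima: any optimal vertex is accepted;
  planted test instances are constructed (via strictly positive duals and
  strict reduced-cost margins) to have unique optima.
* With all objective coefficients ≥ 0 and $x \ge 0$ the objective is
  bounded below, so the solver's "unbounded" status is unreachable for
  well-formed builds; it exists for defensive completeness and flags
  zero-cost columns.

## Survey-weighted caps

`weighted_quantile()` is the left-continuous inverse of the weighted
empirical distribution: the smallest observed value whose cumulative
normalised weight reaches $q$. No interpolation — a cap should be an
attainable, observed amount. Two open choices were fixed here and exposed
as options:

* **Consumers only (default).** The 90th percentile is computed among
  persons who consumed the category. The all-persons alternative would cap
  any category consumed by <90 % of people at 0 g, which contradicts the
  presence of infrequently eaten foods (nutrition bars, fish) in optimised
  combinations. `consumers_only = FALSE` restores the other reading.
* Caps are computed per category over the full intake table, before
  exclusions are applied; this is immaterial for non-excluded categories.

A category nobody consumed yields an explicit "no cap" marker (`NA`),
not a zero.

## Prices

`adjust_for_inflation()` multiplies a price by the ratio of mean CPI
levels of the target and base 2-year cycles; it is linear in price and
invariant to CPI rebasing. `estimate_component_costs()` decomposes mixed
dishes: observed dish costs are regressed on food-pattern component
amounts with a nonnegativity constraint (unit costs are physically
nonnegative and an empty dish should cost ~0), solved as a quadratic
programme via `quadprog`. Whether the historical regression used an
intercept or weights is not documented, so both are available behind
switches, defaulting to no intercept and equal weights.
`apply_price_overrides()` sets explicit prices such as bottled water at
US\$0.25/l (0.025 US\$/100 g).

## What the synthetic generator emulates — and what it does not

`generate_food_db()` draws ~150 categories from eight archetypes (staples,
fortified cereals, fish, leafy greens, juices, nutrition bars, water-like
beverages, milk-substitute-like beverages) with log-uniform nutrient
densities inside archetype ranges stored in an editable parameter file
(`inst/extdata/archetype_params.csv`). The ranges were fixed once, before
any acceptance measurement, at levels a food-composition table would make
plausible; in particular:

* water-like categories have near-zero energy (≤6 kJ/100 g), trace Ca/Mg
  and near-free cost (US\$0.0005–0.01 per 100 g, bracketing municipal tap
  water and bottled water) — making them, as in real price data, the
  cheapest Ca/Mg source, which is what drives the phase-1 water-dominated
  solutions;
* water-like categories are capped at the five real excludable beverage
  codes (7702, 7704, 7302, 7102, 7106) so phase-2 exclusions remove all
  of them, as in the real database;
* fortified cereals, fish, juices and milk substitutes carry vitamin D,
  so phase-2 solutions hinge on the same few vitamin D vehicles as real
  data.

`generate_intakes()` makes single-day recalls: per category a consumption
probability and a log-normal consumed amount (zero-inflated sparsity), and
log-normal survey weights (sd 0.5).

What the generator does **not** emulate: real NHANES marginals or
correlations, demographic structure, survey design (strata/PSU), nutrient
co-occurrence within foods, or the actual price distribution. A green test
on synthetic data therefore establishes that the *pipeline and its
mathematics* behave correctly (feasibility, monotonicity, homogeneity,
binding-nutrient identification), not that any specific published table
cell is reproduced — reproducing those cells requires the restricted
survey/price inputs, which is exactly why the acceptance contract is
property-based.

## Reporting

Per-serving results scale linearly to daily terms (`scale_to_servings()`)
at 1.8 servings (current average intake) or 3.0 (recommended, ages 9+);
the LP's homogeneity in $b$ makes this exact, which the tests verify at
1e-8 relative. Grams convert to approximate RACC servings by division and
rounding to one decimal. Ratios versus dairy are reported as plain ratios
and absolute excesses only: prose like "costs 3.5 times more" is
ambiguous (elsewhere "0.5 times more" clearly means a ratio of 1.5), so
rendering is left to the caller. `compare_to_reference()` implements the
Ca-matched profile comparison used to explain why milk substitutes are
never selected; it is invariant to rescaling of the input profile.

## Known limitations

* Single LP per scenario; no portion-size integrality, no multi-objective
  weighting, no subgroup analyses.
* No bioavailability adjustment (fortified/plant Ca and vitamin D count at
  face value).
* No survey-design variance estimation; strata/PSU columns are carried but
  unused.
* The dairy-reference fixture is a stand-in except for its three pinned
  values; conclusions about magnitudes on synthetic data are qualitative.
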