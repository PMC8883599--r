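# dairylp

Diet optimisation by linear programming: which combinations of non-dairy
food categories can replace the protein and ten shortfall nutrients
(Ca, choline, fibre, Fe, Mg, K, vitamins A, C, D, E) supplied by USDA
cup-equivalent servings of dairy — and what do they cost in dollars,
kilojoules and grams?

The package is aimed at nutrition and public-health researchers doing
dietary scenario modelling on WWEIA/NHANES-style inputs: a food-category
table (nutrients per 100 g, price per 100 g, RACC serving size), a
single-day intake table with survey weights, and a dairy-reference target.
Because the real survey and price databases are restricted, a first-class
synthetic-data generator emulates their statistical structure so the whole
pipeline is testable offline.

## The model

With `x_i >= 0` the grams selected from category `i`, the core problem is

```
min  sum_i c_i x_i
s.t. sum_i a_ij x_i >= b_j   for the 11 constrained nutrients j
     0 <= x_i <= u_i,        x_i = 0 for excluded categories
```

where `a_ij` is nutrient `j` per gram of category `i`, `b_j` the
per-cup-equivalent dairy amount, `c_i` US$/g (cost), kJ/g (energy) or 1
(weight), and `u_i` an optional survey-weighted 90th-percentile intake
cap. The full analysis is a 2 x 3 x 2 grid: exclusion phase (dairy only,
or dairy plus unreasonable substitutes such as baby foods and tap/bottled
water) x objective x cap mode. Nutrients whose constraints bind at the
optimum are the *limiting nutrients*. The LP backend is a built-in
two-phase simplex, cross-checked against an independent brute-force
vertex-enumeration oracle.

## Worked example

```r
library(dairylp)
fx <- dairy_fixture()          # dairy composite: 435 kJ, US$0.41, 153.7 g/serving
foods   <- generate_food_db(150, seed = 42)
intakes <- generate_intakes(foods, n_persons = 500, seed = 43)

res <- run_scenario(foods, intakes, fx$reference,
                    scenario_spec(2, "weight", "p90"))
print(res)
#> <lp_result> status=optimal, objective (weight) = 67.06
#> totals: 0.944 US$, 883.8 kJ, 67.1 g; binding: protein, calcium, choline
#> selected grams:
#>  2818  2224  5514
#> 34.62 21.38 11.06
```

Minimising food weight in phase 2 (dairy and unreasonable substitutes
excluded, amounts capped at the 90th percentile of current intake), the
optimiser replaces one cup-equivalent of dairy with 34.6 g of a fortified
cereal, 21.4 g of a fish category and 11.1 g of a nutrition bar — 67 g of
food in total, less than half the weight of the dairy serving, but at
about twice the cost and energy. Protein, calcium and choline are supplied
at exactly the dairy amounts (the binding, i.e. limiting, nutrients);
everything else is oversupplied.

```r
round(ratios_vs_reference(res, fx$reference)$ratios, 2)
#>   cost energy weight
#>   2.30   2.03   0.44

scale_to_servings(res, 1.8, racc_g = setNames(foods$racc_g, foods$code))
#> <scaled_report> s = 1.8: 1.70 US$/d, 1591 kJ/d, 121 g/d
```

The ratios say the combination costs 2.3 times the dairy serving and
carries twice its energy at 44 % of its weight; scaling by 1.8 (the
current average daily dairy intake) gives the daily cost, energy and
weight of replacing dairy entirely. `run_all()` executes the full
12-scenario grid and `grid_report()` tabulates it, including approximate
RACC servings per selected food.

## Layout

* `R/` — domain types and IO (`food_table`, `intake_table`,
  `dairy_reference`), price adjustment (`adjust_for_inflation`,
  `estimate_component_costs`, `apply_price_overrides`), survey statistics
  (`weighted_quantile`, `intake_p90`), the LP core (`build_lp`,
  `solve_lp`, `binding_nutrients`, `brute_force_oracle`), scenarios
  (`phase_exclusions`, `run_scenario`, `run_all`), reporting
  (`scale_to_servings`, `to_racc_servings`, `ratios_vs_reference`,
  `nutrients_to_limit_summary`, `compare_to_reference`, `grid_report`)
  and the synthetic generators (`generate_food_db`, `generate_intakes`,
  `planted_optimum_instance`, `dairy_fixture`).
* `inst/cli/dairylp.R` — command-line entry point (`synth foods`,
  `synth intakes`, `synth planted`, `run`).
* `vignettes/dairy-replacement-methods.Rmd` — the methods vignette:
  model, assumptions, numerical choices, what the synthetic world does and
  does not establish.
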