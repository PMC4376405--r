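# rutfoptim

Least-cost formulation and nutrient evaluation of ready-to-use
therapeutic foods (RUTFs) from local plant ingredients.

RUTFs treat malnutrition with an energy- and macronutrient-dense product
that needs no preparation. Producing them locally — from cereals,
legumes, oilseeds and roots instead of imported milk-based pastes —
requires choosing the blend of ingredients that meets hard nutrient
floors and ceilings at minimum ingredient cost. That is a linear
program over ingredient mass percentages $w_i$:

$$
\min_w \sum_i \frac{w_i}{100} c_i
\quad\text{s.t.}\quad
\sum_i w_i = 100,\quad
m_n \le \sum_i \frac{w_i}{100} a_{ni} \le M_n,\quad
l_i \le w_i \le u_i,
$$

with prices $c_i$ (USD/kg), per-100 g nutrient values $a_{ni}$, nutrient
density bounds $m_n, M_n$ (e.g. fat ≤ 20 g/100 g, energy ≥ 452
kcal/100 g) and ingredient inclusion bounds $l_i, u_i$ (e.g. sugar ≤
14%, a koji grain fixed at its level). The package is written for
public-health nutrition researchers and formulation engineers who need
the optimization, the downstream arithmetic (linear nutrient blending,
Atwater 4/9/4 energy, carbohydrate by difference, intake and
limiting-nutrient analysis, multi-year cost trends), and the means to
verify all of it.

It ships a complete Mali case study — twelve candidate ingredients,
market prices 2004–2009, daily requirements of pregnant women in the
third trimester, six peanut/cowpea/millet/koji products and their
predicted and measured composition — plus a synthetic-instance
generator with planted optima and a brute-force grid-enumeration oracle
that independently validates the simplex solver.

## Worked example

Evaluate product A (38.4% peanuts, 22.2% cowpeas, 18.4% millet, 14%
sugar, 7% rice koji) over the packaged ingredient profiles:

```r
library(rutfoptim)
set <- mali_ingredients()
blend_profile(rutf_formulations()[["A"]], set)
#> Nutrient profile (per 100 g, as-is basis)
#>   protein 17.6  fat 20.0  ash 2.24  fiber 7.27  carbohydrate 45.3 g
#>   energy 442 kcal  moisture 7.6 g
#>   amino acids (g): lys 0.77  leu 1.34  val 0.80  his 0.47  trp 0.19 ...
```

The blend sits at the 20 g fat cap with 17.6 g protein and 0.77 g
lysine per 100 g — the profile the formulation software was aiming for.
Cost the six products across the price series:

```r
build_cost_trend(rutf_formulations(), mali_prices(), 2004:2009)
#> Ingredient cost of formulations (USD/kg of product mass)
#>         A    B    C    D    E    F      average
#> 2004 0.33 0.34 0.34 0.33 0.33 0.33 0.33 ± 0.006
#> 2005 0.36 0.36 0.36 0.35 0.35 0.35 0.36 ± 0.005
#> 2006 0.38 0.38 0.38 0.37 0.37 0.37 0.37 ± 0.005
#> 2007 0.42 0.42 0.43 0.41 0.41 0.42 0.42 ± 0.006
#> 2008 0.46 0.46 0.47 0.45 0.46 0.46 0.46 ± 0.006
#> 2009 0.49 0.50 0.50 0.49 0.50 0.50 0.50 ± 0.003
#> change 2004-2009 (of printed yearly averages): 0.17 USD/kg
```

Ingredient costs rose from about $0.33 to $0.50 per kg over the six
years — still far below imported commercial RUTFs. How much product
must be eaten per day, and which nutrient drives it?

```r
req <- mali_requirements(lysine = "intake_figure")
intake_needed(req, measured_products()[["A"]]$actual)
#> Daily intake needed (g dry product) per requirement:
#>   lys              613.6
#>   energy           572.3
#>   met_cys          340.4
#>   protein          328.2
#>   ...
#> limiting nutrient: lys
```

Lysine demands the most product (613.6 g dry), so meeting it meets
everything else — it is the limiting nutrient, as expected for an
all-plant blend without milk powder. Fitting a fresh least-cost
formulation instead of evaluating a fixed one:

```r
pool <- set[set$name %in% unique(mali_prices()$ingredient), ]
fit <- least_cost(pool, prices_for_year(mali_prices(), pool$name, 2004),
                  mali_constraints("A"))
fit$status
#> [1] "infeasible"
```

returns a classed fit with `coef()` (optimal percentages), `summary()`
(constraint slack table with binding constraints) and `predict()` (the
blended profile). On the packaged approximate profiles the full
restriction set with the 452 kcal floor is infeasible — consistent with
the published predicted energies of ~441 kcal/100 g sitting below that
floor; see the vignette for why the package reports this rather than
papering over it.

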