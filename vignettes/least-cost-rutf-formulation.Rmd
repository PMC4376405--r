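---
title: "Least-cost RUTF formulation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-cost RUTF formulation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rutfoptim)
```

## The problem

Ready-to-use therapeutic foods (RUTFs) are energy- and macronutrient-dense
products used to treat malnutrition without preparation or refrigeration.
Producing them from local plant ingredients — cereals, legumes, oilseeds,
roots — rather than imported milk-based pastes can cut ingredient cost by
an order of magnitude, but the blend must still satisfy hard nutritional
floors and ceilings. Choosing the cheapest such blend is the classic
least-cost ration problem, and `rutfoptim` implements it end to end for
RUTF design: the linear program, the evaluation of fixed candidate
formulations, the intake arithmetic that identifies the limiting
nutrient, and multi-year ingredient-cost tracking.

The package ships a worked case study: a Mali ingredient pool (corn,
sorghum, peanuts, millet, fonio, cassava, cowpeas, rice, barley, yam,
sugar, sesame), market prices for 2004–2009, daily requirements for
pregnant women in their third trimester, six reference products
(A–C with rice koji at 7/14/21%, D–F with barley koji at 5/10/15%), and
their predicted and laboratory-measured composition on a dry basis.

## The optimization model

Decision variables are ingredient mass percentages $w_i \in [0, 100]$.
With ingredient prices $c_i$ (USD/kg) and per-100 g nutrient values
$a_{ni}$, the fitted model is

$$
\min_w \sum_i \frac{w_i}{100} c_i
\quad\text{s.t.}\quad
\sum_i w_i = 100,\qquad
m_n \le \sum_i \frac{w_i}{100} a_{ni} \le M_n,\qquad
l_i \le w_i \le u_i .
$$

Blending is linear throughout: a product's predicted nutrient density is
the percentage-weighted mean of its ingredients' densities. The case
study's restriction set is: total fat at most 20 g/100 g, energy at least
452 kcal/100 g, sugar at most 14% of mass, and the koji grain fixed at
its product level. Fixed koji levels are encoded as `min == max` bounds,
so the six products are six separate LP instances — no integer
programming is involved. Koji is modeled with the unfermented grain's
profile; its amylase activity matters for processing, not for the LP.

`least_cost()` is the single fitting function; it returns a classed fit
with `print()`, `summary()` (constraint-by-constraint slack table),
`coef()` (the optimal percentages), and `predict()` (the blended
nutrient profile). `formulate_series()` refits per year of a price
table.

### Solver and verification

The simplex method (`boot::simplex`) solves the LP at an internal
feasibility tolerance of 1e-9. The package never trusts the solver
blindly: every returned point is re-verified directly from the profiles
by `check_constraints()` at 1e-6, and constraints with slack below 1e-6
are reported as binding. Ties between equally cheap optima are resolved
by the simplex pivoting rule, deterministically for a fixed instance.
As an independent reference, `enumerate_oracle()` exhaustively scans the
0.1%-step simplex grid (limited to three free ingredients, which keeps
the scan under a second) and shares no code with the simplex path.

### From daily requirements to density bounds

Requirements arrive per day (e.g. 2615.2 kcal, 64 g protein, 3.26 g
lysine); the LP needs per-100 g minima. `requirement_to_density()`
offers two conversions, because formulation practice uses both and the
case study does not record which one its software applied:

* **energy scaling** (default): each requirement is multiplied by
  `reference_energy_density / energy_per_day`. At the 452 kcal/100 g
  floor, protein becomes $64 \times 452 / 2615.2 = 11.06$ g/100 g. A
  product meeting these minima meets every requirement whenever enough
  of it is eaten to meet the energy requirement.
* **scoring-pattern mode**: amino-acid minima are expressed as mg per g
  protein (the amino-acid scoring pattern convention, here the 1- to
  3-year-old pattern) and anchored at a supplied product protein
  density.

## What the case-study data can and cannot support

Three properties of the published tables shape the package's behavior;
all are declared in code rather than silently corrected:

* **The per-ingredient profiles behind the predictions were never
  published.** The packaged `mali_ingredient_profiles_approx.csv` is a
  clearly labeled reference approximation assembled from typical
  food-composition values for the raw commodities. Blending the six
  products over it lands close to the published predicted columns
  (product A: protein 17.6 vs 17.6, fat 20.0 vs 20.0, energy 442 vs
  441, lysine 0.77 vs 0.77), but every check that runs through these
  profiles is a tolerance band (±2 g/100 g macros, ±15 kcal energy,
  ±0.15 g amino acids), never an identity. For the same reason the fat
  cap audit of the fixed candidates allows a 0.25 band: under the
  approximation the barley products blend to 20.07–20.20 fat, while the
  published predictions put all six exactly at the binding 20.0.
* **Printed tables carry print-rounding and internal inconsistencies.**
  Product F's percentages sum to 100.10, so formulations may declare a
  sum slack (0.05 per printed component) instead of being renormalized.
  The predicted proximates of the barley products over-sum by up to
  1.33, and product F's predicted Phe + Tyr (1.60) disagrees with its
  printed components (0.95 + 0.62); profile constructors take explicit
  `proximate_tol` / `aa_sum_tol` declarations for such sources, and
  stored amino-acid sums take precedence over recomputation.
* **The published predicted energies (~441 kcal/100 g) sit below the
  stated 452 kcal/100 g floor.** The package therefore audits candidate
  formulations against the constraint set and reports violations — the
  energy floor is genuinely violated by all six blends — rather than
  asserting that the published instance is feasible. Solving the full
  Mali instance with the 452 floor over the approximate as-is profiles
  returns `infeasible`, which is the honest answer for that input, not
  a solver defect.

Two further published values need a word. Energy prediction: blending
ingredient energy values as reported reproduces the predicted ~441,
whereas applying the 4/9/4 Atwater factors to the blended macros gives
~460; the predictions are consistent with the former, so
`blend_profile()` blends energy and `atwater_energy()` remains a
separate, explicit pathway (it reproduces the *measured* energies, e.g.
457 from product A's measured macros). Lysine requirement: the source
material prints both 3.26 g/day (requirement table) and 3.62 g/day
(intake analysis). `mali_requirements()` defaults to the table's 3.26;
with it, product A's energy intake (572.3 g) slightly exceeds its
lysine intake (552.5 g). The published intake analysis evidently used
3.62 — with `lysine = "intake_figure"` lysine demands the largest
intake in all six products, which is how the package reproduces that
finding.

## Intake analysis

`intake_needed()` divides each daily requirement by the product's
measured density per unit dry weight: `grams = 100 * requirement /
density`. The limiting nutrient is the one demanding the most product;
by construction, eating that much supplies at least the requirement of
every other modeled nutrient, and `limiting_nutrient_ranking()` asserts
this transitivity on every call. Ties are broken alphabetically and
flagged. Wet-weight intake needs the product's moisture, which the case
study does not publish; it is computed only when the user supplies a
moisture value, and absent otherwise — never guessed.

## Cost trends

`formulation_cost()` prices 1 kg of formulation mass,
$\sum_i (w_i/100)\,c_i$; no moisture or yield correction is applied, a
choice validated by the cost table reproducing without one.
`build_cost_trend()` assembles the formulation × year matrix, the yearly
mean and sample (n−1) SD across formulations, and each formulation's
first-to-last change. Stored values are never rounded; display rounds to
two decimals (costs), three significant figures (energy), one decimal
(percentages), two decimals (amino acids). From the packaged prices the
six products cost 0.33–0.34 USD/kg in 2004 and 0.49–0.50 in 2009; the
headline change of the rounded yearly averages is 0.17 USD/kg. Four of
the 36 cells recompute 0.0051–0.0054 away from their printed values —
just past the half-unit print band — because the printed two-decimal
prices and one-decimal percentages are themselves rounded from the
unrounded series used upstream; the package reports what the printed
inputs imply.

## Synthetic instances and solver validation

`generate_pool()` draws ingredient profiles uniformly within
configurable ranges (defaults span common cereal/legume/oilseed/root
commodities), rescales proximates over 100, fills carbohydrate by
difference, and drifts prices multiplicatively per year. All randomness
uses R's Mersenne–Twister generator with inversion sampling, seeded
locally and restored afterwards, so a seed fully determines the output
and the caller's RNG stream is untouched. Uniform draws are a deliberate
simplification: real commodities have correlated amino-acid and
proximate structure that the generator does not emulate, so passing
synthetic tests demonstrates solver correctness, not nutritional realism.

`plant_optimum()` builds instances whose optimum is known by
construction: for a k-ingredient blend, k−1 designated nutrient minima
are placed exactly at the blend's values, and prices are synthesized
from strictly positive dual multipliers of those rows plus the mass
balance, so any feasible deviation strictly increases cost and the
optimum is the unique solution of a nonsingular linear system. Remaining
constrained nutrients get minima at the blended value minus a margin;
margin 0 would let extra rows bind and degrade the optimal face, so it
warns. For up to three free ingredients the construction is certified
against the enumeration oracle. Across 100 seeded three-ingredient
instances the simplex solver recovers the planted blend to well under
0.1 percentage points and agrees with the oracle to under 0.001 USD/kg;
`scripts/acceptance.R` recomputes these rates on every run (100
planted instances, oracle cross-check on 25 — sizes chosen to keep a
full run under ten seconds while estimating the recovery rate at the
percent level).

## Known limitations

* Nutrient losses during processing (notably Maillard lysine loss, which
  the measured tables show clearly) are outside the model: predictions
  are raw-ingredient blends.
* No micronutrient constraints; premix design is a separate problem.
* The enumeration oracle is exponential in free ingredients and
  deliberately capped at three.
* Cost covers ingredients only — no processing, packaging or transport.
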