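# Packaged Mali case study: ingredient prices 2004-2009, daily
# requirements for pregnant women in the third trimester, the six
# peanut/cowpea/millet/koji product formulations, and their predicted and
# laboratory-measured composition (dry basis).
#
# The ingredient nutrient profiles are a clearly labeled *reference
# approximation*: the case study fed standard food-composition entries
# for the raw, whole commodities into its formulation software but those
# per-ingredient values were not published, so the packaged CSV carries
# typical values for the same commodities. Downstream checks that depend
# on them are tolerance bands, not exact identities.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "rutfoptim")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Mali ingredient profiles (reference approximation)
#'
#' Per-100 g as-is profiles of the 12 candidate ingredients (corn,
#' sorghum, peanuts, millet, fonio, cassava, cowpeas, rice, barley, yam,
#' sugar, sesame). These approximate the standard food-composition
#' entries for the raw, whole commodities; the exact values used by the
#' original formulation software were not published, so treat
#' blend predictions over this set as approximate.
#'
#' @return An [ingredient_set()] of 12 ingredients.
#' @export
mali_ingredients <- function() {
  read_ingredient_set(fixture_path("mali_ingredient_profiles_approx.csv"))
}

#' Mali ingredient prices, 2004-2009
#'
#' USD/kg by ingredient and year. Sugar has a single surveyed price,
#' constant across years; the barley series is from neighbouring Algeria
#' (Mali prices were unavailable); sesame is unpriced and therefore
#' absent — computations that need it fail loudly.
#'
#' @return A [price_table()] with 11 priced ingredients x 6 years.
#' @export
mali_prices <- function() {
  read_price_table(fixture_path("mali_prices_2004_2009.csv"))
}

#' Daily nutrient requirements (pregnant women, third trimester)
#'
#' Energy 2615.2 kcal/day, protein 64 g, carbohydrate 65 g, fat 58.12 g,
#' and essential amino acids per the 1- to 3-year-old scoring pattern.
#'
#' Two lysine values circulate in the source material: 3.26 g/day in the
#' requirement table and 3.62 g/day in the intake analysis. The table
#' value is the default; pass `lysine = "intake_figure"` to reproduce the
#' intake/limiting-nutrient analysis, which used 3.62 g/day.
#'
#' @param lysine `"table"` (3.26 g/day) or `"intake_figure"` (3.62 g/day).
#' @return A [requirement_set()].
#' @export
mali_requirements <- function(lysine = c("table", "intake_figure")) {
  lysine <- match.arg(lysine)
  df <- utils::read.csv(fixture_path("mali_daily_requirements.csv"),
                        stringsAsFactors = FALSE)
  v <- stats::setNames(df$amount_per_day, df$nutrient)
  if (lysine == "intake_figure") v["lys"] <- 3.62
  aa <- v[setdiff(names(v), c("energy", "protein", "carbohydrate", "fat"))]
  requirement_set(energy_kcal_day = v[["energy"]],
                  protein_g_day = v[["protein"]],
                  carbohydrate_g_day = v[["carbohydrate"]],
                  fat_g_day = v[["fat"]],
                  amino_acids_g_day = aa)
}

#' The six RUTF product formulations
#'
#' Mass-percent compositions of products A-C (rice koji at 7/14/21%) and
#' D-F (barley koji at 5/10/15%), each with peanuts, cowpeas, millet and
#' sugar making up the balance. The percentages are as printed at one
#' decimal; the rounding can leave a sum slightly off 100 (product F sums
#' to 100.10), so each formulation declares a 0.25 sum slack — 0.05 per
#' printed component — instead of being renormalized.
#'
#' @return Named list of six validated [formulation()] objects.
#' @export
rutf_formulations <- function() {
  df <- utils::read.csv(fixture_path("rutf_formulations.csv"),
                        stringsAsFactors = FALSE)
  out <- lapply(split(df, df$formulation), function(d)
    validate_formulation(formulation(
      stats::setNames(d$percentage, d$ingredient), name = d$formulation[1],
      sum_tol = 0.05 * nrow(d))))
  out[order(names(out))]
}

#' Predicted and measured composition of the six products
#'
#' Long table of software-predicted values, laboratory-measured values
#' (dry basis) and the published difference (actual - predicted, computed
#' upstream from unrounded data), for macronutrients/energy and amino
#' acids.
#'
#' @param table `"macros"`, `"amino_acids"` or `"all"`.
#' @return Data frame with columns
#'   `nutrient, product, predicted, actual, published_difference`.
#' @export
rutf_measured <- function(table = c("all", "macros", "amino_acids")) {
  table <- match.arg(table)
  m <- utils::read.csv(fixture_path("rutf_measured_macros.csv"),
                       stringsAsFactors = FALSE)
  a <- utils::read.csv(fixture_path("rutf_measured_amino_acids.csv"),
                       stringsAsFactors = FALSE)
  switch(table, macros = m, amino_acids = a, all = rbind(m, a))
}

# assemble a dry-basis profile from one product's column of the measured
# tables; `which` selects the predicted or actual values. The published
# predicted proximates of the barley products over-sum by up to 1.33
# (their carbohydrate was not recomputed by difference from the printed
# components), so predicted profiles declare that slack.
product_profile <- function(product, which = c("actual", "predicted")) {
  which <- match.arg(which)
  df <- rutf_measured("all")
  df <- df[df$product == product, ]
  v <- stats::setNames(df[[which]], df$nutrient)
  aa <- v[intersect(AA_KEYS, names(v))]
  p <- nutrient_profile(
    protein = v[["protein"]], fat = v[["fat"]], ash = v[["ash"]],
    fiber = v[["fiber"]], carbohydrate = v[["carbohydrate"]],
    energy = v[["energy"]], moisture = 0, amino_acids = aa,
    met_cys = v[["met_cys"]], phe_tyr = v[["phe_tyr"]], basis = "dry",
    proximate_tol = if (which == "predicted") 1.5 else PROXIMATE_TOL,
    # product F's predicted Phe+Tyr prints 1.60 against components
    # 0.95 + 0.62 = 1.57 (Tyr is a likely 0.65 misprint)
    aa_sum_tol = if (which == "predicted") 0.035 else 0.015)
  attr(p, "product") <- product
  p
}

#' Measured products as comparison-ready objects
#'
#' One [measured_product()] per formulation A-F, pairing the predicted
#' with the measured dry-basis profile and carrying the published
#' differences for the rounding cross-check in
#' [compare_predicted_actual()].
#'
#' @return Named list of six [measured_product()] objects.
#' @export
measured_products <- function() {
  df <- rutf_measured("all")
  prods <- sort(unique(df$product))
  out <- lapply(prods, function(p) {
    d <- df[df$product == p, ]
    measured_product(
      formulation_name = p,
      predicted = product_profile(p, "predicted"),
      actual = product_profile(p, "actual"),
      reference_difference = stats::setNames(d$published_difference,
                                             d$nutrient))
  })
  stats::setNames(out, prods)
}

#' Constraint set used to formulate the Mali products
#'
#' The published restriction set: total fat at most 20 g/100 g, energy at
#' least 452 kcal/100 g, sugar at most 14% of mass, and the koji grain
#' fixed at its product level (rice 7/14/21% for products A-C, barley
#' 5/10/15% for D-F) with the other grain excluded. Amino-acid minima are
#' derived from the daily requirements via [requirement_to_density()]
#' (energy scaling at the 452 kcal/100 g floor by default), or omitted
#' with `amino_acid_minima = "none"`.
#'
#' @param product One of `"A"` ... `"F"`, selecting the koji level.
#' @param amino_acid_minima `"energy"`, `"protein_pattern"` or `"none"`.
#' @param requirements A [requirement_set()]; defaults to
#'   [mali_requirements()].
#' @return A [constraint_spec()].
#' @export
mali_constraints <- function(product = "A",
                             amino_acid_minima = c("energy",
                                                   "protein_pattern",
                                                   "none"),
                             requirements = mali_requirements()) {
  amino_acid_minima <- match.arg(amino_acid_minima)
  koji <- list(A = c("rice", 7), B = c("rice", 14), C = c("rice", 21),
               D = c("barley", 5), E = c("barley", 10),
               F = c("barley", 15))[[product]]
  if (is.null(koji)) stop("product must be one of A-F")
  grain <- koji[1]; level <- as.numeric(koji[2])
  other <- if (grain == "rice") "barley" else "rice"
  nb <- list(fat = c(min = NA, max = 20),
             energy = c(min = 452, max = NA))
  if (amino_acid_minima != "none") {
    mins <- requirement_to_density(requirements, 452,
                                   method = amino_acid_minima)
    aa <- names(requirements$amino_acids_g_day)
    for (n in aa) nb[[n]] <- c(min = unname(mins[n]), max = NA)
  }
  ib <- list(sugar = c(min = 0, max = 14))
  ib[[grain]] <- c(min = level, max = level)
  ib[[other]] <- c(min = 0, max = 0)
  constraint_spec(nutrient_bounds = nb, ingredient_bounds = ib)
}
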