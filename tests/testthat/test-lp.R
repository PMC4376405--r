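# Least-cost LP: construction, solving, verification, yearly series.

test_that("requirement-to-density conversion scales by energy", {
  req <- mali_requirements()
  mins <- requirement_to_density(req, 452)
  expect_equal(mins[["protein"]], 64 * 452 / 2615.2, tolerance = 1e-12)
  expect_equal(mins[["protein"]], 11.06, tolerance = 1e-3)
  # one 100 g serving supplying all daily energy: scale factor 1
  mins1 <- requirement_to_density(req, req$energy_kcal_day)
  expect_equal(mins1[["protein"]], req$protein_g_day)
  expect_equal(mins1[["lys"]], req$amino_acids_g_day[["lys"]])
  expect_error(requirement_to_density(req, 0), "> 0")
  # scoring-pattern mode anchors amino acids to a protein density
  pat <- requirement_to_density(req, 452, method = "protein_pattern",
                                protein_density = 17.6)
  expect_equal(pat[["lys"]], 3.26 / 64 * 17.6, tolerance = 1e-12)
  expect_equal(pat[["protein"]], mins[["protein"]])
})

test_that("LP construction exposes the published restriction rows", {
  set <- mali_ingredients()
  pt <- mali_prices()
  pool <- set[set$name %in% unique(pt$ingredient), ]
  class(pool) <- class(set)
  cs <- mali_constraints("A", amino_acid_minima = "none")
  prob <- build_lp(pool, prices_for_year(pt, pool$name, 2004), cs)
  expect_equal(prob$constraints$nutrient_bounds$fat[["max"]], 20)
  expect_equal(prob$constraints$nutrient_bounds$energy[["min"]], 452)
  expect_equal(unname(prob$upper["sugar"]), 14)
  expect_equal(unname(prob$lower["rice"]), 7)   # fixed koji level
  expect_equal(unname(prob$upper["rice"]), 7)
  expect_error(build_lp(pool, c(corn = 0.1), cs), "missing price")
})

test_that("structural counts for a bound-free two-ingredient LP", {
  set <- toy_set()[1:2, ]
  class(set) <- c("ingredient_set", "data.frame")
  prob <- build_lp(set, c(x = 1, y = 2), constraint_spec())
  expect_length(prob$objective, 2)
  expect_equal(nrow(prob$nutrient_coef), 0)
  expect_equal(unname(prob$lower), c(0, 0))
  expect_equal(unname(prob$upper), c(100, 100))
})

test_that("dominance: with no nutrient bounds the cheapest ingredient wins", {
  set <- toy_set()[1:2, ]
  class(set) <- c("ingredient_set", "data.frame")
  fit <- least_cost(set, c(x = 1, y = 2), constraint_spec())
  expect_equal(fit$status, "optimal")
  expect_equal(unname(coef(fit)), c(100, 0))
  expect_equal(fit$cost_usd_per_kg, 1.00)
})

test_that("impossible nutrient minima give status infeasible", {
  set <- toy_set()
  cs <- constraint_spec(nutrient_bounds =
                          list(protein = c(min = 25, max = NA)))
  fit <- least_cost(set, c(x = 1, y = 2, z = 3), cs)
  expect_equal(fit$status, "infeasible")
  expect_null(coef(fit))
})

test_that("single-ingredient degenerate input: 100% if feasible", {
  set <- toy_set()[1, ]
  class(set) <- c("ingredient_set", "data.frame")
  fit <- least_cost(set, c(x = 0.5), constraint_spec())
  expect_equal(unname(coef(fit)), 100)
  cs <- constraint_spec(nutrient_bounds =
                          list(protein = c(min = 15, max = NA)))
  expect_equal(least_cost(set, c(x = 0.5), cs)$status, "infeasible")
})

test_that("optimal solutions verify against the constraint spec", {
  set <- toy_set()
  cs <- constraint_spec(
    nutrient_bounds = list(protein = c(min = 14, max = NA),
                           lys = c(min = 0.6, max = NA),
                           fat = c(min = NA, max = 4)),
    ingredient_bounds = list(x = c(min = 0, max = 60)))
  fit <- least_cost(set, c(x = 0.2, y = 0.9, z = 0.3), cs)
  expect_equal(fit$status, "optimal")
  f <- validate_formulation(fit$formulation, set)
  chk <- check_constraints(f, cs, set)
  expect_true(all(chk$satisfied))
  # binding rows have (near) zero slack in the verification table
  expect_true(all(fit$binding_constraints %in% chk$constraint))
  expect_true(length(fit$binding_constraints) >= 1)
  # cost equals the objective at the solution
  expect_equal(fit$cost_usd_per_kg,
               sum(coef(fit) / 100 * c(x = 0.2, y = 0.9, z = 0.3)))
  # predicted profile of the fit satisfies the bounds directly
  prof <- predict(fit)
  expect_gte(prof$protein, 14 - 1e-6)
  expect_lte(prof$fat, 4 + 1e-6)
})

test_that("weak duality: optimum is at most any feasible grid point", {
  set.seed(21)
  for (s in 1:5) {
    blend <- random_grid_blend()
    prob <- plant_optimum(blend, margin = 1, seed = s, certify = FALSE)
    fit <- solve_lp(prob)
    expect_equal(fit$status, "optimal")
    # sample random feasible points by perturbing toward vertices
    w0 <- as.numeric(attr(prob, "planted"))
    nb <- prob$constraints$nutrient_bounds
    n_ok <- 0
    for (i in 1:200) {
      lam <- runif(3); lam <- lam / sum(lam)
      w <- 100 * lam
      d <- as.numeric(prob$nutrient_coef %*% (w / 100))
      feas <- all(vapply(seq_along(nb), function(j)
        is.na(nb[[j]]["min"]) || d[j] >= nb[[j]]["min"] - 1e-9, logical(1)))
      if (feas) {
        n_ok <- n_ok + 1
        expect_gte(sum(w / 100 * prob$prices),
                   fit$cost_usd_per_kg - 1e-9)
      }
    }
  }
})

test_that("scaling all prices by k scales cost by k, formulation unchanged", {
  set <- toy_set()
  cs <- constraint_spec(nutrient_bounds =
                          list(protein = c(min = 12, max = NA)))
  pr <- c(x = 0.31, y = 0.57, z = 0.22)
  f1 <- least_cost(set, pr, cs)
  for (k in c(0.5, 2, 17)) {
    fk <- least_cost(set, k * pr, cs)
    expect_equal(unname(coef(fk)), unname(coef(f1)), tolerance = 1e-9)
    expect_equal(fk$cost_usd_per_kg, k * f1$cost_usd_per_kg,
                 tolerance = 1e-12)
  }
})

test_that("yearly series: determinism and per-year independence", {
  set <- toy_set()
  pt <- price_table(data.frame(
    ingredient = rep(c("x", "y", "z"), each = 2),
    year = rep(1:2, 3),
    price_usd_per_kg = c(0.3, 0.3, 0.5, 0.5, 0.2, 0.2)))
  cs <- constraint_spec(nutrient_bounds =
                          list(protein = c(min = 12, max = NA)))
  ser <- formulate_series(set, pt, cs, 1:2)
  expect_s3_class(ser, "least_cost_series")
  # identical prices in both years -> identical solutions
  expect_equal(coef(ser[["1"]]), coef(ser[["2"]]))
  # single year equals a direct solve
  one <- formulate_series(set, pt, cs, 1)
  direct <- least_cost(set, prices_for_year(pt, set$name, 1), cs)
  expect_equal(coef(one[["1"]]), coef(direct))
  expect_equal(attr(ser, "drift")$cost_usd_per_kg[1],
               direct$cost_usd_per_kg)
})

test_that("doubling one price never increases that ingredient's share", {
  # three-ingredient instance checked against the enumeration oracle
  set <- toy_set()
  cs <- constraint_spec(nutrient_bounds =
                          list(protein = c(min = 13, max = NA)))
  pr <- c(x = 0.30, y = 0.40, z = 0.25)
  shares <- c(); oracle_shares <- c()
  for (mult in c(1, 2)) {
    p2 <- pr; p2["y"] <- pr["y"] * mult
    fit <- least_cost(set, p2, cs)
    shares <- c(shares, coef(fit)[["y"]])
    orc <- enumerate_oracle(build_lp(set, p2, cs), step = 0.5)
    oracle_shares <- c(oracle_shares, orc$formulation[["y"]])
    expect_equal(fit$cost_usd_per_kg, orc$cost, tolerance = 0.001)
  }
  expect_lte(shares[2], shares[1] + 1e-9)
  expect_lte(oracle_shares[2], oracle_shares[1] + 1e-9)
})

test_that("published candidate formulations satisfy sugar, koji and fat caps", {
  set <- mali_ingredients()
  forms <- rutf_formulations()
  for (p in names(forms)) {
    cs <- mali_constraints(p, amino_acid_minima = "none")
    chk <- check_constraints(forms[[p]], cs, set, tol = 1e-9)
    row <- function(id) chk[chk$constraint == id, ]
    # sugar cap and fixed koji levels depend only on the printed
    # percentages: exact
    expect_true(row("ingredient_max:sugar")$satisfied)
    koji <- chk[grepl("^ingredient_(min|max):(rice|barley)",
                      chk$constraint), ]
    expect_true(all(koji$satisfied), info = p)
    # the fat cap depends on the approximate packaged profiles, under
    # which the blends sit at 20.0-20.2; audited as a band around the cap
    expect_lte(row("nutrient_max:fat")$value, 20 + 0.25)
    # the 452 kcal/100 g floor is NOT met by the blends (the published
    # predicted energies sit near 441): report, don't assert feasibility
    expect_false(row("nutrient_min:energy")$satisfied)
  }
})
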