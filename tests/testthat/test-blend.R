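# Linear blending of ingredient profiles and the predicted-vs-actual
# comparison stage.

test_that("blending is the identity on single-ingredient formulations", {
  set <- toy_set()
  p <- blend_profile(formulation(c(x = 100)), set)
  px <- ingredient_profile(set, "x")
  for (n in c("protein", "fat", "ash", "fiber", "carbohydrate", "energy",
              "moisture", "lys"))
    expect_equal(nutrient_value(p, n), nutrient_value(px, n))
})

test_that("blending averages linearly", {
  set <- toy_set()
  p <- blend_profile(formulation(c(x = 50, y = 50)), set)
  expect_equal(p$protein, 15)         # midpoint of 10 and 20
  expect_equal(nutrient_value(p, "lys"), (0.3 + 1.2) / 2,
               tolerance = 1e-12)
  # convex combination of formulations = combination of blends
  f1 <- c(x = 70, y = 20, z = 10)
  f2 <- c(x = 10, y = 50, z = 40)
  for (lam in c(0.25, 0.5, 0.9)) {
    fmix <- formulation(lam * f1 + (1 - lam) * f2)
    pm <- blend_profile(fmix, set)
    p1 <- blend_profile(formulation(f1), set)
    p2 <- blend_profile(formulation(f2), set)
    for (n in c("protein", "fat", "energy", "lys"))
      expect_equal(nutrient_value(pm, n),
                   lam * nutrient_value(p1, n) +
                     (1 - lam) * nutrient_value(p2, n),
                   tolerance = 1e-9)
  }
})

test_that("shifting mass to a higher-protein ingredient never lowers protein", {
  set <- toy_set()  # y has more protein than z
  base <- c(x = 40, y = 20, z = 40)
  last <- blend_profile(formulation(base), set)$protein
  for (shift in seq(5, 40, by = 5)) {
    w <- base + c(0, shift, -shift)
    cur <- blend_profile(formulation(w), set)$protein
    expect_gte(cur, last - 1e-12)
    last <- cur
  }
})

test_that("mixed bases and partially missing amino acids are surfaced", {
  set <- as.data.frame(toy_set())
  set$basis[2] <- "dry"; set$moisture[2] <- 0
  set$carbohydrate[2] <- set$carbohydrate[2] + 12
  set <- ingredient_set(set)
  expect_error(blend_profile(formulation(c(x = 50, y = 50)), set),
               "mixed bases")
  set2 <- as.data.frame(toy_set())
  set2$lys[2] <- NA
  set2 <- ingredient_set(set2)
  expect_warning(p <- blend_profile(formulation(c(x = 50, y = 50)), set2),
                 "lys")
  expect_true(is.na(nutrient_value(p, "lys")))
  expect_false(is.na(nutrient_value(p, "leu")))
})

test_that("blends of the packaged formulations track the predicted columns", {
  # the packaged profiles approximate unpublished food-composition
  # entries, so these are tolerance bands, not identities
  set <- mali_ingredients()
  pred <- rutf_measured("all")
  for (p in c("A", "D")) {
    bl <- blend_profile(rutf_formulations()[[p]], set)
    ref <- stats::setNames(pred$predicted[pred$product == p],
                           pred$nutrient[pred$product == p])
    expect_equal(bl$protein, ref[["protein"]], tolerance = 2 / ref[["protein"]])
    expect_equal(bl$fat, ref[["fat"]], tolerance = 1.5 / ref[["fat"]])
    expect_equal(bl$energy, ref[["energy"]], tolerance = 15 / ref[["energy"]])
    expect_equal(nutrient_value(bl, "lys"), ref[["lys"]],
                 tolerance = 0.15 / ref[["lys"]])
  }
  # spec headline: formulation A protein near 17.6
  a <- blend_profile(rutf_formulations()[["A"]], set)
  expect_equal(a$protein, 17.6, tolerance = 0.02)
})

test_that("comparison rows difference printed values with a rounding flag", {
  cmp <- compare_predicted_actual(measured_products())
  expect_s3_class(cmp, "comparison_table")
  # difference column is actual - predicted throughout
  expect_equal(cmp$abs_difference, cmp$actual - cmp$predicted,
               tolerance = 1e-12)
  ea <- cmp[cmp$nutrient == "energy" & cmp$product == "A", ]
  expect_equal(ea$abs_difference, 16)
  # A lysine from printed cells: 0.59 - 0.77 = -0.18, within the 0.05
  # rounding band of the published -0.17, hence unflagged
  la <- cmp[cmp$nutrient == "lys" & cmp$product == "A", ]
  expect_equal(la$abs_difference, -0.18)
  expect_false(la$flag)
  # B energy: 459 - 441 = 18.0 vs published 17.5 -> flagged
  eb <- cmp[cmp$nutrient == "energy" & cmp$product == "B", ]
  expect_true(eb$flag)
})

test_that("comparison handles identical profiles and key mismatches", {
  p <- nutrient_profile(10, 5, 2, 3, amino_acids = c(lys = 0.5))
  same <- measured_product("P", p, p)
  cmp <- compare_predicted_actual(same)
  expect_true(all(cmp$abs_difference == 0))
  q <- nutrient_profile(10, 5, 2, 3, amino_acids = c(leu = 1.0))
  expect_error(compare_predicted_actual(measured_product("P", p, q)),
               "keys differ")
})
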