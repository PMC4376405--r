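# Synthetic instances: random ingredient pools and price series, LP
# instances with a planted (known) optimum, and a brute-force grid
# enumeration oracle for verifying the simplex solver.
#
# All randomness goes through R's Mersenne-Twister generator with the
# Inversion normal kind, seeded locally and restored afterwards, so a seed
# fully determines every output on every platform.

with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# realistic per-100 g ranges spanning common cereal/legume/oilseed/root
# commodities (as-is basis)
DEFAULT_NUTRIENT_RANGES <- list(
  protein = c(1, 28), fat = c(0.2, 50), ash = c(0.5, 4.5),
  fiber = c(1, 15), moisture = c(5, 15),
  lys = c(0.04, 1.6), leu = c(0.05, 1.9), val = c(0.03, 1.2),
  his = c(0.02, 0.8), trp = c(0.02, 0.4), thr = c(0.03, 0.9),
  ile = c(0.03, 1.0), met = c(0.01, 0.6), cys = c(0.02, 0.4),
  phe = c(0.03, 1.4), tyr = c(0.02, 1.1))

#' Specification for a synthetic ingredient pool
#'
#' @param n_ingredients Number of ingredients (>= 2).
#' @param nutrient_ranges Named list of `c(low, high)` per-100 g ranges;
#'   defaults span common cereal and legume commodities.
#' @param price_range `c(low, high)` first-year prices, USD/kg.
#' @param price_drift Fractional multiplicative price change per year.
#' @param years Number of years in the price series.
#' @param seed Integer seed; fully determines the generated pool.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ingredients = 12,
                           nutrient_ranges = DEFAULT_NUTRIENT_RANGES,
                           price_range = c(0.05, 1.2),
                           price_drift = 0.08, years = 6, seed = 1) {
  if (n_ingredients < 2) stop("n_ingredients must be >= 2")
  ranges <- utils::modifyList(DEFAULT_NUTRIENT_RANGES, nutrient_ranges)
  for (n in names(ranges))
    if (ranges[[n]][1] > ranges[[n]][2])
      stop("infeasible range for ", n, ": low > high")
  if (price_range[1] > price_range[2] || price_range[1] <= 0)
    stop("infeasible price range")
  structure(list(n_ingredients = n_ingredients, nutrient_ranges = ranges,
                 price_range = price_range, price_drift = price_drift,
                 years = as.integer(years), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic ingredient pool and price series
#'
#' Profiles are drawn uniformly within the spec ranges; when the drawn
#' proximate components exceed 100 they are rescaled proportionally, and
#' carbohydrate is then filled by difference. Energy is the Atwater value
#' of the drawn macros. Prices start uniform in `price_range` and drift
#' multiplicatively by `price_drift` per year. The same seed reproduces
#' the pool exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `ingredients` ([ingredient_set()]) and
#'   `prices` ([price_table()], years `1:years`).
#' @export
generate_pool <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$seed, {
    k <- spec$n_ingredients
    draw <- function(n) {
      r <- spec$nutrient_ranges[[n]]
      stats::runif(k, r[1], r[2])
    }
    protein <- draw("protein"); fat <- draw("fat"); ash <- draw("ash")
    fiber <- draw("fiber"); moisture <- draw("moisture")
    comp <- protein + fat + ash + fiber + moisture
    over <- comp > 100
    if (any(over)) {
      sc <- 100 / comp[over]
      protein[over] <- protein[over] * sc; fat[over] <- fat[over] * sc
      ash[over] <- ash[over] * sc; fiber[over] <- fiber[over] * sc
      moisture[over] <- moisture[over] * sc
    }
    carbohydrate <- pmax(100 - (protein + fat + ash + fiber + moisture), 0)
    aa <- lapply(AA_KEYS, draw)
    names(aa) <- AA_KEYS
    df <- data.frame(name = sprintf("ing%02d", seq_len(k)),
                     basis = "as_is", protein = protein, fat = fat,
                     ash = ash, fiber = fiber,
                     carbohydrate = carbohydrate,
                     energy = atwater_energy(protein, fat, carbohydrate),
                     moisture = moisture, aa, stringsAsFactors = FALSE)
    base <- stats::runif(k, spec$price_range[1], spec$price_range[2])
    prices <- do.call(rbind, lapply(seq_len(spec$years), function(y)
      data.frame(ingredient = df$name, year = y,
                 price_usd_per_kg = base * (1 + spec$price_drift)^(y - 1),
                 stringsAsFactors = FALSE)))
    list(ingredients = ingredient_set(df), prices = price_table(prices))
  })
}

#' Construct an LP instance whose optimum is a planted blend
#'
#' Builds profiles, prices and constraints such that `blend` is the unique
#' least-cost formulation. The first `k - 1` constrained nutrients are
#' "designated": their minima are set exactly at the blend's values so
#' that, together with the mass balance, they pin the optimum. Prices are
#' synthesized from strictly positive dual multipliers of those rows, so
#' any feasible deviation from the planted blend strictly increases cost.
#' Remaining constrained nutrients get minima at the blended value minus
#' `margin`, keeping them slack; `margin = 0` makes additional rows bind
#' and the optimal face may degenerate (a warning is issued and uniqueness
#' is not guaranteed).
#'
#' For three or fewer ingredients the construction is certified with
#' [enumerate_oracle()]: every grid point matching the optimal cost within
#' 1e-9 must lie within one grid step of the planted blend.
#'
#' @param blend A [formulation()] with all components > 0.
#' @param margin Per-100 g slack for non-designated nutrient minima
#'   (> 0 for a certified unique optimum).
#' @param seed Integer seed for the pool and dual multipliers.
#' @param certify Run the oracle certification (default when <= 3
#'   ingredients).
#' @return A [build_lp()] problem with attribute `planted` (the blend).
#' @export
plant_optimum <- function(blend, margin = 1, seed = 1,
                          certify = length(blend) <= 3) {
  blend <- validate_formulation(blend)
  if (any(as.numeric(blend) <= 0))
    stop("planted blend must have strictly positive components")
  k <- length(blend)
  if (margin < 0) stop("margin must be >= 0")
  if (margin == 0)
    warning("margin 0: additional binding rows may create a degenerate ",
            "optimal face; uniqueness is not guaranteed")
  designated <- c("protein", "lys", "fat", "leu")[seq_len(k - 1)]
  slackn <- c("thr", "ile")
  with_rng(seed, {
    for (attempt in 1:50) {
      pool <- generate_pool(synthetic_spec(
        n_ingredients = k, seed = stats::runif(1, 1, 2^30)))
      set <- pool$ingredients
      set$name <- names(blend)
      rownames(set) <- NULL
      M <- rbind(mass = rep(1, k))
      for (cn in designated)
        M <- rbind(M, vapply(seq_len(k), function(i) set[[cn]][i] / 100,
                             numeric(1)))
      rownames(M) <- c("mass", designated)
      if (abs(det(M)) < 1e-4) next   # near-singular: redraw the pool
      w <- as.numeric(blend)
      b <- as.numeric(M %*% w)       # blended values at the plant
      y <- c(0.002, stats::runif(k - 1, 0.5, 1.5))  # positive duals
      a <- as.numeric(t(M) %*% y)    # objective: cost per percent point
      prices <- stats::setNames(100 * a, names(blend))
      nb <- stats::setNames(
        lapply(seq_along(designated), function(j)
          c(min = b[j + 1] * 100 / 100, max = NA_real_)), designated)
      # non-designated slack rows at blended value minus margin
      for (cn in slackn) {
        bv <- sum(w / 100 * set[[cn]])
        nb[[cn]] <- c(min = max(bv - margin, 0), max = NA_real_)
      }
      cs <- constraint_spec(nutrient_bounds = nb)
      prob <- build_lp(set, prices, cs)
      attr(prob, "planted") <- blend
      if (certify) {
        orc <- enumerate_oracle(prob, step = 0.1)
        target <- sum(w / 100 * prices)
        ok <- orc$status == "optimal" &&
          orc$cost >= target - 1e-9 &&
          max(abs(orc$formulation[names(blend)] - w)) <= 0.1 + 1e-9
        if (!ok) next
      }
      return(prob)
    }
    stop("planting error: could not certify a unique optimum in 50 attempts")
  })
}

#' Brute-force grid enumeration oracle
#'
#' Exhaustively scans the simplex grid of formulations at a given step
#' (percent) and returns the cheapest feasible grid point. Ingredients
#' whose bounds fix them (`min == max`) are held fixed; at most three
#' ingredients may be free. Ties are broken by the first point in
#' lexicographic grid order. The oracle shares no code path with the
#' simplex solver and is the independent reference for [solve_lp()].
#'
#' @param problem A [build_lp()] problem.
#' @param step Grid resolution in percent; must divide 100.
#' @return List with `status` (`"optimal"`/`"infeasible"`), `formulation`
#'   (named percentages) and `cost` (USD/kg).
#' @export
enumerate_oracle <- function(problem, step = 0.1) {
  stopifnot(inherits(problem, "least_cost_problem"))
  if (abs(100 / step - round(100 / step)) > 1e-9)
    stop("step must divide 100")
  nm <- names(problem$prices)
  lo <- problem$lower; hi <- problem$upper
  fixed <- abs(hi - lo) < 1e-12
  free <- which(!fixed)
  if (length(free) > 3)
    stop("complexity error: more than 3 free ingredients (",
         length(free), ")")
  rem <- 100 - sum(lo[fixed])
  if (rem < -1e-9) return(list(status = "infeasible",
                               formulation = NULL, cost = NA_real_))
  nf <- length(free)
  grid <- if (nf == 0) {
    matrix(numeric(0), 1, 0)
  } else if (nf == 1) {
    matrix(rem, 1, 1)
  } else if (nf == 2) {
    v <- seq(0, rem, by = step)
    cbind(v, rem - v)
  } else {
    v <- seq(0, rem, by = step)
    n1 <- rep(v, times = vapply(v, function(a)
      length(seq(0, rem - a, by = step)), numeric(1)))
    n2 <- unlist(lapply(v, function(a) seq(0, rem - a, by = step)))
    cbind(n1, n2, rem - n1 - n2)
  }
  X <- matrix(rep(lo, each = nrow(grid)), nrow(grid), length(nm),
              dimnames = list(NULL, nm))
  if (nf) X[, free] <- grid
  keep <- rep(TRUE, nrow(X))
  for (j in seq_along(nm))
    keep <- keep & X[, j] >= lo[j] - 1e-9 & X[, j] <= hi[j] + 1e-9
  nb <- problem$constraints$nutrient_bounds
  for (cn in names(nb)) {
    d <- as.numeric(X %*% (problem$nutrient_coef[cn, ] / 100))
    if (!is.na(nb[[cn]]["min"])) keep <- keep & d >= nb[[cn]]["min"] - 1e-9
    if (!is.na(nb[[cn]]["max"])) keep <- keep & d <= nb[[cn]]["max"] + 1e-9
  }
  if (!any(keep))
    return(list(status = "infeasible", formulation = NULL, cost = NA_real_))
  Xf <- X[keep, , drop = FALSE]
  cost <- as.numeric(Xf %*% (problem$prices / 100))
  i <- which.min(cost)   # first minimum = lexicographic tie-break
  list(status = "optimal",
       formulation = stats::setNames(Xf[i, ], nm), cost = cost[i])
}
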