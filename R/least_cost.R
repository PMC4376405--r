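# Least-cost formulation: build the blending LP, solve it, and verify the
# solution independently of the solver.
#
# Decision variables are ingredient mass percentages w (0-100 scale).
#   minimize    sum_i (w_i / 100) * price_i            [USD per kg product]
#   subject to  sum_i w_i = 100                        [mass balance]
#               min_n <= sum_i (w_i / 100) * a_{n,i} <= max_n   [densities]
#               lo_i <= w_i <= hi_i                    [inclusion bounds]
# where a_{n,i} is nutrient n's per-100 g value in ingredient i.

SOLVER_EPS <- 1e-9     # internal simplex feasibility tolerance
VERIFY_TOL <- 1e-6     # external constraint verification tolerance

#' Build a least-cost formulation LP
#'
#' Assembles the linear program from an ingredient set, a named price
#' vector (USD/kg) and a [constraint_spec()].
#'
#' @param ingredients An [ingredient_set()] on a single common basis.
#' @param prices Named numeric vector, USD/kg, covering every ingredient.
#' @param constraints A [constraint_spec()].
#' @return Object of class `least_cost_problem` holding the objective and
#'   constraint matrices.
#' @export
build_lp <- function(ingredients, prices, constraints) {
  stopifnot(inherits(constraints, "constraint_spec"))
  if (length(unique(ingredients$basis)) > 1)
    stop("ingredient profiles must share a common basis")
  nm <- ingredients$name
  missing_price <- setdiff(nm, names(prices))
  if (length(missing_price))
    stop("missing price for ingredient(s): ",
         paste(missing_price, collapse = ", "))
  prices <- prices[nm]
  unknown <- setdiff(names(constraints$ingredient_bounds), nm)
  if (length(unknown))
    stop("ingredient bound(s) reference unknown ingredient(s): ",
         paste(unknown, collapse = ", "))

  n <- length(nm)
  # nutrient coefficient rows (per-100 g values over ingredients)
  nut <- names(constraints$nutrient_bounds)
  coef <- matrix(NA_real_, length(nut), n, dimnames = list(nut, nm))
  for (cn in nut) {
    vals <- vapply(nm, function(g)
      nutrient_value(ingredient_profile(ingredients, g), cn), numeric(1))
    if (anyNA(vals))
      stop(sprintf("constrained nutrient '%s' absent from profile(s): %s",
                   cn, paste(nm[is.na(vals)], collapse = ", ")))
    coef[cn, ] <- vals
  }

  lo <- stats::setNames(rep(0, n), nm)
  hi <- stats::setNames(rep(100, n), nm)
  for (g in names(constraints$ingredient_bounds)) {
    b <- constraints$ingredient_bounds[[g]]
    if (!is.na(b["min"])) lo[g] <- b["min"]
    if (!is.na(b["max"])) hi[g] <- b["max"]
  }

  structure(list(ingredients = ingredients, prices = prices,
                 constraints = constraints, objective = unname(prices) / 100,
                 nutrient_coef = coef, lower = lo, upper = hi),
            class = "least_cost_problem")
}

#' @export
print.least_cost_problem <- function(x, ...) {
  nb <- x$constraints$nutrient_bounds
  cat(sprintf("Least-cost LP: %d ingredient(s), %d nutrient bound row(s)\n",
              length(x$prices), sum(vapply(nb, function(v)
                sum(!is.na(v)), numeric(1)))))
  cat("  objective: minimize sum(pct/100 * price), prices USD/kg\n")
  invisible(x)
}

#' Solve a least-cost formulation LP
#'
#' Solves with the simplex method ([boot::simplex()]) and independently
#' re-verifies every constraint at tolerance `1e-6` before declaring the
#' solution optimal. Deterministic for a fixed problem: ties between
#' equally cheap optima are broken by the simplex pivoting rule, and the
#' chosen vertex is recorded in the solution.
#'
#' @param problem A [build_lp()] problem.
#' @return Object of class `least_cost_fit` with fields `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `formulation`,
#'   `cost_usd_per_kg` and `binding_constraints` (zero slack at `1e-6`).
#' @seealso [least_cost()] for the one-call interface.
#' @export
solve_lp <- function(problem) {
  stopifnot(inherits(problem, "least_cost_problem"))
  nm <- names(problem$prices)
  n <- length(nm)
  coef <- problem$nutrient_coef / 100   # density rows per unit percent
  nb <- problem$constraints$nutrient_bounds

  A1 <- NULL; b1 <- NULL; r1 <- character()  # <= rows
  A2 <- NULL; b2 <- NULL; r2 <- character()  # >= rows
  A3 <- matrix(1, 1, n); b3 <- 100; r3 <- "mass_balance"
  add <- function(A, b, r, row, rhs, lab) {
    list(A = rbind(A, row), b = c(b, rhs), r = c(r, lab))
  }
  for (cn in names(nb)) {
    if (!is.na(nb[[cn]]["max"])) {
      u <- add(A1, b1, r1, coef[cn, ], nb[[cn]]["max"],
               paste0("nutrient_max:", cn))
      A1 <- u$A; b1 <- u$b; r1 <- u$r
    }
    if (!is.na(nb[[cn]]["min"])) {
      u <- add(A2, b2, r2, coef[cn, ], nb[[cn]]["min"],
               paste0("nutrient_min:", cn))
      A2 <- u$A; b2 <- u$b; r2 <- u$r
    }
  }
  for (i in seq_len(n)) {
    lo <- problem$lower[i]; hi <- problem$upper[i]
    unit <- rep(0, n); unit[i] <- 1
    if (abs(hi - lo) < 1e-12) {
      # fixed inclusion level -> equality row (or plain x_i >= 0 when 0)
      if (lo > 0) {
        A3 <- rbind(A3, unit); b3 <- c(b3, lo)
        r3 <- c(r3, paste0("ingredient_fix:", nm[i]))
      } else {
        u <- add(A1, b1, r1, unit, 0, paste0("ingredient_max:", nm[i]))
        A1 <- u$A; b1 <- u$b; r1 <- u$r
      }
    } else {
      u <- add(A1, b1, r1, unit, hi, paste0("ingredient_max:", nm[i]))
      A1 <- u$A; b1 <- u$b; r1 <- u$r
      if (lo > 0) {
        u <- add(A2, b2, r2, unit, lo, paste0("ingredient_min:", nm[i]))
        A2 <- u$A; b2 <- u$b; r2 <- u$r
      }
    }
  }
  if (is.null(A1)) {  # boot::simplex requires at least one <= row
    A1 <- matrix(1, 1, n); b1 <- 100; r1 <- "mass_upper"
  }

  res <- tryCatch(
    boot::simplex(a = problem$objective, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = FALSE,
                  n.iter = 50 * (n + length(b1) + length(b2) + length(b3)),
                  eps = SOLVER_EPS),
    error = function(e) stop("solver failure: ", conditionMessage(e)))

  if (res$solved == -1)
    return(new_least_cost_fit("infeasible", problem))
  if (res$solved != 1)
    stop("solver failure: simplex did not converge (status ", res$solved, ")")

  w <- stats::setNames(as.numeric(res$soln[seq_len(n)]), nm)
  w[abs(w) < 1e-10] <- 0
  f <- formulation(w, name = "least_cost_optimum")
  chk <- check_constraints(f, problem$constraints, problem$ingredients,
                           tol = VERIFY_TOL)
  if (!all(chk$satisfied))
    stop("solver failure: returned point violates ",
         paste(chk$constraint[!chk$satisfied], collapse = ", "))
  cost <- sum(w / 100 * problem$prices)
  binding <- chk$constraint[chk$slack <= VERIFY_TOL]
  new_least_cost_fit("optimal", problem, formulation = f, cost = cost,
                     binding = binding, value = res$value)
}

new_least_cost_fit <- function(status, problem, formulation = NULL,
                               cost = NA_real_, binding = character(),
                               value = NA_real_) {
  structure(list(status = status, formulation = formulation,
                 cost_usd_per_kg = cost, binding_constraints = binding,
                 problem = problem, objective_value = value),
            class = "least_cost_fit")
}

#' Fit a least-cost formulation
#'
#' The one-call modelling interface: builds the LP with [build_lp()] and
#' solves it with [solve_lp()].
#'
#' @inheritParams build_lp
#' @return A `least_cost_fit`; see [solve_lp()].
#' @examples
#' set <- mali_ingredients()
#' pr <- prices_for_year(mali_prices(), set$name, 2004)
#' cs <- constraint_spec(
#'   nutrient_bounds = list(fat = c(min = NA, max = 20)),
#'   ingredient_bounds = list(sugar = c(min = 0, max = 14)))
#' fit <- least_cost(set, pr, cs)
#' coef(fit)
#' @export
least_cost <- function(ingredients, prices, constraints) {
  solve_lp(build_lp(ingredients, prices, constraints))
}

#' Verify a candidate formulation against a constraint specification
#'
#' Independent of the solver: recomputes every blended density and bound
#' directly from the profiles. Used both to certify LP solutions and to
#' audit fixed candidate formulations.
#'
#' @param f A [formulation()].
#' @param constraints A [constraint_spec()].
#' @param ingredients An [ingredient_set()].
#' @param tol Feasibility tolerance (default `1e-6`).
#' @return Data frame with columns
#'   `constraint, value, bound, slack, satisfied`.
#' @export
check_constraints <- function(f, constraints, ingredients, tol = VERIFY_TOL) {
  f <- validate_formulation(f, ingredients)
  w <- stats::setNames(rep(0, nrow(ingredients)), ingredients$name)
  w[names(f)] <- as.numeric(f)
  dens <- function(cn) {
    vals <- vapply(ingredients$name, function(g)
      nutrient_value(ingredient_profile(ingredients, g), cn), numeric(1))
    if (any(is.na(vals) & w > 0))
      stop(sprintf("nutrient '%s' absent from used ingredient(s): %s", cn,
                   paste(names(w)[is.na(vals) & w > 0], collapse = ", ")))
    vals[is.na(vals)] <- 0
    sum(w / 100 * vals)
  }
  rows <- list()
  for (cn in names(constraints$nutrient_bounds)) {
    b <- constraints$nutrient_bounds[[cn]]
    v <- dens(cn)
    if (!is.na(b["min"]))
      rows[[length(rows) + 1]] <- data.frame(
        constraint = paste0("nutrient_min:", cn), value = v,
        bound = unname(b["min"]), slack = v - b["min"])
    if (!is.na(b["max"]))
      rows[[length(rows) + 1]] <- data.frame(
        constraint = paste0("nutrient_max:", cn), value = v,
        bound = unname(b["max"]), slack = b["max"] - v)
  }
  for (g in names(constraints$ingredient_bounds)) {
    b <- constraints$ingredient_bounds[[g]]
    v <- unname(w[g])
    if (!is.na(b["min"]))
      rows[[length(rows) + 1]] <- data.frame(
        constraint = paste0("ingredient_min:", g), value = v,
        bound = unname(b["min"]), slack = v - b["min"])
    if (!is.na(b["max"]))
      rows[[length(rows) + 1]] <- data.frame(
        constraint = paste0("ingredient_max:", g), value = v,
        bound = unname(b["max"]), slack = b["max"] - v)
  }
  rows[[length(rows) + 1]] <- data.frame(
    constraint = "mass_balance", value = sum(w), bound = 100,
    slack = -abs(sum(w) - 100))
  out <- do.call(rbind, rows)
  out$satisfied <- out$slack >= -tol
  rownames(out) <- NULL
  out
}

#' @export
print.least_cost_fit <- function(x, ...) {
  cat("Least-cost formulation fit\n")
  cat("  status:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  ingredient cost: %.4f USD/kg\n", x$cost_usd_per_kg))
    w <- x$formulation
    used <- names(w)[w > 1e-9]
    for (g in used) cat(sprintf("  %-10s %6.2f %%\n", g, w[[g]]))
  }
  invisible(x)
}

#' @export
summary.least_cost_fit <- function(object, ...) {
  out <- list(status = object$status, cost = object$cost_usd_per_kg,
              formulation = object$formulation,
              constraints = if (object$status == "optimal")
                check_constraints(object$formulation,
                                  object$problem$constraints,
                                  object$problem$ingredients) else NULL,
              binding = object$binding_constraints)
  class(out) <- "summary.least_cost_fit"
  out
}

#' @export
print.summary.least_cost_fit <- function(x, ...) {
  cat("Least-cost formulation —", x$status, "\n")
  if (!is.null(x$constraints)) {
    cat(sprintf("cost %.4f USD/kg; binding: %s\n", x$cost,
                paste(x$binding, collapse = ", ")))
    df <- x$constraints
    df$value <- round(df$value, 4); df$slack <- round(df$slack, 4)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.least_cost_fit <- function(object, ...) {
  if (object$status != "optimal") return(NULL)
  stats::setNames(as.numeric(object$formulation),
                  names(object$formulation))
}

#' Predicted product profile of a fitted formulation
#'
#' Blends the optimal percentages over the problem's ingredient set (or a
#' replacement set supplied as `newdata`).
#'
#' @param object A `least_cost_fit`.
#' @param newdata Optional [ingredient_set()] to blend over instead.
#' @param ... Unused.
#' @return A [nutrient_profile()], or `NULL` when the fit is not optimal.
#' @export
predict.least_cost_fit <- function(object, newdata = NULL, ...) {
  if (object$status != "optimal") return(NULL)
  set <- if (is.null(newdata)) object$problem$ingredients else newdata
  blend_profile(object$formulation, set)
}

#' Solve the least-cost LP for each of several years
#'
#' One independent solve per year at that year's prices, plus a drift
#' summary of how the optimal percentages move across years.
#'
#' @param ingredients An [ingredient_set()].
#' @param price_table A [price_table()] covering all ingredients in all
#'   requested years.
#' @param constraints A [constraint_spec()].
#' @param years Integer vector of years.
#' @return Object of class `least_cost_series`: a list of fits (named by
#'   year) with a `drift` data frame attribute.
#' @export
formulate_series <- function(ingredients, price_table, constraints, years) {
  stopifnot(length(years) >= 1)
  fits <- lapply(years, function(y) {
    pr <- tryCatch(prices_for_year(price_table, ingredients$name, y),
                   error = function(e)
                     stop(sprintf("year %d: %s", as.integer(y),
                                  conditionMessage(e))))
    tryCatch(least_cost(ingredients, pr, constraints),
             error = function(e)
               stop(sprintf("year %d: %s", as.integer(y),
                            conditionMessage(e))))
  })
  names(fits) <- as.character(years)
  drift <- do.call(rbind, lapply(names(fits), function(y) {
    ft <- fits[[y]]
    if (ft$status != "optimal")
      return(data.frame(year = as.integer(y), status = ft$status,
                        cost_usd_per_kg = NA_real_,
                        t(stats::setNames(rep(NA_real_, nrow(ingredients)),
                                          ingredients$name)),
                        check.names = FALSE))
    w <- stats::setNames(rep(0, nrow(ingredients)), ingredients$name)
    w[names(ft$formulation)] <- as.numeric(ft$formulation)
    data.frame(year = as.integer(y), status = "optimal",
               cost_usd_per_kg = ft$cost_usd_per_kg, t(w),
               check.names = FALSE)
  }))
  structure(fits, drift = drift, class = "least_cost_series")
}

#' @export
print.least_cost_series <- function(x, ...) {
  cat("Least-cost formulation series\n")
  d <- attr(x, "drift")
  d$cost_usd_per_kg <- round(d$cost_usd_per_kg, 4)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, 2)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' @export
plot.least_cost_series <- function(x, ...) {
  d <- attr(x, "drift")
  graphics::plot(d$year, d$cost_usd_per_kg, type = "b", pch = 19,
                 xlab = "year", ylab = "optimal ingredient cost (USD/kg)",
                 main = "Least-cost formulation across years", ...)
  invisible(x)
}
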