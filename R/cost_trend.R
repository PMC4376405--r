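# Ingredient-cost trends: per-year cost of fixed formulations, yearly
# summaries across formulations, and first-to-last period change.

#' Ingredient cost of one formulation
#'
#' Cost of the ingredients in 1 kg of formulation mass:
#' `sum(pct_i / 100 * price_i)` in USD/kg.
#'
#' @param f A [formulation()].
#' @param prices Named numeric vector, USD/kg.
#' @return Cost in USD/kg.
#' @examples
#' pr <- prices_for_year(mali_prices(),
#'                       c("peanuts", "cowpeas", "millet", "sugar", "rice"),
#'                       2004)
#' formulation_cost(rutf_formulations()[["A"]], pr)  # 0.331
#' @export
formulation_cost <- function(f, prices) {
  f <- validate_formulation(f)
  used <- names(f)[f > 0]
  miss <- setdiff(used, names(prices))
  if (length(miss))
    stop("missing price for ingredient(s): ", paste(miss, collapse = ", "))
  sum(f[used] / 100 * prices[used])
}

#' Cost trend of fixed formulations across years
#'
#' Computes the full formulation-by-year ingredient-cost matrix, the
#' yearly mean and sample (n-1) standard deviation across formulations,
#' and the first-to-last-year change per formulation. Stored values are
#' never rounded; rounding happens only at print time.
#'
#' @param formulations Named list of [formulation()] objects.
#' @param price_table A [price_table()] covering every (ingredient, year).
#' @param years Integer vector of years.
#' @return Object of class `cost_trend_table`: list with `costs` (year x
#'   formulation matrix), `yearly_mean`, `yearly_sd` (NA when only one
#'   formulation) and `period_change` (per formulation, last - first).
#' @examples
#' ct <- build_cost_trend(rutf_formulations(), mali_prices(), 2004:2009)
#' print(ct)
#' @export
build_cost_trend <- function(formulations, price_table, years) {
  stopifnot(length(formulations) >= 1, length(years) >= 1)
  if (is.null(names(formulations)))
    names(formulations) <- vapply(formulations, attr, "", "name")
  years <- as.integer(years)
  costs <- matrix(NA_real_, length(years), length(formulations),
                  dimnames = list(years, names(formulations)))
  for (yi in seq_along(years)) {
    for (fi in seq_along(formulations)) {
      f <- formulations[[fi]]
      used <- names(f)[as.numeric(f) > 0]
      pr <- tryCatch(prices_for_year(price_table, used, years[yi]),
                     error = function(e) stop(conditionMessage(e)))
      costs[yi, fi] <- formulation_cost(f, pr)
    }
  }
  yearly_mean <- rowMeans(costs)
  yearly_sd <- if (ncol(costs) > 1) apply(costs, 1, stats::sd)
               else stats::setNames(rep(NA_real_, nrow(costs)),
                                    rownames(costs))
  period_change <- costs[nrow(costs), ] - costs[1, ]
  structure(list(costs = costs, yearly_mean = yearly_mean,
                 yearly_sd = yearly_sd, period_change = period_change,
                 years = years),
            class = "cost_trend_table")
}

#' @export
print.cost_trend_table <- function(x, digits = 2, ...) {
  cat("Ingredient cost of formulations (USD/kg of product mass)\n")
  df <- as.data.frame(round(x$costs, digits))
  df$average <- ifelse(
    is.na(x$yearly_sd),
    sprintf("%.*f", digits, x$yearly_mean),
    sprintf("%.*f ± %.3f", digits, x$yearly_mean, x$yearly_sd))
  print.data.frame(df)
  if (nrow(x$costs) > 1)
    cat(sprintf("change %s-%s (of printed yearly averages): %.2f USD/kg\n",
                min(x$years), max(x$years),
                round(x$yearly_mean[length(x$years)], digits) -
                  round(x$yearly_mean[1], digits)))
  invisible(x)
}

#' Write a cost trend table as CSV
#'
#' Years as rows, one column per formulation, and a final
#' `mean`/`sd` pair of columns.
#'
#' @param ct A [build_cost_trend()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_trend_csv <- function(ct, path) {
  df <- data.frame(year = rownames(ct$costs),
                   as.data.frame(ct$costs, check.names = FALSE),
                   mean = unname(ct$yearly_mean),
                   sd = unname(ct$yearly_sd), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
plot.cost_trend_table <- function(x, ...) {
  graphics::matplot(x$years, x$costs, type = "b", pch = 19, lty = 1,
                    xlab = "year", ylab = "ingredient cost (USD/kg)",
                    main = "Formulation ingredient-cost trend", ...)
  graphics::legend("topleft", legend = colnames(x$costs), col = seq_len(
    ncol(x$costs)), pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
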