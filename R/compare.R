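# Predicted-vs-actual comparison tables for formulated products.

#' Measured product
#'
#' Pairs a software-predicted profile with a laboratory-measured (dry
#' basis) profile for one formulation, optionally carrying the published
#' per-nutrient differences for cross-checking.
#'
#' @param formulation_name Identifier referencing a known formulation.
#' @param predicted,actual [nutrient_profile()] objects.
#' @param reference_difference Optional named numeric vector of published
#'   `actual - predicted` differences.
#' @return Object of class `measured_product`.
#' @export
measured_product <- function(formulation_name, predicted, actual,
                             reference_difference = NULL) {
  stopifnot(inherits(predicted, "nutrient_profile"),
            inherits(actual, "nutrient_profile"))
  structure(list(formulation_name = formulation_name,
                 predicted = predicted, actual = actual,
                 reference_difference = reference_difference),
            class = "measured_product")
}

# nutrients a profile actually carries, in report order
profile_nutrients <- function(p) {
  macro <- c("protein", "fat", "ash", "fiber", "carbohydrate", "energy")
  aa <- names(p$amino_acids)
  sums <- AA_SUM_KEYS[vapply(AA_SUM_KEYS, function(s)
    !is.na(nutrient_value(p, s)), logical(1))]
  c(macro, aa, sums)
}

#' Compare predicted with measured composition
#'
#' Builds one row per (nutrient, product) with the difference
#' `actual - predicted` computed from the supplied values. When a product
#' carries published differences (computed upstream from unrounded data),
#' a row is flagged whenever the recomputed difference disagrees with the
#' published one by more than 0.05 — the footprint of print rounding.
#'
#' @param products A list of [measured_product()] objects (a single one is
#'   accepted).
#' @return A data frame of class `comparison_table` with columns
#'   `nutrient, product, predicted, actual, abs_difference, flag`.
#' @examples
#' compare_predicted_actual(measured_products())
#' @export
compare_predicted_actual <- function(products) {
  if (inherits(products, "measured_product")) products <- list(products)
  stopifnot(length(products) > 0)
  rows <- lapply(products, function(mp) {
    np <- profile_nutrients(mp$predicted)
    na_ <- profile_nutrients(mp$actual)
    if (!setequal(np, na_))
      stop(sprintf(
        "product %s: nutrient keys differ between predicted and actual (%s)",
        mp$formulation_name,
        paste(union(setdiff(np, na_), setdiff(na_, np)), collapse = ", ")))
    pred <- vapply(np, function(n) nutrient_value(mp$predicted, n), numeric(1))
    act <- vapply(np, function(n) nutrient_value(mp$actual, n), numeric(1))
    diff <- act - pred
    flag <- rep(FALSE, length(np))
    if (!is.null(mp$reference_difference)) {
      ref <- mp$reference_difference[np]
      flag <- !is.na(ref) & abs(diff - ref) > 0.05
    }
    data.frame(nutrient = np, product = mp$formulation_name,
               predicted = unname(pred), actual = unname(act),
               abs_difference = unname(diff), flag = flag,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table as CSV
#' @param tab A `comparison_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  cat("Predicted vs measured composition (difference = actual - predicted)\n")
  df <- as.data.frame(x)
  df$predicted <- round(df$predicted, digits)
  df$actual <- round(df$actual, digits)
  df$abs_difference <- round(df$abs_difference, digits)
  print.data.frame(df, row.names = FALSE)
  if (any(x$flag))
    cat(sprintf("%d row(s) flagged: recomputed difference disagrees with the published value by > 0.05\n",
                sum(x$flag)))
  invisible(x)
}
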