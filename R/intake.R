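# Intake analysis: grams of product needed to meet each daily requirement,
# limiting-nutrient identification, and fold comparison against reference
# products.

#' Grams of product needed to meet each daily requirement
#'
#' For every nutrient the daily requirement is divided by the product's
#' density per unit dry weight: `grams_dry = 100 * requirement / density`.
#' The limiting nutrient is the one demanding the most product; meeting it
#' meets every other modeled requirement. Wet-weight grams are computed
#' only when a product moisture value is supplied
#' (`wet = dry / (1 - moisture/100)`) and are otherwise absent, never
#' guessed.
#'
#' @param req A [requirement_set()].
#' @param actual Dry-basis [nutrient_profile()] of the product as eaten
#'   (measured composition).
#' @param moisture_pct Optional product moisture, g/100 g wet product.
#' @return Object of class `intake_report` with fields `per_nutrient_grams`
#'   (dry), `per_nutrient_grams_wet` (or `NULL`), `limiting_nutrient` and
#'   `tie` (TRUE when the maximum is attained by several nutrients; ties
#'   are broken alphabetically).
#' @examples
#' prof <- measured_products()[["A"]]$actual
#' intake_needed(mali_requirements(lysine = "intake_figure"), prof)
#' @export
intake_needed <- function(req, actual, moisture_pct = NULL) {
  stopifnot(inherits(req, "requirement_set"),
            inherits(actual, "nutrient_profile"))
  if (actual$basis != "dry")
    stop("intake analysis requires a dry-basis product profile")
  target <- requirement_vector(req)
  dens <- vapply(names(target), function(n) nutrient_value(actual, n),
                 numeric(1))
  if (anyNA(dens))
    stop("requirement nutrient(s) absent from product profile: ",
         paste(names(dens)[is.na(dens)], collapse = ", "))
  zero <- dens == 0
  if (any(zero))
    stop("requirement cannot be met: zero density for ",
         paste(names(dens)[zero], collapse = ", "))
  grams <- 100 * target / dens
  ord <- order(-grams, names(grams))   # max first, alphabetical tie-break
  limiting <- names(grams)[ord[1]]
  tie <- sum(abs(grams - max(grams)) < 1e-12) > 1
  wet <- NULL
  if (!is.null(moisture_pct)) {
    if (moisture_pct < 0 || moisture_pct >= 100)
      stop("moisture_pct must be in [0, 100)")
    wet <- grams / (1 - moisture_pct / 100)
  }
  structure(list(product = attr(actual, "product"),
                 per_nutrient_grams = grams,
                 per_nutrient_grams_wet = wet,
                 limiting_nutrient = limiting, tie = tie,
                 requirements = target, densities = dens),
            class = "intake_report")
}

#' @export
print.intake_report <- function(x, ...) {
  cat("Daily intake needed (g dry product) per requirement:\n")
  g <- sort(x$per_nutrient_grams, decreasing = TRUE)
  for (n in names(g)) cat(sprintf("  %-13s %8.1f\n", n, g[[n]]))
  cat("limiting nutrient:", x$limiting_nutrient,
      if (isTRUE(x$tie)) "(tie, broken alphabetically)" else "", "\n")
  if (!is.null(x$per_nutrient_grams_wet))
    cat(sprintf("wet-weight intake for limiting nutrient: %.0f g\n",
                x$per_nutrient_grams_wet[[x$limiting_nutrient]]))
  invisible(x)
}

#' Rank nutrients by required intake across products
#'
#' For each report, nutrients are sorted by required grams (descending)
#' and the transitivity property is checked: consuming enough product to
#' meet the top-ranked (limiting) nutrient supplies at least the daily
#' requirement of every other nutrient.
#'
#' @param reports A named list of [intake_needed()] reports (names are
#'   product identifiers).
#' @return Data frame of class `limiting_rank_table` with columns
#'   `product, nutrient, grams, rank, limiting, tie`.
#' @export
limiting_nutrient_ranking <- function(reports) {
  stopifnot(length(reports) > 0)
  if (is.null(names(reports)))
    names(reports) <- paste0("product_", seq_along(reports))
  rows <- lapply(names(reports), function(p) {
    r <- reports[[p]]
    g <- r$per_nutrient_grams
    ord <- order(-g, names(g))
    g <- g[ord]
    # meeting the top grams supplies >= requirement of every nutrient
    supplied <- g[1] * r$densities[names(g)] / 100
    stopifnot(all(supplied >= r$requirements[names(g)] - 1e-9))
    data.frame(product = p, nutrient = names(g), grams = unname(g),
               rank = seq_along(g),
               limiting = names(g) == r$limiting_nutrient,
               tie = r$tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("limiting_rank_table", "data.frame")
  out
}

#' @export
print.limiting_rank_table <- function(x, ...) {
  cat("Required intake ranking (g dry product per daily requirement)\n")
  df <- as.data.frame(x); df$grams <- round(df$grams, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Fold comparison of two nutrient profiles
#'
#' For each nutrient, the fold `max(a, r) / min(a, r)` between a product
#' and a reference product (e.g. a commercial peanut-paste RUTF), with a
#' direction flag: `"more"` when the product exceeds the reference,
#' `"less"` when it falls short, `"equal"` at parity.
#'
#' @param actual,reference [nutrient_profile()] objects.
#' @param nutrients Nutrients to compare; defaults to energy, protein and
#'   fat.
#' @return Data frame with columns
#'   `nutrient, actual, reference, fold, direction`.
#' @examples
#' plumpy <- nutrient_profile(protein = 13.6, fat = 35.7, ash = 3,
#'                            fiber = 2, energy = 545, basis = "dry")
#' fold_comparison(measured_products()[["A"]]$actual, plumpy)
#' @export
fold_comparison <- function(actual, reference,
                            nutrients = c("energy", "protein", "fat")) {
  stopifnot(inherits(actual, "nutrient_profile"),
            inherits(reference, "nutrient_profile"))
  a <- vapply(nutrients, function(n) nutrient_value(actual, n), numeric(1))
  r <- vapply(nutrients, function(n) nutrient_value(reference, n), numeric(1))
  if (anyNA(a) || anyNA(r))
    stop("nutrient absent from one of the profiles")
  if (any(r <= 0))
    stop("reference density must be > 0 for: ",
         paste(nutrients[r <= 0], collapse = ", "))
  fold <- pmax(a, r) / pmin(a, r)
  direction <- ifelse(a > r, "more", ifelse(a < r, "less", "equal"))
  data.frame(nutrient = nutrients, actual = unname(a),
             reference = unname(r), fold = unname(fold),
             direction = unname(direction), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Serialize an intake report
#'
#' @param report An [intake_needed()] report.
#' @param path Output path (`.json` or `.csv` by extension).
#' @return `path`, invisibly.
#' @export
write_intake_report <- function(report, path) {
  df <- data.frame(nutrient = names(report$per_nutrient_grams),
                   grams_dry = unname(report$per_nutrient_grams),
                   grams_wet = if (is.null(report$per_nutrient_grams_wet))
                     NA_real_ else unname(report$per_nutrient_grams_wet),
                   limiting = names(report$per_nutrient_grams) ==
                     report$limiting_nutrient,
                   stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(limiting_nutrient = report$limiting_nutrient, tie = report$tie,
           per_nutrient = df), path, auto_unbox = TRUE, digits = NA,
      na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
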