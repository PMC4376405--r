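# Ingredient price tables: USD/kg by ingredient and year.

#' Price table
#'
#' Long data frame of ingredient prices with columns
#' `ingredient, year, price_usd_per_kg`. Cells that are not present are
#' absent: any computation needing one fails loudly rather than
#' interpolating.
#'
#' @param df Data frame with the three columns above.
#' @return The validated data frame with class `price_table`.
#' @export
price_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("ingredient", "year", "price_usd_per_kg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("price table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty price table")
  if (!is.numeric(df$price_usd_per_kg) || anyNA(df$price_usd_per_kg))
    stop("unparsable price value(s) in price table")
  if (any(df$price_usd_per_kg <= 0))
    stop("prices must be strictly positive")
  key <- paste(df$ingredient, df$year)
  if (anyDuplicated(key))
    stop("duplicate (ingredient, year) cell(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df$year <- as.integer(df$year)
  class(df) <- c("price_table", "data.frame")
  df
}

#' Read a price table from CSV
#'
#' Accepts either the long layout (`ingredient,year,price_usd_per_kg`) or a
#' wide layout with a `year` column followed by one column per ingredient;
#' empty cells in the wide layout are recorded as absent.
#'
#' @param path CSV path.
#' @return A [price_table()].
#' @export
read_price_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!nrow(df)) stop("empty price table: ", path)
  if (all(c("ingredient", "year", "price_usd_per_kg") %in% names(df)))
    return(price_table(df))
  if (!"year" %in% names(df))
    stop("price CSV must be long (ingredient,year,price_usd_per_kg) or wide with a 'year' column")
  ing <- setdiff(names(df), "year")
  long <- do.call(rbind, lapply(ing, function(g)
    data.frame(ingredient = g, year = df$year, price_usd_per_kg = df[[g]],
               stringsAsFactors = FALSE)))
  long <- long[!is.na(long$price_usd_per_kg), ]
  price_table(long)
}

#' Write a price table to long CSV
#' @param pt A [price_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_price_table <- function(pt, path) {
  utils::write.csv(as.data.frame(pt), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up one price
#'
#' @param pt A [price_table()].
#' @param ingredient Ingredient name.
#' @param year Integer year.
#' @return Price in USD/kg; absent cells raise an error.
#' @export
price_at <- function(pt, ingredient, year) {
  i <- which(pt$ingredient == ingredient & pt$year == year)
  if (!length(i))
    stop(sprintf("no price for (%s, %d)", ingredient, as.integer(year)))
  pt$price_usd_per_kg[i]
}

#' Named price vector for one year
#'
#' @param pt A [price_table()].
#' @param ingredients Character vector of names; every one must be priced.
#' @param year Integer year.
#' @return Named numeric vector, USD/kg.
#' @export
prices_for_year <- function(pt, ingredients, year) {
  v <- vapply(ingredients, function(g) price_at(pt, g, year), numeric(1))
  names(v) <- ingredients
  v
}

#' @export
print.price_table <- function(x, ...) {
  yrs <- sort(unique(x$year))
  cat(sprintf("Price table: %d ingredient(s), years %s-%s (USD/kg)\n",
              length(unique(x$ingredient)), min(yrs), max(yrs)))
  print(utils::head(as.data.frame(x), ...))
  invisible(x)
}
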