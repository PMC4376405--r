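# Ingredient sets: wide data frames of per-100 g profiles, one row per
# ingredient, with readers/writers for CSV and JSON mirrors.

REQUIRED_PROFILE_COLS <- c("name", "protein", "fat", "ash", "fiber",
                           "carbohydrate", "energy", "moisture")

#' Ingredient set
#'
#' A data frame with one row per ingredient: `name`, optional `notes` and
#' `basis` (default `"as_is"`), the proximate columns
#' `protein, fat, ash, fiber, carbohydrate, energy, moisture`, and optional
#' amino-acid columns (`lys` ... `tyr`, plus `met_cys`/`phe_tyr` sums).
#' Missing amino-acid cells are `NA` — absent, never zero.
#'
#' @param df A data frame with at least the required columns.
#' @return The validated data frame with class `ingredient_set`.
#' @export
ingredient_set <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_PROFILE_COLS, names(df))
  if (length(missing_cols))
    stop("ingredient table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate ingredient name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  if (!"basis" %in% names(df)) df$basis <- "as_is"
  if (!"notes" %in% names(df)) df$notes <- ""
  df$notes <- ifelse(is.na(df$notes), "", as.character(df$notes))
  num_cols <- intersect(c(setdiff(REQUIRED_PROFILE_COLS, "name"),
                          AA_KEYS, AA_SUM_KEYS), names(df))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v))
      stop("column ", cl, " is not numeric")
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      stop(sprintf("negative value in column '%s' at row %d", cl, bad[1]))
  }
  # full per-row validation through the profile constructor
  for (i in seq_len(nrow(df))) ingredient_profile(df, df$name[i])
  class(df) <- c("ingredient_set", "data.frame")
  df
}

#' Extract one ingredient's profile from a set
#'
#' @param set An [ingredient_set()].
#' @param name Ingredient name.
#' @return A [nutrient_profile()].
#' @export
ingredient_profile <- function(set, name) {
  stopifnot(is.data.frame(set))
  i <- match(name, set$name)
  if (is.na(i)) stop("unknown ingredient: ", name)
  row <- set[i, ]
  aa <- vapply(AA_KEYS, function(k)
    if (k %in% names(row)) row[[k]] else NA_real_, numeric(1))
  aa <- aa[!is.na(aa)]
  grab <- function(k) if (k %in% names(row) && !is.na(row[[k]])) row[[k]] else NULL
  nutrient_profile(
    protein = row$protein, fat = row$fat, ash = row$ash, fiber = row$fiber,
    carbohydrate = row$carbohydrate, energy = row$energy,
    moisture = row$moisture, amino_acids = aa,
    met_cys = grab("met_cys"), phe_tyr = grab("phe_tyr"),
    basis = if ("basis" %in% names(row)) row$basis else "as_is")
}

#' Read an ingredient set from CSV or JSON
#'
#' CSV is wide (one row per ingredient, UTF-8, header row); JSON is an
#' array of objects with the same snake_case field names. Optional
#' amino-acid fields that are missing are recorded as absent (`NA`),
#' not zero.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return An [ingredient_set()].
#' @export
read_ingredient_set <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    as.data.frame(recs, stringsAsFactors = FALSE)
  }
  if (!nrow(df)) stop("empty ingredient table: ", path)
  ingredient_set(df)
}

#' Write an ingredient set to CSV or JSON
#'
#' Round-trips with [read_ingredient_set()] field-for-field.
#'
#' @param set An [ingredient_set()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_ingredient_set <- function(set, path,
                                 format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- as.data.frame(set)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' @export
print.ingredient_set <- function(x, ...) {
  cat(sprintf("Ingredient set: %d ingredient(s) [%s basis]\n", nrow(x),
              paste(unique(x$basis), collapse = "/")))
  print.data.frame(x, ...)
  invisible(x)
}
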