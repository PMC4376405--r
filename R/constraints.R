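# Constraint specifications and daily-requirement handling for the
# least-cost formulation LP.

#' Constraint specification for one LP instance
#'
#' Per-nutrient density bounds (per 100 g of product) and per-ingredient
#' inclusion bounds (mass percent, `min == max` fixes a level), on top of
#' the implicit mass balance that percentages sum to 100.
#'
#' @param nutrient_bounds Named list; each element `c(min = , max = )`
#'   with `NA` for an absent side.
#' @param ingredient_bounds Named list of `c(min = , max = )` percentages.
#' @return Object of class `constraint_spec`.
#' @examples
#' constraint_spec(
#'   nutrient_bounds = list(fat = c(min = NA, max = 20),
#'                          energy = c(min = 452, max = NA)),
#'   ingredient_bounds = list(sugar = c(min = 0, max = 14)))
#' @export
constraint_spec <- function(nutrient_bounds = list(),
                            ingredient_bounds = list()) {
  norm <- function(b, what) {
    lapply(b, function(v) {
      v <- c(min = unname(v["min"]), max = unname(v["max"]))
      if (!is.na(v["min"]) && !is.na(v["max"]) && v["min"] > v["max"])
        stop(what, " bound has min > max")
      v
    })
  }
  nutrient_bounds <- norm(nutrient_bounds, "nutrient")
  ingredient_bounds <- norm(ingredient_bounds, "ingredient")
  lo <- vapply(ingredient_bounds, function(v)
    if (is.na(v["min"])) 0 else v["min"], numeric(1))
  if (length(lo) && sum(lo) > 100 + 1e-9)
    stop("ingredient minimum bounds alone exceed 100% of mass")
  structure(list(nutrient_bounds = nutrient_bounds,
                 ingredient_bounds = ingredient_bounds),
            class = "constraint_spec")
}

#' Read / write constraint specifications (YAML or JSON)
#'
#' Layout: `nutrient_bounds: {nutrient: {min:, max:}}` and
#' `ingredient_bounds: {ingredient: {min:, max:}}`; a missing side is
#' `null`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [constraint_spec()].
#' @export
read_constraint_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = FALSE)
  conv <- function(b) lapply(b, function(v)
    c(min = if (is.null(v$min)) NA_real_ else as.numeric(v$min),
      max = if (is.null(v$max)) NA_real_ else as.numeric(v$max)))
  constraint_spec(nutrient_bounds = conv(raw$nutrient_bounds),
                  ingredient_bounds = conv(raw$ingredient_bounds))
}

#' @rdname read_constraint_spec
#' @param spec A [constraint_spec()].
#' @export
write_constraint_spec <- function(spec, path) {
  conv <- function(b) lapply(b, function(v)
    list(min = if (is.na(v["min"])) NULL else unname(v["min"]),
         max = if (is.na(v["max"])) NULL else unname(v["max"])))
  out <- list(nutrient_bounds = conv(spec$nutrient_bounds),
              ingredient_bounds = conv(spec$ingredient_bounds))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

#' @export
print.constraint_spec <- function(x, ...) {
  fmt <- function(b) vapply(names(b), function(n) {
    v <- b[[n]]
    sprintf("  %-14s min %s  max %s", n,
            ifelse(is.na(v["min"]), "-", format(v["min"])),
            ifelse(is.na(v["max"]), "-", format(v["max"])))
  }, character(1))
  cat("Constraint specification\n nutrient bounds (per 100 g):\n")
  cat(fmt(x$nutrient_bounds), sep = "\n")
  if (length(x$ingredient_bounds)) {
    cat("\n ingredient bounds (mass %):\n")
    cat(fmt(x$ingredient_bounds), sep = "\n")
  }
  cat("\n mass balance: percentages sum to 100\n")
  invisible(x)
}

#' Daily nutrient requirement set
#'
#' Daily amounts for energy, the macronutrients, and the essential amino
#' acids (with methionine+cysteine and phenylalanine+tyrosine as sums, the
#' scoring-pattern convention).
#'
#' @param energy_kcal_day kcal/day.
#' @param protein_g_day,carbohydrate_g_day,fat_g_day g/day.
#' @param amino_acids_g_day Named numeric vector (g/day), names among
#'   `lys, leu, val, his, trp, thr, ile, met_cys, phe_tyr`.
#' @return Object of class `requirement_set`.
#' @export
requirement_set <- function(energy_kcal_day, protein_g_day,
                            carbohydrate_g_day, fat_g_day,
                            amino_acids_g_day = numeric()) {
  vals <- c(energy_kcal_day, protein_g_day, carbohydrate_g_day, fat_g_day,
            amino_acids_g_day)
  if (any(is.na(vals)) || any(vals <= 0))
    stop("all requirement values must be > 0")
  ok <- c(AA_KEYS, AA_SUM_KEYS)
  if (length(amino_acids_g_day) &&
      !all(names(amino_acids_g_day) %in% ok))
    stop("unknown amino-acid requirement key(s): ",
         paste(setdiff(names(amino_acids_g_day), ok), collapse = ", "))
  structure(list(energy_kcal_day = energy_kcal_day,
                 protein_g_day = protein_g_day,
                 carbohydrate_g_day = carbohydrate_g_day,
                 fat_g_day = fat_g_day,
                 amino_acids_g_day = amino_acids_g_day),
            class = "requirement_set")
}

#' @export
print.requirement_set <- function(x, ...) {
  cat("Daily requirements:\n")
  cat(sprintf("  energy %.1f kcal, protein %.2f g, carbohydrate %.2f g, fat %.2f g\n",
              x$energy_kcal_day, x$protein_g_day, x$carbohydrate_g_day,
              x$fat_g_day))
  if (length(x$amino_acids_g_day))
    cat("  amino acids (g/day): ",
        paste(sprintf("%s %.2f", names(x$amino_acids_g_day),
                      x$amino_acids_g_day), collapse = "  "), "\n", sep = "")
  invisible(x)
}

# flat named vector of all daily amounts
requirement_vector <- function(req) {
  c(energy = req$energy_kcal_day, protein = req$protein_g_day,
    carbohydrate = req$carbohydrate_g_day, fat = req$fat_g_day,
    req$amino_acids_g_day)
}

#' Convert daily requirements to minimum nutrient densities
#'
#' Maps daily amounts (per day) to minimum densities (per 100 g of
#' product) for use as LP `nutrient_bounds` minima.
#'
#' Two conversions are provided because formulation practice uses both:
#'
#' * `"energy"` (default): every requirement is scaled by the product's
#'   reference energy density — the density a product must have so that
#'   eating enough of it to meet the energy requirement also meets every
#'   other requirement:
#'   `min_density = daily_amount * reference_energy_density / energy_kcal_day`.
#' * `"protein_pattern"`: amino-acid minima follow the scoring-pattern
#'   convention (mg amino acid per g protein): the daily amino-acid to
#'   protein ratio is applied to a product protein density,
#'   `aa_min = (aa_g_day / protein_g_day) * protein_density`. This
#'   anchors amino-acid quality to the protein the product actually
#'   carries instead of to energy. Macronutrient minima are as in
#'   `"energy"`.
#'
#' @param req A [requirement_set()].
#' @param reference_energy_density kcal/100 g; e.g. an energy floor of
#'   452 kcal/100 g.
#' @param method `"energy"` or `"protein_pattern"`.
#' @param protein_density Protein density (g/100 g) anchoring the
#'   scoring-pattern mode; defaults to the energy-scaled protein minimum
#'   (in which case the two modes coincide — supply the product's target
#'   protein density to make the pattern bind to it).
#' @return Named numeric vector of minimum densities (g/100 g; kcal/100 g
#'   for `energy`).
#' @examples
#' req <- mali_requirements()
#' requirement_to_density(req, 452)["protein"]  # 64 * 452 / 2615.2 = 11.06
#' @export
requirement_to_density <- function(req, reference_energy_density,
                                   method = c("energy", "protein_pattern"),
                                   protein_density = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(req, "requirement_set"))
  if (reference_energy_density <= 0)
    stop("reference_energy_density must be > 0")
  if (req$energy_kcal_day <= 0) stop("energy requirement must be > 0")
  scale <- reference_energy_density / req$energy_kcal_day
  out <- requirement_vector(req) * scale
  if (method == "protein_pattern" && length(req$amino_acids_g_day)) {
    if (is.null(protein_density))
      protein_density <- req$protein_g_day * scale
    aa <- req$amino_acids_g_day / req$protein_g_day * protein_density
    out[names(aa)] <- aa
  }
  out
}
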