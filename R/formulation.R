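# Formulations: named ingredient -> mass-percent maps summing to 100,
# and linear blending of ingredient profiles into a product profile.

FORMULATION_SUM_TOL <- 0.05

#' Formulation
#'
#' A named numeric vector of ingredient mass percentages (0-100 scale)
#' summing to 100.
#'
#' @param components Named numeric vector, percent of total mass.
#' @param name Formulation identifier.
#' @param sum_tol Declared slack for the sum-to-100 check (default 0.05).
#'   Formulations transcribed from tables printed at one decimal can
#'   carry up to 0.05 of rounding error per component; declare the wider
#'   slack here rather than silently renormalizing.
#' @return Object of class `formulation`.
#' @examples
#' formulation(c(peanuts = 38.4, cowpeas = 22.2, millet = 18.4,
#'               sugar = 14.0, rice = 7.0), name = "A")
#' @export
formulation <- function(components, name = "formulation",
                        sum_tol = FORMULATION_SUM_TOL) {
  stopifnot(is.numeric(components), !is.null(names(components)))
  structure(components, name = name, sum_tol = sum_tol,
            class = "formulation")
}

#' Validate a formulation
#'
#' Checks that every percentage is non-negative and that the percentages
#' sum to 100 within the formulation's declared slack (default +/- 0.05);
#' optionally checks every component against a known ingredient set.
#'
#' @param f A [formulation()] (or named numeric vector).
#' @param ingredients Optional [ingredient_set()]; unknown component names
#'   raise a reference error.
#' @return `f`, classed, when valid; otherwise an error.
#' @export
validate_formulation <- function(f, ingredients = NULL) {
  if (!inherits(f, "formulation")) f <- formulation(f)
  if (any(is.na(f))) stop("formulation has NA percentage(s)")
  if (any(f < 0))
    stop("negative percentage for: ",
         paste(names(f)[f < 0], collapse = ", "))
  s <- sum(f)
  tol <- attr(f, "sum_tol")
  if (is.null(tol)) tol <- FORMULATION_SUM_TOL
  if (abs(s - 100) > tol)
    stop(sprintf("formulation '%s' percentages sum to %.2f, not 100",
                 attr(f, "name"), s))
  if (!is.null(ingredients)) {
    unknown <- setdiff(names(f), ingredients$name)
    if (length(unknown))
      stop("component(s) not in ingredient set: ",
           paste(unknown, collapse = ", "))
  }
  f
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("Formulation '%s' (mass %%):\n", attr(x, "name")))
  for (n in names(x)) if (x[[n]] > 0) cat(sprintf("  %-10s %6.2f\n", n, x[[n]]))
  invisible(x)
}

#' Blend ingredient profiles into a predicted product profile
#'
#' Each nutrient of the product is the percentage-weighted average of the
#' ingredient values: `sum(pct_i / 100 * nutrient_i)`. Energy is blended
#' from the ingredient energy values as reported, not recomputed with the
#' Atwater factors — formulation software predicts product energy this
#' way, and the two pathways differ whenever ingredient energies already
#' embody fiber or digestibility corrections. Use [atwater_energy()] on
#' the blended macros for the alternative pathway.
#'
#' Amino acids present in every component are blended; acids missing from
#' any component are omitted from the result with a warning.
#'
#' @param f A [formulation()]; validated first.
#' @param ingredients An [ingredient_set()] on a single common basis.
#' @return A [nutrient_profile()] on the common basis of the inputs.
#' @examples
#' set <- mali_ingredients()
#' blend_profile(rutf_formulations()[["A"]], set)
#' @export
blend_profile <- function(f, ingredients) {
  f <- validate_formulation(f, ingredients)
  used <- names(f)[f > 0]
  rows <- ingredients[match(used, ingredients$name), ]
  if (length(unique(rows$basis)) > 1)
    stop("mixed bases among components: ",
         paste(unique(rows$basis), collapse = ", "))
  w <- f[used] / 100
  wmean <- function(col) sum(w * rows[[col]])
  aa_cols <- intersect(AA_KEYS, names(rows))
  have <- aa_cols[vapply(aa_cols, function(k) !anyNA(rows[[k]]), logical(1))]
  dropped <- setdiff(aa_cols[vapply(aa_cols, function(k) any(!is.na(rows[[k]])),
                                    logical(1))], have)
  if (length(dropped))
    warning("partial result: amino acid(s) missing in some component, omitted: ",
            paste(dropped, collapse = ", "))
  aa <- vapply(have, wmean, numeric(1))
  nutrient_profile(
    protein = wmean("protein"), fat = wmean("fat"), ash = wmean("ash"),
    fiber = wmean("fiber"), carbohydrate = wmean("carbohydrate"),
    energy = wmean("energy"), moisture = wmean("moisture"),
    amino_acids = aa, basis = rows$basis[1])
}
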