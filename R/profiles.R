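# Nutrient profiles: per-100 g composition vectors for ingredients and products.

#' @keywords internal
AA_KEYS <- c("lys", "leu", "val", "his", "trp", "thr", "ile",
             "met", "cys", "phe", "tyr")

#' @keywords internal
AA_SUM_KEYS <- c("met_cys", "phe_tyr")

MACRO_KEYS <- c("protein", "fat", "ash", "fiber", "carbohydrate",
                "energy", "moisture")

# proximate components may exceed 100 by at most this much (rounding slack)
PROXIMATE_TOL <- 0.5

#' Per-100 g nutrient profile
#'
#' Constructs a validated nutrient profile for one ingredient or one
#' product: proximate composition (g/100 g), energy (kcal/100 g), and an
#' optional set of amino acids (g/100 g). A profile is either on an
#' as-is basis (moisture included) or a dry basis (moisture forced to 0).
#'
#' Amino-acid sums `met_cys` and `phe_tyr` can be supplied directly when a
#' source table reports only the sum; a stored sum takes precedence over
#' recomputation from the individual acids.
#'
#' @param protein,fat,ash,fiber,carbohydrate Proximate components, g/100 g.
#' @param energy Energy density, kcal/100 g. If `NULL`, computed from the
#'   Atwater factors (4/9/4) on protein, fat and carbohydrate.
#' @param moisture Moisture, g/100 g; must be 0 on a dry basis.
#' @param amino_acids Named numeric vector with names among
#'   `r paste(AA_KEYS, collapse = ", ")`. Absent acids stay absent (they are
#'   not treated as zero).
#' @param met_cys,phe_tyr Optional stored sums, g/100 g. When both the sum
#'   and its components are present they must agree within 0.015.
#' @param basis `"as_is"` or `"dry"`.
#' @param proximate_tol Allowed excess of the proximate sum over 100
#'   (default 0.5). Published composition tables occasionally carry a
#'   larger internal inconsistency; declare it explicitly rather than
#'   editing the data.
#' @param aa_sum_tol Allowed disagreement between a stored amino-acid sum
#'   (`met_cys`, `phe_tyr`) and the sum of its stored components
#'   (default 0.015, two half-units of the second printed decimal).
#' @return An object of class `nutrient_profile`.
#' @examples
#' p <- nutrient_profile(protein = 19.5, fat = 19.3, ash = 2.95,
#'                       fiber = 6.90, basis = "dry",
#'                       amino_acids = c(lys = 0.59, leu = 1.42))
#' p$carbohydrate  # filled by difference when omitted
#' @export
nutrient_profile <- function(protein, fat, ash, fiber, carbohydrate = NULL,
                             energy = NULL, moisture = 0,
                             amino_acids = numeric(),
                             met_cys = NULL, phe_tyr = NULL,
                             basis = c("as_is", "dry"),
                             proximate_tol = PROXIMATE_TOL,
                             aa_sum_tol = 0.015) {
  basis <- match.arg(basis)
  if (basis == "dry" && moisture != 0)
    stop("a dry-basis profile must have moisture 0, got ", moisture)
  if (is.null(carbohydrate))
    carbohydrate <- carbohydrate_by_difference(protein, fat, ash, fiber,
                                               moisture)
  if (is.null(energy))
    energy <- atwater_energy(protein, fat, carbohydrate)
  macros <- c(protein = protein, fat = fat, ash = ash, fiber = fiber,
              carbohydrate = carbohydrate, energy = energy,
              moisture = moisture)
  if (any(is.na(macros)))
    stop("macronutrient fields must not be NA")
  if (any(macros < 0))
    stop("nutrient values must be non-negative; offending field(s): ",
         paste(names(macros)[macros < 0], collapse = ", "))
  prox <- protein + fat + ash + fiber + carbohydrate + moisture
  if (prox > 100 + proximate_tol)
    stop(sprintf("proximate components sum to %.2f > 100 (+%.1f tolerance)",
                 prox, proximate_tol))
  if (length(amino_acids)) {
    if (is.null(names(amino_acids)) ||
        !all(names(amino_acids) %in% AA_KEYS))
      stop("amino_acids must be named with names among: ",
           paste(AA_KEYS, collapse = ", "))
    if (any(is.na(amino_acids)))
      amino_acids <- amino_acids[!is.na(amino_acids)]
    if (any(amino_acids < 0))
      stop("amino acid values must be non-negative")
  }
  obj <- structure(
    list(basis = basis, protein = protein, fat = fat, ash = ash,
         fiber = fiber, carbohydrate = carbohydrate, energy = energy,
         moisture = moisture, amino_acids = amino_acids,
         met_cys = met_cys, phe_tyr = phe_tyr),
    class = "nutrient_profile")
  for (s in AA_SUM_KEYS) {
    stored <- obj[[s]]
    if (is.null(stored) || is.na(stored)) next
    if (stored < 0) stop(s, " must be non-negative")
    parts <- strsplit(s, "_", fixed = TRUE)[[1]]
    if (all(parts %in% names(amino_acids))) {
      recomputed <- sum(amino_acids[parts])
      if (abs(stored - recomputed) > aa_sum_tol)
        stop(sprintf("stored %s (%.3f) disagrees with %s + %s (%.3f) by > %.3f",
                     s, stored, parts[1], parts[2], recomputed, aa_sum_tol))
    }
  }
  obj
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat(sprintf("Nutrient profile (per 100 g, %s basis)\n",
              sub("_", "-", x$basis)))
  cat(sprintf("  protein %.1f  fat %.1f  ash %.2f  fiber %.2f  carbohydrate %.1f g\n",
              x$protein, x$fat, x$ash, x$fiber, x$carbohydrate))
  cat(sprintf("  energy %s kcal  moisture %.1f g\n",
              signif(x$energy, 3), x$moisture))
  if (length(x$amino_acids))
    cat("  amino acids (g): ",
        paste(sprintf("%s %.2f", names(x$amino_acids), x$amino_acids),
              collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Look up one nutrient density from a profile
#'
#' Resolves macronutrients, individual amino acids and the sum keys
#' `met_cys` / `phe_tyr` (stored sums take precedence; otherwise the sum of
#' the two stored acids). Returns `NA` when the nutrient is absent.
#'
#' @param profile A [nutrient_profile()].
#' @param nutrient Nutrient identifier, e.g. `"protein"`, `"lys"`,
#'   `"met_cys"`.
#' @return Density per 100 g (kcal for `"energy"`), or `NA` if absent.
#' @export
nutrient_value <- function(profile, nutrient) {
  stopifnot(inherits(profile, "nutrient_profile"))
  if (nutrient %in% MACRO_KEYS) return(profile[[nutrient]])
  if (nutrient %in% AA_KEYS) {
    v <- profile$amino_acids[nutrient]
    return(if (length(v) && !is.na(v)) unname(v) else NA_real_)
  }
  if (nutrient %in% AA_SUM_KEYS) {
    stored <- profile[[nutrient]]
    if (!is.null(stored) && !is.na(stored)) return(stored)
    parts <- strsplit(nutrient, "_", fixed = TRUE)[[1]]
    v <- profile$amino_acids[parts]
    if (length(v) == 2 && !any(is.na(v))) return(sum(v))
    return(NA_real_)
  }
  stop("unknown nutrient: ", nutrient)
}

#' Atwater energy of a composition
#'
#' Energy as 4 kcal/g of protein, 9 kcal/g of fat and 4 kcal/g of
#' carbohydrate — the general factors used for therapeutic-food labelling.
#'
#' @param protein,fat,carbohydrate Amounts in g (per 100 g for a density).
#' @return Energy in kcal (per 100 g when densities were supplied).
#' @examples
#' atwater_energy(19.5, 19.3, 51.3)  # 456.9 kcal/100 g
#' @export
atwater_energy <- function(protein, fat, carbohydrate) {
  if (any(c(protein, fat, carbohydrate) < 0, na.rm = FALSE))
    stop("atwater_energy: inputs must be non-negative")
  4 * protein + 9 * fat + 4 * carbohydrate
}

#' Carbohydrate by difference
#'
#' Total carbohydrate as 100 minus protein, fat, ash, fiber and moisture,
#' the standard proximate-analysis convention. On a dry basis pass
#' `moisture = 0`.
#'
#' @param protein,fat,ash,fiber,moisture Components, g/100 g.
#' @return Carbohydrate, g/100 g.
#' @examples
#' carbohydrate_by_difference(19.5, 19.3, 2.95, 6.90)  # 51.35
#' @export
carbohydrate_by_difference <- function(protein, fat, ash, fiber,
                                       moisture = 0) {
  comp <- protein + fat + ash + fiber + moisture
  if (any(c(protein, fat, ash, fiber, moisture) < 0))
    stop("carbohydrate_by_difference: inputs must be non-negative")
  if (any(comp > 100))
    stop(sprintf("infeasible composition: components sum to %.2f > 100",
                 max(comp)))
  100 - comp
}
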