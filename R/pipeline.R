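# Pipeline orchestration: formulate -> evaluate -> compare -> intake ->
# cost trend, writing deterministic artifacts to an output directory.

#' Pipeline run configuration
#'
#' Paths default to the packaged Mali case study when `NULL`.
#'
#' @param ingredients_path,prices_path CSV paths (wide profiles; long or
#'   wide prices).
#' @param constraints_path Optional YAML/JSON constraint file; default is
#'   the published restriction set of the selected product.
#' @param product Product identifier `"A"`-`"F"` selecting the koji level
#'   for the formulation stage.
#' @param years Integer vector of years for formulation and cost trend.
#' @param out_dir Output directory (created if needed).
#' @param lysine Which lysine requirement to use; see
#'   [mali_requirements()].
#' @param seed Integer seed for synthetic stages.
#' @param verbose Log progress to stderr.
#' @return Object of class `run_config`.
#' @export
run_config <- function(ingredients_path = NULL, prices_path = NULL,
                       constraints_path = NULL, product = "A",
                       years = 2004:2009, out_dir = "rutfoptim-run",
                       lysine = "table", seed = 1, verbose = TRUE) {
  for (p in c(ingredients_path, prices_path, constraints_path))
    if (!is.null(p) && !file.exists(p))
      stop("config error: file not found: ", p)
  structure(list(ingredients_path = ingredients_path,
                 prices_path = prices_path,
                 constraints_path = constraints_path, product = product,
                 years = as.integer(years), out_dir = out_dir,
                 lysine = lysine, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full formulation pipeline
#'
#' Stages: (1) least-cost formulation per year under the constraint set;
#' (2) evaluation of the six fixed product formulations by linear
#' blending; (3) predicted-vs-measured comparison; (4) intake and
#' limiting-nutrient analysis; (5) ingredient-cost trend. Outputs
#' (`solutions.json`, `comparison.csv`, `intake.csv`, `cost_trend.csv`,
#' `run_log.txt`) are deterministic: identical configuration and inputs
#' give byte-identical files.
#'
#' @param config A [run_config()].
#' @return Named character vector of written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (config$verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say("rutfoptim pipeline (R %s, rutfoptim %s)", getRversion(),
      as.character(utils::packageVersion("rutfoptim")))

  ing <- stage("data", if (is.null(config$ingredients_path))
    mali_ingredients() else read_ingredient_set(config$ingredients_path))
  pt <- stage("data", if (is.null(config$prices_path))
    mali_prices() else read_price_table(config$prices_path))
  req <- stage("data", mali_requirements(config$lysine))
  cs <- stage("data", if (is.null(config$constraints_path))
    mali_constraints(config$product, requirements = req)
    else read_constraint_spec(config$constraints_path))
  priced <- intersect(ing$name, unique(pt$ingredient))
  pool <- ing[match(priced, ing$name), ]
  class(pool) <- class(ing)

  # 1. least-cost formulation per year
  sols <- stage("formulate", lapply(config$years, function(y) {
    fit <- least_cost(pool, prices_for_year(pt, pool$name, y), cs)
    say("formulate %d: %s%s", y, fit$status,
        if (fit$status == "optimal")
          sprintf(" (%.4f USD/kg; binding: %s)", fit$cost_usd_per_kg,
                  paste(fit$binding_constraints, collapse = ", ")) else "")
    list(year = y, status = fit$status,
         cost_usd_per_kg = if (is.na(fit$cost_usd_per_kg)) NULL
           else fit$cost_usd_per_kg,
         formulation = if (fit$status == "optimal")
           as.list(coef(fit)) else NULL,
         binding_constraints = fit$binding_constraints)
  }))
  f_sol <- file.path(config$out_dir, "solutions.json")
  jsonlite::write_json(sols, f_sol, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # 2-3. evaluate fixed products and compare with measurements
  forms <- stage("evaluate", rutf_formulations())
  blends <- stage("evaluate", lapply(forms, blend_profile,
                                     ingredients = ing))
  cmp <- stage("compare", compare_predicted_actual(measured_products()))
  f_cmp <- file.path(config$out_dir, "comparison.csv")
  write_comparison_csv(cmp, f_cmp)
  say("compare: %d rows, %d flagged", nrow(cmp), sum(cmp$flag))

  # 4. intake analysis on measured products
  reports <- stage("intake", lapply(measured_products(), function(mp)
    intake_needed(req, mp$actual)))
  rank <- limiting_nutrient_ranking(reports)
  f_int <- file.path(config$out_dir, "intake.csv")
  utils::write.csv(as.data.frame(rank), f_int, row.names = FALSE,
                   fileEncoding = "UTF-8")
  say("intake: limiting nutrient(s): %s",
      paste(unique(rank$nutrient[rank$limiting]), collapse = ", "))

  # 5. cost trend
  ct <- stage("cost-trend", build_cost_trend(forms, pt, config$years))
  f_ct <- file.path(config$out_dir, "cost_trend.csv")
  write_cost_trend_csv(ct, f_ct)
  say("cost-trend: %d x %d cells, %s mean %.2f -> %s mean %.2f USD/kg",
      nrow(ct$costs), ncol(ct$costs), min(config$years),
      ct$yearly_mean[1], max(config$years),
      ct$yearly_mean[length(config$years)])

  f_log <- file.path(config$out_dir, "run_log.txt")
  writeLines(log, f_log)
  invisible(c(solutions = f_sol, comparison = f_cmp, intake = f_int,
              cost_trend = f_ct, log = f_log))
}
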