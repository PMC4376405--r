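# Shared helpers: tiny hand-built ingredient sets and LP instances.

toy_set <- function() {
  ingredient_set(data.frame(
    name = c("x", "y", "z"),
    basis = "as_is",
    protein = c(10, 20, 5),
    fat = c(5, 2, 1),
    ash = c(1, 2, 1),
    fiber = c(2, 4, 1),
    carbohydrate = c(70, 60, 80),
    energy = c(365, 338, 349),
    moisture = c(12, 12, 12),
    lys = c(0.3, 1.2, 0.2),
    leu = c(1.0, 1.5, 0.5),
    thr = c(0.35, 0.8, 0.25),
    ile = c(0.4, 0.9, 0.3),
    stringsAsFactors = FALSE))
}

# published cost table: year x formulation matrix (USD/kg) as printed
printed_cost_matrix <- function() {
  matrix(c(0.33, 0.34, 0.34, 0.33, 0.33, 0.33,
           0.36, 0.36, 0.36, 0.36, 0.35, 0.35,
           0.37, 0.38, 0.38, 0.37, 0.37, 0.37,
           0.41, 0.42, 0.43, 0.41, 0.41, 0.41,
           0.46, 0.46, 0.47, 0.45, 0.46, 0.46,
           0.49, 0.50, 0.50, 0.49, 0.50, 0.50),
         nrow = 6, byrow = TRUE,
         dimnames = list(2004:2009, LETTERS[1:6]))
}

# random blend on the 0.1% grid with all components >= min_pct
random_grid_blend <- function(k = 3, min_pct = 5) {
  repeat {
    cuts <- sort(sample(seq(min_pct * 10, 1000 - min_pct * 10),
                        k - 1)) / 10
    w <- diff(c(0, cuts, 100))
    if (all(w >= min_pct)) break
  }
  formulation(stats::setNames(w, paste0("p", seq_len(k))), name = "random")
}
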