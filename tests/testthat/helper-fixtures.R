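# Small in-code builders for classifier and pipeline tests. Energy is
# specified per 8 fl oz (the scale criteria are stated on) and stored on
# the kcal/100g scale the tables use: kcal100 = kcal8 * 12.5 / factor.

make_foodcodes <- function(codes, kcal8 = 100, factor = 30,
                           category = 7204L,
                           main = "Synthetic beverage",
                           additional = "", cycle = "c1") {
  validate_foodcode_table(data.frame(
    code = codes, cycle = cycle,
    main_description = rep_len(main, length(codes)),
    additional_description = rep_len(additional, length(codes)),
    wweia_category = rep_len(category, length(codes)),
    kcal_per_100g = rep_len(kcal8, length(codes)) * 12.5 /
      rep_len(factor, length(codes)),
    grams_per_floz = rep_len(factor, length(codes)),
    stringsAsFactors = FALSE))
}

make_products <- function(code, ingredients, kcal = NA_real_, known = TRUE,
                          cycle = "c1", brand = NULL) {
  n <- length(ingredients)
  validate_products(data.frame(
    brand = brand %||% sprintf("brand-%d", seq_len(n)),
    code = rep_len(code, n), cycle = rep_len(cycle, n),
    ingredients = ingredients,
    kcal_per_8floz_mfr = rep_len(kcal, n),
    ingredients_known = rep_len(known, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_participants <- function(n, weight = 1, stratum = 1L, psu = seq_len(n),
                              water_g = 0, age = 10L) {
  validate_participants(data.frame(
    participant_id = sprintf("T%04d", seq_len(n)),
    age_years = rep_len(age, n), sex = "female",
    race_ethnicity = "other", income = "middle",
    physical_activity = "moderate", bmi_percentile = 50,
    diabetes_dx = FALSE, reliable_recall = TRUE,
    questionnaire_water_g = rep_len(water_g, n),
    stratum_id = rep_len(stratum, n), psu_id = rep_len(psu, n),
    weight = rep_len(weight, n), stringsAsFactors = FALSE))
}

# Independent linearization oracle: covariance of the WLS coefficients
# assembled directly from per-PSU score totals, written as plain loops.
oracle_linearization <- function(X, y, w, stratum, psu) {
  b <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  e <- as.numeric(y - X %*% b)
  U <- X * (w * e)
  V <- matrix(0, ncol(X), ncol(X))
  for (h in unique(stratum)) {
    rows <- which(stratum == h)
    psus <- unique(psu[rows])
    Z <- t(vapply(psus, function(p) {
      colSums(U[rows[psu[rows] == p], , drop = FALSE])
    }, numeric(ncol(X))))
    nh <- length(psus)
    zbar <- colMeans(Z)
    Sh <- matrix(0, ncol(X), ncol(X))
    for (j in seq_len(nh)) {
      d <- Z[j, ] - zbar
      Sh <- Sh + outer(d, d)
    }
    V <- V + nh / (nh - 1) * Sh
  }
  A <- solve(t(X) %*% diag(w) %*% X)
  A %*% V %*% A
}
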