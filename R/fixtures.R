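#' Packaged worked-example fixtures
#'
#' Two small fixtures transcribed from published worked examples are
#' shipped with the package as plain CSV:
#'
#' * `fixture_table2()`: the 17 foodcodes of the FNDDS subcategory
#'   "Fruit juice drinks and fruit flavored drinks, low calorie"
#'   (2013-2016), with database energy densities, survey categories,
#'   branded products, manufacturer energies, and the LCS each
#'   manufacturer listed. Fifteen codes contain an LCS in every located
#'   product; two (92550380, 92552030) contain none despite "light"/"less
#'   sugar" labelling. Database and manufacturer energies disagree
#'   markedly for several codes (e.g. 92550040: 46 vs 10 kcal/8 fl oz;
#'   92552020: 5 vs 60).
#' * `fixture_table3()`: foodcode 92530610 ("Fruit juice drink, with high
#'   Vitamin C", 114 kcal/8 fl oz in the database) and the branded
#'   beverages sold under it, some containing sucralose and some none —
#'   the canonical mixed foodcode.
#'
#' Energy densities are stored per 100 g; at the stored 30 g/fl oz
#' conversion factor the derived kcal/8 fl oz values reproduce the
#' published per-serving figures to within 0.02 kcal.
#'
#' @return list with elements `foodcodes` and `products` (validated
#'   data.frames).
#' @export
fixture_table2 <- function() {
  list(
    foodcodes = read_foodcode_table(
      system.file("extdata", "table2_foodcodes.csv", package = "bevclass",
                  mustWork = TRUE)),
    products = read_products(
      system.file("extdata", "table2_products.csv", package = "bevclass",
                  mustWork = TRUE))
  )
}

#' @rdname fixture_table2
#' @export
fixture_table3 <- function() {
  list(
    foodcodes = read_foodcode_table(
      system.file("extdata", "table3_foodcodes.csv", package = "bevclass",
                  mustWork = TRUE)),
    products = read_products(
      system.file("extdata", "table3_products.csv", package = "bevclass",
                  mustWork = TRUE))
  )
}
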