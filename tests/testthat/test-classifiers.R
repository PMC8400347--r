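test_that("per-serving energy follows from density and conversion factor", {
  fc <- make_foodcodes("92000001", factor = 25)
  fc$kcal_per_100g <- 0
  expect_equal(kcal_per_serving(fc)$kcal_per_8floz, 0)
  expect_equal(kcal_per_serving(fc)$kcal_per_240g, 0)

  fc$kcal_per_100g <- 19.18
  fc$grams_per_floz <- 30
  expect_equal(kcal_per_serving(fc)$kcal_per_8floz, 46.032)

  fc$kcal_per_100g <- 100
  fc$grams_per_floz <- 25
  k <- kcal_per_serving(fc)
  expect_equal(k$kcal_per_8floz, 200)
  expect_equal(k$kcal_per_240g, 240)

  fc$grams_per_floz <- NA
  expect_error(kcal_per_serving(fc), "missing conversion factor")
})

test_that("prefix strategy needs both the prefix and a diet-style term", {
  cfg <- strategy_config(strategy1_terms = c("sugar-free", "reduced sugar",
                                             "low-calorie sweetener",
                                             "no-calorie sweetener", "diet"))
  soft <- make_foodcodes("92410560",
                         main = "Soft drink, fruit flavored, caffeine containing, diet")
  expect_true(strategy1_fndds_prefix(soft, cfg))

  juice <- make_foodcodes("92550040", main = "Fruit juice drink, diet")
  expect_false(strategy1_fndds_prefix(juice, cfg))

  blank <- make_foodcodes("92410560", main = "", additional = "")
  expect_false(strategy1_fndds_prefix(blank, cfg))
})

test_that("category strategy flags exactly the diet beverage categories", {
  expect_true(strategy2_wweia(make_foodcodes("92550400", category = 7106L)))
  expect_false(strategy2_wweia(make_foodcodes("92550030", category = 7204L)))
  # LCS-containing sweetened carbonated water sits in a non-diet category
  expect_false(strategy2_wweia(make_foodcodes(
    "92410250", category = 7832L,
    main = "Carbonated water, sweetened, with low-calorie sweetener")))
})

test_that("caloric-density criteria use strict inequalities and propagate unknowns", {
  th <- thresholds()
  k <- function(kcal8) data.frame(kcal_per_8floz = kcal8,
                                  kcal_per_240g = kcal8)
  # database-vs-manufacturer discordance flips FDA low-calorie status
  expect_false(strategy3_caloric_density(k(46), "FDA_LOW", th))
  expect_true(strategy3_caloric_density(k(10), "FDA_LOW", th))
  # listed at 5 kcal but actually 60: every criterion flips
  for (crit in c("FDA_LOW", "FDA_NO", "LEAHY", "MAILLOT")) {
    expect_true(strategy3_caloric_density(k(4.99), crit, th))
    expect_false(strategy3_caloric_density(k(60), crit, th))
  }
  # boundary values are excluded
  expect_false(strategy3_caloric_density(k(40), "FDA_LOW", th))
  expect_false(strategy3_caloric_density(k(6.7), "LEAHY", th))
  # unknown energy yields NA, not FALSE
  expect_true(is.na(strategy3_caloric_density(k(NA), "LEAHY", th)))
})

test_that("tighter caloric thresholds flag subsets of looser ones", {
  set.seed(1)
  kcal <- data.frame(kcal_per_8floz = runif(200, 0, 150))
  for (i in 1:20) {
    a <- sort(runif(2, 1, 120))
    fa <- kcal$kcal_per_8floz < a[1]
    fb <- kcal$kcal_per_8floz < a[2]
    expect_true(all(fb[fa])) # flagged under tighter => flagged under looser
  }
})

test_that("text strategy matches whole tokens with hyphen/space variants", {
  expect_true(strategy4_text(make_foodcodes("92550040",
                                            main = "Fruit juice drink, diet")))
  expect_false(strategy4_text(make_foodcodes(
    "92530610", main = "Fruit juice drink, with high Vitamin C")))
  # no substring firing: "diet" must not match "Dietary"
  expect_false(strategy4_text(make_foodcodes(
    "92999999", main = "Dietary supplement drink")))

  # case and hyphen/space invariance
  variants <- c("SUGAR-FREE lemonade", "sugar free Lemonade",
                "Sugar-Free LEMONADE")
  for (v in variants) {
    expect_true(strategy4_text(make_foodcodes("92999998", main = v)))
  }
})

test_that("ingredient classifier applies the all/some/none rule", {
  # single product without LCS: sugary beverage
  capri <- make_products("92552030", "None", kcal = 94)
  expect_equal(classify_by_ingredients("92552030", "c1", capri)$class, "SB")

  # all products with LCS
  lc <- make_products("92000010", c("water; aspartame", "water; sucralose"))
  expect_equal(classify_by_ingredients("92000010", "c1", lc)$class, "LCSB")

  # a product listing both sugar and LCS counts as LCS-containing
  pen <- make_products("92410110",
                       c("water; sucralose; neotame; high fructose corn syrup",
                         "water; high fructose corn syrup"))
  res <- classify_by_ingredients("92410110", "c1", pen)
  expect_equal(res$class, "MIXED")
  pen1 <- make_products("92410110",
                        "water; sucralose; neotame; high fructose corn syrup")
  expect_equal(classify_by_ingredients("92410110", "c1", pen1)$class, "LCSB")

  # unknown-ingredient products alone cannot classify
  unk <- make_products("92000011", "", known = FALSE)
  expect_error(classify_by_ingredients("92000011", "c1", unk),
               "92000011.*unknown ingredients")
  # ... unless the description is explicit
  rec <- make_foodcodes("92000011", main = "Fruit drink, diet")
  expect_equal(classify_by_ingredients("92000011", "c1", unk, rec)$class,
               "LCSB")

  # explicit description contradicted by unanimous ingredients: ingredients win
  rec2 <- make_foodcodes("92000012", main = "Fruit drink, diet")
  sb <- make_products("92000012", "water; sugar")
  res2 <- classify_by_ingredients("92000012", "c1", sb, rec2)
  expect_equal(res2$class, "SB")
  expect_match(res2$provenance, "CONFLICT")
})

test_that("ingredient classifier ignores product order and duplicates", {
  prods <- make_products("92000020",
                         c("water; sucralose", "water; sugar",
                           "water; stevia"))
  base <- classify_by_ingredients("92000020", "c1", prods)$class
  shuffled <- prods[c(3, 1, 2), ]
  dup <- rbind(prods, prods)
  expect_equal(classify_by_ingredients("92000020", "c1", shuffled)$class, base)
  expect_equal(classify_by_ingredients("92000020", "c1", dup)$class, base)
})

test_that("classification table reproduces the 17-code worked example", {
  t2 <- fixture_table2()
  tab <- build_classification_table(t2$foodcodes, t2$products)
  counts <- table(tab$class)
  expect_equal(unname(counts["LCSB"]), 15)
  expect_equal(unname(counts["SB"]), 2)
  expect_false("MIXED" %in% names(counts))
  expect_equal(sort(tab$code[tab$class == "SB"]),
               c("92550380", "92552030"))
  expect_equal(nrow(build_classification_table(
    t2$foodcodes[0, ], t2$products)), 0)
})

test_that("classification table matches planted composition and a brute-force oracle", {
  cfg <- generator_config(seed = 7, n_codes = 50, frac_lcsb = 0.3,
                          frac_sb = 0.5, frac_mixed = 0.1,
                          frac_nonsweetened = 0.1)
  u <- gen_universe(cfg)
  tab <- build_classification_table(u$foodcodes, u$products,
                                    nonsweetened_codes = u$nonsweetened_codes)
  expect_equal(tab$class, u$truth$true_class[match(tab$code, u$truth$code)])

  # independent brute force: per code, textual LCS scan of known products
  lexicon <- strategy_config()$lcs_lexicon
  brute <- vapply(tab$code, function(cd) {
    if (cd %in% u$nonsweetened_codes) return("NONSWEETENED")
    p <- u$products[u$products$code == cd & u$products$ingredients_known, ]
    has <- vapply(tolower(p$ingredients), function(s) {
      any(vapply(lexicon, function(l) grepl(l, s, fixed = TRUE), logical(1)))
    }, logical(1))
    if (all(has)) "LCSB" else if (!any(has)) "SB" else "MIXED"
  }, character(1))
  expect_equal(tab$class, unname(brute))
})

test_that("strategy comparison reports published per-strategy totals", {
  t2 <- fixture_table2()
  tab <- build_classification_table(t2$foodcodes, t2$products)
  cmp <- compare_strategies(tab)
  expect_equal(unname(cmp$per_strategy["s2"]), 5)
  expect_equal(unname(cmp$per_strategy["s1"]), 0)
  expect_equal(unname(cmp$per_strategy["s4"]), 17)

  # Leahy criterion on database energies among LCS-containing codes
  kc <- kcal_per_serving(t2$foodcodes)
  leahy <- strategy3_caloric_density(kc, "LEAHY")
  expect_equal(sum(leahy[tab$class == "LCSB"]), 4)

  single <- tab[1, , drop = FALSE]
  cmp1 <- compare_strategies(single)
  expect_true(all(diag(cmp1$disagree) == 0))
  expect_true(all(diag(cmp1$agree) == 1))
})
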