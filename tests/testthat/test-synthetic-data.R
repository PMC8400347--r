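test_that("universe composition follows the configured fractions exactly", {
  cfg <- generator_config(seed = 2, n_codes = 300, frac_lcsb = 0.25,
                          frac_sb = 0.66, frac_mixed = 0.05,
                          frac_nonsweetened = 0.04)
  u <- gen_universe(cfg)
  counts <- table(u$truth$true_class[seq_len(300)])  # water rows excluded
  expect_equal(unname(counts["MIXED"]), 15)
  expect_equal(unname(counts["LCSB"]), 75)
  expect_equal(unname(counts["SB"]), 198)
  expect_equal(unname(counts["NONSWEETENED"]), 12)

  expect_error(generator_config(frac_mixed = 0.5, frac_sb = 0.21,
                                brands_per_code = c(1L, 1L)),
               "brands_per_code")
  expect_error(generator_config(frac_lcsb = 0.5), "sum to 1")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 99, n_codes = 40, n_participants = 60)
  u1 <- gen_universe(cfg); u2 <- gen_universe(cfg)
  expect_identical(u1, u2)
  p1 <- gen_population(cfg, u1); p2 <- gen_population(cfg, u2)
  expect_identical(p1, p2)

  cfg2 <- generator_config(seed = 100, n_codes = 40, n_participants = 60)
  u3 <- gen_universe(cfg2)
  expect_false(identical(u1$foodcodes$code, u3$foodcodes$code))
})

test_that("generated data satisfy every reader invariant", {
  cfg <- generator_config(seed = 12, n_codes = 50, n_participants = 80)
  u <- gen_universe(cfg)
  pop <- gen_population(cfg, u)
  # validators throw on any invariant violation
  expect_silent(validate_foodcode_table(u$foodcodes))
  expect_silent(validate_products(u$products))
  expect_silent(validate_recalls(pop$recalls))
  expect_silent(validate_participants(pop$participants))
  # mixed codes always have at least two products that disagree on LCS
  lex <- strategy_config()$lcs_lexicon
  for (cd in u$truth$code[u$truth$true_class == "MIXED"]) {
    p <- u$products[u$products$code == cd & u$products$ingredients_known, ]
    has <- vapply(find_lcs(p), function(x) length(x) > 0, logical(1))
    expect_true(any(has) && !all(has))
  }
})

test_that("noiseless populations are recovered exactly end to end", {
  cfg <- generator_config(seed = 8, n_codes = 60, n_participants = 400,
                          frac_lcsb = 0.3, frac_sb = 0.62, frac_mixed = 0,
                          frac_nonsweetened = 0.08,
                          noise_sd = c(energy_kcal = 0, carbohydrate_g = 0,
                                       total_sugar_g = 0, added_sugar_g = 0))
  u <- gen_universe(cfg)
  pop <- gen_population(cfg, u)
  tab <- build_classification_table(u$foodcodes, u$products,
                                    nonsweetened_codes = u$nonsweetened_codes)
  for (scen in c("MIXED_AS_LCSB", "MIXED_AS_SB")) {
    days <- participant_days(pop$participants, pop$recalls, tab,
                             u$foodcodes, scen)
    tru <- pop$truth[match(days$participant_id, pop$truth$participant_id), ]
    expect_equal(as.character(days$group), tru$true_group)
  }
  # planted effects are reproduced exactly by the model
  inputs <- list(foodcodes = u$foodcodes, products = u$products,
                 recalls = pop$recalls, participants = pop$participants,
                 nonsweetened_codes = u$nonsweetened_codes)
  res <- run_scenario(inputs, "MIXED_AS_LCSB", outcomes = "energy_kcal",
                      models = 1)
  ls <- res$results$energy_kcal$model1$lsm
  eff <- generator_config()$effect_sizes$energy_kcal
  diffs <- ls$lsm[match(names(eff), ls$group)] - ls$lsm[ls$group == "WATER"]
  expect_equal(unname(diffs), unname(eff - eff["WATER"]), tolerance = 1e-8)
})

test_that("degenerate group propensities break the group model informatively", {
  cfg <- generator_config(seed = 13, n_codes = 40, n_participants = 60,
                          group_propensities = c(WATER = 1, LCSB = 0, SB = 0,
                                                 LCSB_SB = 0, UNGROUPED = 0))
  u <- gen_universe(cfg)
  pop <- gen_population(cfg, u)
  inputs <- list(foodcodes = u$foodcodes, products = u$products,
                 recalls = pop$recalls, participants = pop$participants,
                 nonsweetened_codes = u$nonsweetened_codes)
  expect_error(run_scenario(inputs, "MIXED_AS_LCSB",
                            outcomes = "energy_kcal", models = 1))
})

test_that("the packaged worked-example fixture matches its published rows", {
  t2 <- fixture_table2()
  expect_equal(nrow(t2$foodcodes), 17)
  kc <- kcal_per_serving(t2$foodcodes)
  expect_equal(kc$kcal_per_8floz[kc$code == "92550040"], 46, tolerance = 0.001)
  snapple <- t2$products[t2$products$code == "92550040", ]
  expect_equal(snapple$kcal_per_8floz_mfr, 10)
  expect_equal(find_lcs(snapple)[[1]], "aspartame")
  capri <- t2$products[t2$products$code == "92552030", ]
  expect_equal(capri$kcal_per_8floz_mfr, 94)
  expect_length(find_lcs(capri)[[1]], 0)
  # one product could not be located: unknown, not LCS-free
  dole <- t2$products[t2$products$brand == "Dole Light", ]
  expect_false(dole$ingredients_known)
  expect_true(is.na(dole$kcal_per_8floz_mfr))

  t3 <- fixture_table3()
  expect_equal(t3$foodcodes$code, "92530610")
  expect_equal(kcal_per_serving(t3$foodcodes)$kcal_per_8floz, 114)
  has <- vapply(find_lcs(t3$products), function(x) length(x) > 0, logical(1))
  expect_true(any(has) && !all(has))
})
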