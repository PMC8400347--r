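#' Synthetic-universe and population generator configuration
#'
#' Controls a generator that emulates the structure of national dietary
#' surveillance data: a per-cycle foodcode universe with branded products
#' (including "mixed" codes whose products disagree on LCS content and
#' database-vs-manufacturer calorie discordance), and a child/adolescent
#' participant population with stratified cluster design, sampling weights,
#' recall items stored in grams, and outcomes with planted group effects.
#'
#' Defaults are chosen to mirror the magnitudes seen in national data:
#' about 3/4 of sweetened-beverage codes are sugary and a few percent are
#' mixed; conversion factors span 24-32 g/fl oz; about 3% of recalls have
#' a questionnaire-vs-items plain-water mismatch; and energy effects are
#' ordered water < LCSB < SB < LCSB+SB with a roughly 1560 kcal water-group
#' baseline.
#'
#' @param seed integer seed; identical configs produce identical output.
#' @param n_codes number of sweetened/nonsweetened beverage codes (the
#'   three plain-water codes are always appended on top).
#' @param frac_lcsb,frac_sb,frac_mixed,frac_nonsweetened universe
#'   composition; must sum to 1. Counts use largest-remainder rounding in
#'   the class order LCSB, SB, MIXED, NONSWEETENED.
#' @param brands_per_code integer range (min, max) of branded products per
#'   code; mixed codes require at least 2.
#' @param kcal_model list: `lcsb_mean_8floz`, `lcsb_sd`, `sb_mean_8floz`,
#'   `sb_sd`, `mfr_noise_sd` (additive manufacturer noise), and
#'   `discordance_prob` (probability a product's manufacturer energy is
#'   resampled from the opposite side of the 40 kcal/8 fl oz boundary).
#' @param conversion_factor_range grams per fl oz range.
#' @param n_participants population size.
#' @param group_propensities named probabilities over WATER, LCSB, SB,
#'   LCSB_SB, UNGROUPED.
#' @param outcome_baselines named water-group outcome means.
#' @param effect_sizes list per outcome of named additive group effects
#'   (relative to the water group).
#' @param noise_sd named residual standard deviations per outcome (may be
#'   0 for the noiseless limit).
#' @param n_strata,psus_per_stratum survey design dimensions.
#' @param weight_distribution lognormal `meanlog`/`sdlog` for weights.
#' @param water_mismatch_rate share of participants whose recall water
#'   items are perturbed away from the questionnaire value.
#' @param mixed_volume_share probability that an LCSB-side consumer's
#'   LCSB-type volume is consumed entirely through mixed foodcodes.
#'   Intended groups are realized exactly under the MIXED_AS_LCSB
#'   scenario; under MIXED_AS_SB these consumers shift toward the SB
#'   side, while the water group is unchanged.
#' @param explicit_desc_rate share of LCSB codes whose description carries
#'   an explicit "diet" marker.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_codes = 300L,
    frac_lcsb = 0.25, frac_sb = 0.66, frac_mixed = 0.05,
    frac_nonsweetened = 0.04,
    brands_per_code = c(1L, 4L),
    kcal_model = list(lcsb_mean_8floz = 8, lcsb_sd = 5,
                      sb_mean_8floz = 110, sb_sd = 25,
                      mfr_noise_sd = 3, discordance_prob = 0.1),
    conversion_factor_range = c(24, 32),
    n_participants = 2000L,
    group_propensities = c(WATER = 0.15, LCSB = 0.08, SB = 0.55,
                           LCSB_SB = 0.12, UNGROUPED = 0.10),
    outcome_baselines = c(energy_kcal = 1560, carbohydrate_g = 192,
                          total_sugar_g = 72, added_sugar_g = 33),
    effect_sizes = list(
      energy_kcal = c(WATER = 0, LCSB = 160, SB = 320, LCSB_SB = 490),
      carbohydrate_g = c(WATER = 0, LCSB = 34, SB = 60, LCSB_SB = 89),
      total_sugar_g = c(WATER = 0, LCSB = 24, SB = 46, LCSB_SB = 65),
      added_sugar_g = c(WATER = 0, LCSB = 27, SB = 36, LCSB_SB = 55)),
    noise_sd = c(energy_kcal = 450, carbohydrate_g = 60,
                 total_sugar_g = 35, added_sugar_g = 25),
    n_strata = 15L, psus_per_stratum = 2L,
    weight_distribution = c(meanlog = 0, sdlog = 0.5),
    water_mismatch_rate = 0.03,
    mixed_volume_share = 0,
    explicit_desc_rate = 0.2) {
  fracs <- c(frac_lcsb, frac_sb, frac_mixed, frac_nonsweetened)
  if (abs(sum(fracs) - 1) > 1e-8) {
    bc_stop("generator_config: composition fractions must sum to 1 (got %g)",
            sum(fracs))
  }
  if (any(fracs < 0)) bc_stop("generator_config: negative fraction")
  if (any(noise_sd < 0)) bc_stop("generator_config: noise_sd must be >= 0")
  if (frac_mixed > 0 && max(brands_per_code) < 2) {
    bc_stop("generator_config: mixed codes need brands_per_code max >= 2")
  }
  if (abs(sum(group_propensities) - 1) > 1e-8) {
    bc_stop("generator_config: group propensities must sum to 1")
  }
  if (water_mismatch_rate < 0 || water_mismatch_rate > 1) {
    bc_stop("generator_config: water_mismatch_rate must be in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed), n_codes = as.integer(n_codes),
    frac_lcsb = frac_lcsb, frac_sb = frac_sb, frac_mixed = frac_mixed,
    frac_nonsweetened = frac_nonsweetened,
    brands_per_code = as.integer(brands_per_code),
    kcal_model = kcal_model,
    conversion_factor_range = conversion_factor_range,
    n_participants = as.integer(n_participants),
    group_propensities = group_propensities,
    outcome_baselines = outcome_baselines,
    effect_sizes = effect_sizes, noise_sd = noise_sd,
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    weight_distribution = weight_distribution,
    water_mismatch_rate = water_mismatch_rate,
    mixed_volume_share = mixed_volume_share,
    explicit_desc_rate = explicit_desc_rate
  ), class = "generator_config")
}

# Largest-remainder apportionment of n into length(fracs) classes, ties
# broken by class order.
apportion <- function(n, fracs) {
  raw <- n * fracs
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, seq_along(fracs), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

water_foodcode_rows <- function(cycle) {
  data.frame(
    code = c("94000100", "94100100", "94300100"),
    cycle = cycle,
    main_description = c("Water, tap (synthetic)",
                         "Water, bottled, unsweetened (synthetic)",
                         "Water, nursery (synthetic)"),
    additional_description = "",
    wweia_category = 9999L,
    kcal_per_100g = 0,
    grams_per_floz = 29.6,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic foodcode universe with branded products
#'
#' Draws `n_codes` beverage codes with the configured class composition,
#' database energy densities, conversion factors, and branded products
#' whose ingredient lists realize each code's true class: LCSB codes have
#' an LCS in every product (sometimes alongside sugar), SB codes in none,
#' and mixed codes in some but not all. Manufacturer energies carry noise
#' plus occasional large discordance across the 40 kcal/8 fl oz boundary.
#' The three plain-water codes are appended as nonsweetened.
#'
#' @param cfg [generator_config()].
#' @param cycle cycle label for the generated tables.
#' @return list with `foodcodes`, `products`, `truth` (data.frame `code`,
#'   `true_class`), and `nonsweetened_codes`.
#' @export
gen_universe <- function(cfg = generator_config(), cycle = "synthetic-cycle") {
  set.seed(cfg$seed)
  n <- cfg$n_codes
  counts <- apportion(n, c(cfg$frac_lcsb, cfg$frac_sb, cfg$frac_mixed,
                           cfg$frac_nonsweetened))
  classes <- rep(c("LCSB", "SB", "MIXED", "NONSWEETENED"), counts)
  classes <- sample(classes)

  codes <- sprintf("92%06d", sample.int(999999L, n))
  fac <- stats::runif(n, cfg$conversion_factor_range[1],
                      cfg$conversion_factor_range[2])
  km <- cfg$kcal_model
  kcal8 <- numeric(n)
  kcal8[classes == "LCSB"] <- pmax(0, stats::rnorm(sum(classes == "LCSB"),
                                                   km$lcsb_mean_8floz,
                                                   km$lcsb_sd))
  kcal8[classes == "SB"] <- pmax(45, stats::rnorm(sum(classes == "SB"),
                                                  km$sb_mean_8floz, km$sb_sd))
  kcal8[classes == "MIXED"] <- pmax(30, stats::rnorm(sum(classes == "MIXED"),
                                                     0.8 * km$sb_mean_8floz,
                                                     km$sb_sd))
  kcal8[classes == "NONSWEETENED"] <- 0
  kcal100 <- kcal8 * 12.5 / fac

  flavors <- c("fruit punch", "citrus", "berry", "grape", "tropical",
               "apple", "cherry", "cola type")
  main_desc <- sprintf("Synthetic beverage, %s, code %s",
                       sample(flavors, n, replace = TRUE), codes)
  is_explicit <- classes == "LCSB" &
    stats::runif(n) < cfg$explicit_desc_rate
  main_desc[is_explicit] <- paste0(main_desc[is_explicit], ", diet")
  cat_pool <- list(LCSB = c(7102L, 7104L, 7106L, 7204L),
                   SB = c(7202L, 7204L, 7206L),
                   MIXED = c(7204L, 7206L),
                   NONSWEETENED = c(7004L, 7302L))
  wweia <- vapply(classes, function(cl) {
    pool <- cat_pool[[cl]]
    pool[sample.int(length(pool), 1)]
  }, integer(1))

  foodcodes <- data.frame(
    code = codes, cycle = cycle, main_description = main_desc,
    additional_description = "", wweia_category = wweia,
    kcal_per_100g = kcal100, grams_per_floz = fac,
    stringsAsFactors = FALSE)
  foodcodes <- rbind(foodcodes, water_foodcode_rows(cycle))
  foodcodes <- validate_foodcode_table(foodcodes)

  lcs_pool <- c("aspartame", "sucralose", "acesulfame potassium", "stevia",
                "neotame")
  sugar_pool <- c("sugar", "high fructose corn syrup", "cane syrup")
  prods <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    nb <- sample(seq(cfg$brands_per_code[1], cfg$brands_per_code[2]), 1)
    if (cl == "MIXED") nb <- max(nb, 2L)
    with_lcs <- switch(cl,
      LCSB = rep(TRUE, nb),
      SB = rep(FALSE, nb),
      NONSWEETENED = rep(FALSE, nb),
      MIXED = {
        v <- stats::runif(nb) < 0.5
        v[1] <- TRUE; v[2] <- FALSE
        v
      })
    ing <- vapply(seq_len(nb), function(j) {
      base <- c("water", "citric acid", "natural flavor")
      if (cl == "NONSWEETENED") return(paste(base, collapse = "; "))
      sweet <- if (with_lcs[j]) {
        s <- sample(lcs_pool, sample(1:2, 1))
        if (stats::runif(1) < 0.2) s <- c(sample(sugar_pool, 1), s)
        s
      } else {
        sample(sugar_pool, 1)
      }
      paste(c(base[1], sweet, base[-1]), collapse = "; ")
    }, character(1))
    known <- stats::runif(nb) >= 0.05
    known[1] <- TRUE  # never leave a code without usable evidence
    if (cl == "MIXED") known[1:2] <- TRUE
    mfr <- pmax(0, kcal8[i] + stats::rnorm(nb, 0, km$mfr_noise_sd))
    discord <- stats::runif(nb) < km$discordance_prob
    if (any(discord)) {
      mfr[discord] <- if (kcal8[i] < 40) {
        stats::runif(sum(discord), 45, 120)
      } else {
        stats::runif(sum(discord), 5, 35)
      }
    }
    ing[!known] <- ""
    prods[[i]] <- data.frame(
      brand = sprintf("Brand %s-%d", codes[i], seq_len(nb)),
      code = codes[i], cycle = cycle, ingredients = ing,
      kcal_per_8floz_mfr = mfr, ingredients_known = known,
      stringsAsFactors = FALSE)
  }
  products <- validate_products(do.call(rbind, prods))

  truth <- data.frame(code = c(codes, water_foodcode_rows(cycle)$code),
                      true_class = c(classes, rep("NONSWEETENED", 3)),
                      stringsAsFactors = FALSE)
  list(foodcodes = foodcodes, products = products, truth = truth,
       nonsweetened_codes = truth$code[truth$true_class == "NONSWEETENED"])
}

#' Generate a synthetic participant population with recalls
#'
#' Each participant draws an intended consumer group from the configured
#' propensities; beverage volumes are then placed on the correct side of
#' the 4-oz thresholds so that the pipeline recovers the intended group
#' exactly under the `MIXED_AS_LCSB` scenario (when
#' `mixed_volume_share > 0`, a share of LCSB-side consumers drink their
#' LCSB-type volume through mixed codes instead). Volumes
#' are drawn in fluid ounces and stored as grams via each code's own
#' conversion factor, so the pipeline's unit bridge is genuinely
#' exercised. Outcomes are group effect + age/sex trends + Gaussian noise;
#' a configured share of participants gets recall water items perturbed
#' away from the questionnaire value.
#'
#' @param cfg [generator_config()].
#' @param universe result of [gen_universe()].
#' @return list with `participants`, `recalls`, and `truth` (participant
#'   id, intended group, and per-outcome true means).
#' @export
gen_population <- function(cfg = generator_config(),
                           universe = gen_universe(cfg)) {
  set.seed((cfg$seed + 77003L) %% .Machine$integer.max)
  n <- cfg$n_participants
  id <- sprintf("P%06d", seq_len(n))

  age <- sample(2:17, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  race <- sample(c("nh-white", "nh-black", "hispanic", "other"), n,
                 replace = TRUE)
  income <- sample(c("low", "middle", "high"), n, replace = TRUE)
  pa <- sample(c("low", "moderate", "high"), n, replace = TRUE)
  bmi <- stats::runif(n, 1, 99)
  diabetes <- stats::runif(n) < 0.01
  reliable <- stats::runif(n) >= 0.02
  stratum <- sample(cfg$n_strata, n, replace = TRUE)
  psu <- sample(cfg$psus_per_stratum, n, replace = TRUE)
  wdist <- cfg$weight_distribution
  weight <- stats::rlnorm(n, wdist["meanlog"], wdist["sdlog"])

  groups <- names(cfg$group_propensities)
  g <- sample(groups, n, replace = TRUE, prob = cfg$group_propensities)

  lcsb_oz <- sb_oz <- mixed_oz <- water_oz <- numeric(n)
  small <- function(m) stats::runif(m, 0, 3.5)
  big <- function(m) stats::runif(m, 4.5, 30)
  for (grp in groups) {
    idx <- which(g == grp)
    m <- length(idx)
    if (m == 0) next
    switch(grp,
      WATER = {
        water_oz[idx] <- stats::runif(m, 4.5, 40)
        lcsb_oz[idx] <- small(m); sb_oz[idx] <- small(m)
      },
      LCSB = {
        lcsb_oz[idx] <- big(m); sb_oz[idx] <- small(m)
        water_oz[idx] <- stats::runif(m, 0, 40)
      },
      SB = {
        sb_oz[idx] <- big(m); lcsb_oz[idx] <- small(m)
        water_oz[idx] <- stats::runif(m, 0, 40)
      },
      LCSB_SB = {
        lcsb_oz[idx] <- big(m); sb_oz[idx] <- big(m)
        water_oz[idx] <- stats::runif(m, 0, 40)
      },
      UNGROUPED = {
        lcsb_oz[idx] <- small(m); sb_oz[idx] <- small(m)
        water_oz[idx] <- small(m)
      })
  }
  # A share of LCSB-side consumers drink their LCSB-type volume entirely as
  # mixed-code beverages. Routing whole participants (not volume slivers)
  # mirrors how mixed codes are consumed in practice and keeps the water
  # group scenario-invariant: a mixed-code consumer carries >= 4 oz of
  # mixed volume and so is never a water consumer under either scenario.
  mixed_codes <- universe$truth$code[universe$truth$true_class == "MIXED"]
  if (cfg$mixed_volume_share > 0 && length(mixed_codes) > 0) {
    cand <- which(g %in% c("LCSB", "LCSB_SB"))
    sel <- cand[stats::runif(length(cand)) < cfg$mixed_volume_share]
    mixed_oz[sel] <- lcsb_oz[sel]
    lcsb_oz[sel] <- 0
  }

  age_coef <- c(energy_kcal = 25, carbohydrate_g = 3, total_sugar_g = 1.5,
                added_sugar_g = 1)
  sex_coef <- c(energy_kcal = 80, carbohydrate_g = 10, total_sugar_g = 4,
                added_sugar_g = 2)
  outcomes <- names(cfg$outcome_baselines)
  truth <- data.frame(participant_id = id, true_group = g,
                      stringsAsFactors = FALSE)
  out_cols <- list()
  for (oc in outcomes) {
    eff <- cfg$effect_sizes[[oc]]
    mu <- cfg$outcome_baselines[[oc]] +
      ifelse(g %in% names(eff), eff[g], 0) +
      age_coef[[oc]] * (age - 9.5) +
      sex_coef[[oc]] * (sex == "male")
    out_cols[[oc]] <- mu + stats::rnorm(n, 0, cfg$noise_sd[[oc]])
    truth[[paste0("mu_", oc)]] <- mu
  }

  participants <- data.frame(
    participant_id = id, age_years = age, sex = sex, race_ethnicity = race,
    income = income, physical_activity = pa, bmi_percentile = bmi,
    diabetes_dx = diabetes, reliable_recall = reliable,
    questionnaire_water_g = water_oz * 29.6,
    stratum_id = stratum, psu_id = psu, weight = weight,
    stringsAsFactors = FALSE)
  for (oc in outcomes) participants[[oc]] <- out_cols[[oc]]

  # recall items: split each nonzero class volume over two sampled codes
  tr <- universe$truth
  fc <- universe$foodcodes
  class_codes <- list(
    lcsb = tr$code[tr$true_class == "LCSB"],
    sb = tr$code[tr$true_class == "SB"],
    mixed = mixed_codes,
    water = c("94000100", "94100100", "94300100"))
  vol_of <- list(lcsb = lcsb_oz, sb = sb_oz, mixed = mixed_oz,
                 water = water_oz)
  items <- list()
  for (cl in names(class_codes)) {
    pool <- class_codes[[cl]]
    vol <- vol_of[[cl]]
    idx <- which(vol > 0)
    if (length(idx) == 0 || length(pool) == 0) next
    frac <- stats::runif(length(idx), 0.2, 0.8)
    c1 <- sample(pool, length(idx), replace = TRUE)
    c2 <- sample(pool, length(idx), replace = TRUE)
    f1 <- fc$grams_per_floz[match(c1, fc$code)]
    f2 <- fc$grams_per_floz[match(c2, fc$code)]
    items[[paste0(cl, "1")]] <- data.frame(
      participant_id = id[idx], code = c1,
      grams = vol[idx] * frac * f1, stringsAsFactors = FALSE)
    items[[paste0(cl, "2")]] <- data.frame(
      participant_id = id[idx], code = c2,
      grams = vol[idx] * (1 - frac) * f2, stringsAsFactors = FALSE)
  }
  recalls <- do.call(rbind, items)
  rownames(recalls) <- NULL

  # plant questionnaire-vs-recall water mismatches
  mism <- which(stats::runif(n) < cfg$water_mismatch_rate & water_oz > 0)
  if (length(mism) > 0) {
    tgt <- id[mism]
    first_water <- which(recalls$code %in% class_codes$water &
                         recalls$participant_id %in% tgt)
    first_water <- first_water[!duplicated(recalls$participant_id[first_water])]
    shift <- stats::runif(length(first_water), 10, 120) *
      sample(c(-1, 1), length(first_water), replace = TRUE)
    recalls$grams[first_water] <- pmax(0, recalls$grams[first_water] + shift)
  }
  truth$water_mismatch <- id %in% id[mism]

  list(participants = validate_participants(participants),
       recalls = validate_recalls(recalls),
       truth = truth)
}
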