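#' Strategy configuration
#'
#' Bundles the term lists, category sets, and lexicon used by the four
#' published LCSB-identification strategies and the ingredient-based
#' reference classifier. Defaults reproduce the published settings; every
#' piece is overridable because the original analyses themselves disagreed
#' on the exact term lists.
#'
#' @param strategy1_prefix foodcode prefix for the database-organization
#'   strategy (carbonated soft drinks start with "924").
#' @param strategy1_terms description terms that mark a prefix-matched code
#'   as a diet drink.
#' @param strategy2_categories survey food-category codes treated as diet
#'   beverage categories (7102 diet soft drinks, 7104 diet sport and energy
#'   drinks, 7106 other diet drinks).
#' @param strategy3_criterion caloric-density criterion: `"FDA_LOW"`
#'   (<40 kcal/8 fl oz), `"FDA_NO"` (<5), `"LEAHY"` (<6.7), or `"MAILLOT"`
#'   (<50 kcal/240 g).
#' @param strategy3_kcal_source `"FNDDS"` (database energy density) or
#'   `"MANUFACTURER"` (label energy per 8 fl oz).
#' @param strategy4_terms description terms for the text-search strategy.
#' @param lcs_lexicon recognized low-calorie sweetener ingredient names.
#' @param explicit_lcs_terms the subset of description terms strong enough
#'   to classify a code as LCS-containing without ingredient evidence.
#'   Deliberately excludes "light", "reduced sugar", and "less sugar":
#'   products carrying those labels demonstrably exist without any LCS.
#' @return an object of class `strategy_config` (a named list).
#' @export
strategy_config <- function(
    strategy1_prefix = "924",
    strategy1_terms = c("sugar-free", "reduced sugar", "low-calorie sweetener",
                        "no-calorie sweetener"),
    strategy2_categories = c(7102L, 7104L, 7106L),
    strategy3_criterion = c("FDA_LOW", "FDA_NO", "LEAHY", "MAILLOT"),
    strategy3_kcal_source = c("FNDDS", "MANUFACTURER"),
    strategy4_terms = c("diet", "dietetic", "low-calorie", "no sugar added",
                        "light", "lite", "sugar-free", "sugar substitute",
                        "low-calorie sweetener", "no-calorie sweetener",
                        "reduced sugar", "less sugar", "zero calorie"),
    lcs_lexicon = c("aspartame", "sucralose", "acesulfame potassium", "acek",
                    "saccharin", "neotame", "advantame", "stevia",
                    "steviol glycosides", "rebaudioside a", "reba", "rebiana",
                    "monk fruit", "luo han guo"),
    explicit_lcs_terms = c("low-calorie sweetener", "no-calorie sweetener",
                           "sugar-free", "diet", "dietetic",
                           "artificial sweetener")) {
  structure(list(
    strategy1_prefix = strategy1_prefix,
    strategy1_terms = strategy1_terms,
    strategy2_categories = as.integer(strategy2_categories),
    strategy3_criterion = match.arg(strategy3_criterion),
    strategy3_kcal_source = match.arg(strategy3_kcal_source),
    strategy4_terms = strategy4_terms,
    lcs_lexicon = lcs_lexicon,
    explicit_lcs_terms = explicit_lcs_terms
  ), class = "strategy_config")
}

#' Energy per serving from database values
#'
#' Bridges the database's energy density (kcal/100 g) and conversion factor
#' (g/fl oz) to the two serving bases used by caloric-density criteria:
#' kcal per 8 fl oz (volume) and kcal per 240 g (mass). The mass basis does
#' not involve the fl-oz factor at all:
#' `kcal_per_8floz = kcal_per_100g * 8 * grams_per_floz / 100` and
#' `kcal_per_240g = kcal_per_100g * 2.4`.
#'
#' @param foodcodes validated foodcode table (any number of rows).
#' @return data.frame with `code`, `kcal_per_8floz`, `kcal_per_240g`, and
#'   `source = "FNDDS"`.
#' @export
#' @examples
#' fc <- data.frame(code = "92550040", cycle = "x", main_description = "d",
#'                  additional_description = "", wweia_category = 7204,
#'                  kcal_per_100g = 19.18, grams_per_floz = 30)
#' kcal_per_serving(fc)
kcal_per_serving <- function(foodcodes) {
  if (anyNA(foodcodes$grams_per_floz)) {
    bc_stop("kcal_per_serving: missing conversion factor for foodcode %s",
            foodcodes$code[which(is.na(foodcodes$grams_per_floz))[1]])
  }
  if (anyNA(foodcodes$kcal_per_100g)) {
    bc_stop("kcal_per_serving: missing kcal_per_100g for foodcode %s",
            foodcodes$code[which(is.na(foodcodes$kcal_per_100g))[1]])
  }
  data.frame(
    code = foodcodes$code,
    kcal_per_8floz = foodcodes$kcal_per_100g * 8 * foodcodes$grams_per_floz / 100,
    kcal_per_240g = foodcodes$kcal_per_100g * 2.4,
    source = "FNDDS",
    stringsAsFactors = FALSE
  )
}

#' Strategy 1: database organization (foodcode prefix + description terms)
#'
#' Flags a code as a diet beverage when its foodcode starts with the
#' carbonated-soft-drink prefix *and* its description carries one of the
#' diet-style terms. Identifies very few codes by construction.
#'
#' @param foodcodes validated foodcode table.
#' @param cfg [strategy_config()].
#' @return logical vector, one element per row.
#' @export
strategy1_fndds_prefix <- function(foodcodes, cfg = strategy_config()) {
  prefix_hit <- startsWith(foodcodes$code, cfg$strategy1_prefix)
  desc <- paste(foodcodes$main_description, foodcodes$additional_description)
  prefix_hit & matches_terms(desc, cfg$strategy1_terms)
}

#' Strategy 2: survey diet-beverage categories
#'
#' Flags codes whose food-category assignment is one of the diet beverage
#' categories.
#'
#' @param foodcodes validated foodcode table.
#' @param cfg [strategy_config()].
#' @return logical vector, one element per row.
#' @export
strategy2_wweia <- function(foodcodes, cfg = strategy_config()) {
  as.integer(foodcodes$wweia_category) %in% cfg$strategy2_categories
}

#' Strategy 3: caloric density
#'
#' Applies one of four published caloric-density criteria with strict
#' inequalities. `kcal` rows whose required field is `NA` yield `NA`
#' (explicitly unknown), never `FALSE`.
#'
#' @param kcal data.frame with columns `kcal_per_8floz` and/or
#'   `kcal_per_240g` (e.g. from [kcal_per_serving()]).
#' @param criterion one of `"FDA_LOW"`, `"FDA_NO"`, `"LEAHY"`, `"MAILLOT"`.
#' @param th [thresholds()].
#' @return logical vector (with `NA` for unknown energy values).
#' @export
strategy3_caloric_density <- function(kcal,
                                      criterion = c("FDA_LOW", "FDA_NO",
                                                    "LEAHY", "MAILLOT"),
                                      th = thresholds()) {
  criterion <- match.arg(criterion)
  switch(criterion,
    FDA_LOW = kcal$kcal_per_8floz < th$fda_low_kcal_per_8floz,
    FDA_NO  = kcal$kcal_per_8floz < th$fda_no_kcal_per_8floz,
    LEAHY   = kcal$kcal_per_8floz < th$leahy_kcal_per_8floz,
    MAILLOT = kcal$kcal_per_240g < th$maillot_kcal_per_240g)
}

#' Strategy 4: text search of foodcode descriptions
#'
#' Flags codes whose main or additional description contains at least one
#' of the configured terms, under whole-token matching (so "diet" does not
#' fire on "Dietary supplement") with hyphen/space variants equivalent.
#'
#' @param foodcodes validated foodcode table.
#' @param cfg [strategy_config()].
#' @return logical vector, one element per row.
#' @export
strategy4_text <- function(foodcodes, cfg = strategy_config()) {
  matches_terms(foodcodes$main_description, cfg$strategy4_terms) |
    matches_terms(foodcodes$additional_description, cfg$strategy4_terms)
}

#' Recognized low-calorie sweeteners in ingredient lists
#'
#' Matches the configured LCS lexicon against each product's normalized
#' ingredient list. Products flagged `ingredients_known = FALSE` get `NA`
#' (undefined), not an empty result.
#'
#' @param products validated product table.
#' @param cfg [strategy_config()].
#' @return list (one element per product row) of character vectors of
#'   matched lexicon entries; `NA` elements where ingredients are unknown.
#' @export
find_lcs <- function(products, cfg = strategy_config()) {
  ing_lists <- split_ingredients(products$ingredients)
  lapply(seq_len(nrow(products)), function(i) {
    if (!products$ingredients_known[i]) return(NA_character_)
    ings <- ing_lists[[i]]
    if (length(ings) == 0) return(character(0))
    hits <- cfg$lcs_lexicon[vapply(cfg$lcs_lexicon, function(lcs) {
      any(matches_terms(ings, lcs))
    }, logical(1))]
    unname(hits)
  })
}

#' Ingredient-based reference classification of one foodcode
#'
#' The reference rule examined each foodcode cycle by cycle: a code is
#' `LCSB` if its description explicitly indicates an LCS or if every
#' branded product with a known ingredient list contains at least one LCS
#' (a product listing both sugar and an LCS counts as LCS-containing);
#' `SB` if no known product contains an LCS; and `MIXED` if some but not
#' all do. Products with unknown ingredient lists are excluded from the
#' tally but recorded in the provenance; if they are the only evidence and
#' the description is not explicit, classification fails rather than
#' guessing. When an explicit description contradicts unanimous ingredient
#' evidence, the ingredients win and the conflict is logged.
#'
#' @param code 8-digit foodcode (character or numeric).
#' @param cycle survey-cycle label.
#' @param products validated product table (rows for other codes/cycles are
#'   ignored).
#' @param rec one-row foodcode table for this code (used for the
#'   description); may be `NULL` when only products should decide.
#' @param cfg [strategy_config()].
#' @return list with elements `class` (one of `"LCSB"`, `"SB"`, `"MIXED"`)
#'   and `provenance` (a human-readable reason string).
#' @export
classify_by_ingredients <- function(code, cycle, products, rec = NULL,
                                    cfg = strategy_config()) {
  code <- as.character(code)
  prods <- products[products$code == code & products$cycle == cycle, ,
                    drop = FALSE]
  prods <- prods[!duplicated(paste(prods$brand, prods$ingredients)), ,
                 drop = FALSE]

  explicit <- FALSE
  if (!is.null(rec) && nrow(rec) > 0) {
    desc <- paste(rec$main_description[1], rec$additional_description[1])
    explicit <- matches_terms(desc, cfg$explicit_lcs_terms)
  }

  lcs <- find_lcs(prods, cfg)
  known <- !vapply(lcs, function(x) length(x) == 1 && is.na(x[1]), logical(1))
  n_known <- sum(known)
  n_unknown <- nrow(prods) - n_known
  has_lcs <- vapply(lcs[known], function(x) length(x) > 0, logical(1))

  note_unknown <- if (n_unknown > 0) {
    sprintf("; %d product(s) with unknown ingredients excluded", n_unknown)
  } else ""

  if (n_known == 0) {
    if (explicit) {
      return(list(class = "LCSB",
                  provenance = paste0("explicit LCS description; no usable ",
                                      "ingredient evidence", note_unknown)))
    }
    bc_stop(paste0("cannot classify foodcode %s (%s): all products have ",
                   "unknown ingredients and description is not explicit"),
            code, cycle)
  }

  if (all(has_lcs)) {
    list(class = "LCSB",
         provenance = sprintf("all %d product(s) with known ingredients list an LCS%s",
                              n_known, note_unknown))
  } else if (!any(has_lcs)) {
    prov <- sprintf("no LCS in any of %d product(s) with known ingredients%s",
                    n_known, note_unknown)
    if (explicit) {
      prov <- paste0(prov, "; CONFLICT: explicit description overridden by ",
                     "ingredient evidence")
    }
    list(class = "SB", provenance = prov)
  } else {
    prov <- sprintf("%d of %d product(s) with known ingredients list an LCS%s",
                    sum(has_lcs), n_known, note_unknown)
    if (explicit) {
      prov <- paste0(prov, "; CONFLICT: explicit description overridden by ",
                     "mixed ingredient evidence")
    }
    list(class = "MIXED", provenance = prov)
  }
}

#' Build the full classification table for one cycle
#'
#' Produces, for every foodcode in the input table, the ingredient-based
#' class (`LCSB`/`SB`/`MIXED`/`NONSWEETENED`) together with the boolean
#' flags of the four published strategies and a provenance string. Codes in
#' `nonsweetened_codes` (plain and unsweetened carbonated waters,
#' unsweetened teas and coffees, ...) are labeled `NONSWEETENED` and skip
#' the ingredient logic; the databases themselves provide no flag for this,
#' so the set is an explicit input.
#'
#' When `strategy3_kcal_source = "MANUFACTURER"`, a code's strategy-3 flag
#' uses the lowest known manufacturer energy among its products (a code
#' counts as low-calorie if any branded product under it meets the
#' criterion); codes with no known manufacturer value get `NA`.
#'
#' @param foodcodes validated foodcode table (one cycle).
#' @param products validated product table.
#' @param cfg [strategy_config()].
#' @param th [thresholds()].
#' @param nonsweetened_codes character vector of foodcodes to label
#'   `NONSWEETENED`.
#' @param on_unclassifiable `"error"` (default) or `"warn"`; with `"warn"`,
#'   codes that cannot be classified get class `NA` and a warning.
#' @return data.frame of class `classification_table` with columns `code`,
#'   `cycle`, `class`, `s1`, `s2`, `s3`, `s4`, `provenance`.
#' @export
build_classification_table <- function(foodcodes, products,
                                       cfg = strategy_config(),
                                       th = thresholds(),
                                       nonsweetened_codes = character(0),
                                       on_unclassifiable = c("error", "warn")) {
  on_unclassifiable <- match.arg(on_unclassifiable)
  n <- nrow(foodcodes)
  if (n == 0) {
    out <- data.frame(code = character(0), cycle = character(0),
                      class = character(0), s1 = logical(0), s2 = logical(0),
                      s3 = logical(0), s4 = logical(0),
                      provenance = character(0), stringsAsFactors = FALSE)
    class(out) <- c("classification_table", "data.frame")
    return(out)
  }

  s1 <- strategy1_fndds_prefix(foodcodes, cfg)
  s2 <- strategy2_wweia(foodcodes, cfg)
  s4 <- strategy4_text(foodcodes, cfg)

  if (cfg$strategy3_kcal_source == "FNDDS") {
    kc <- kcal_per_serving(foodcodes)
  } else {
    mfr <- vapply(seq_len(n), function(i) {
      v <- products$kcal_per_8floz_mfr[products$code == foodcodes$code[i] &
                                       products$cycle == foodcodes$cycle[i]]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else min(v)
    }, numeric(1))
    kc <- data.frame(code = foodcodes$code,
                     kcal_per_8floz = mfr,
                     kcal_per_240g = mfr * 30 / foodcodes$grams_per_floz,
                     source = "MANUFACTURER", stringsAsFactors = FALSE)
  }
  s3 <- strategy3_caloric_density(kc, cfg$strategy3_criterion, th)

  cls <- character(n)
  prov <- character(n)
  nonsweetened_codes <- as.character(nonsweetened_codes)
  for (i in seq_len(n)) {
    if (foodcodes$code[i] %in% nonsweetened_codes) {
      cls[i] <- "NONSWEETENED"
      prov[i] <- "listed in the configured nonsweetened code set"
      next
    }
    res <- tryCatch(
      classify_by_ingredients(foodcodes$code[i], foodcodes$cycle[i],
                              products, foodcodes[i, , drop = FALSE], cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (on_unclassifiable == "error") stop(res)
      warning(conditionMessage(res), call. = FALSE)
      cls[i] <- NA_character_
      prov[i] <- "unclassifiable"
    } else {
      cls[i] <- res$class
      prov[i] <- res$provenance
    }
  }

  out <- data.frame(code = foodcodes$code, cycle = foodcodes$cycle,
                    class = cls, s1 = s1, s2 = s2, s3 = s3, s4 = s4,
                    provenance = prov, stringsAsFactors = FALSE)
  class(out) <- c("classification_table", "data.frame")
  out
}

#' Cross-strategy comparison
#'
#' Summarizes how the four published strategies overlap on a classified
#' universe: per-strategy LCSB totals and, for every strategy pair, the
#' number of codes on which the two flags agree and disagree (`NA` flags
#' are treated as not flagged for counting).
#'
#' @param tab a `classification_table` from [build_classification_table()].
#' @return list with `n_codes`, `per_strategy` (named integer vector),
#'   `class_counts` (table of ingredient classes), `agree` and `disagree`
#'   (4x4 integer matrices).
#' @export
compare_strategies <- function(tab) {
  flags <- cbind(s1 = tab$s1, s2 = tab$s2, s3 = tab$s3, s4 = tab$s4)
  flags[is.na(flags)] <- FALSE
  k <- ncol(flags)
  agree <- disagree <- matrix(0L, k, k, dimnames = list(colnames(flags),
                                                        colnames(flags)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      agree[i, j] <- sum(flags[, i] == flags[, j])
      disagree[i, j] <- sum(flags[, i] != flags[, j])
    }
  }
  list(n_codes = nrow(tab),
       per_strategy = colSums(flags),
       class_counts = table(factor(tab$class,
                                   levels = c("LCSB", "SB", "MIXED",
                                              "NONSWEETENED"))),
       agree = agree,
       disagree = disagree)
}
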