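#' Convert beverage mass to volume
#'
#' Dietary files store intake in grams; group assignment works in fluid
#' ounces. Each foodcode carries its own grams-per-fluid-ounce factor
#' because beverage densities differ (LCS-sweetened drinks are less dense
#' than sugar-sweetened ones, e.g. 30 vs 31 g/fl oz), so using a single
#' factor biases volume comparisons between beverage classes.
#'
#' @param grams mass in grams (vectorized).
#' @param factor grams per fluid ounce (vectorized, must be > 0).
#' @return volume in fluid ounces.
#' @export
#' @examples
#' grams_to_floz(29.6, 29.6)  # 1 fl oz of plain water
grams_to_floz <- function(grams, factor) {
  if (any(!is.finite(factor) | factor <= 0)) {
    bc_stop("grams_to_floz: conversion factor must be > 0")
  }
  grams / factor
}

#' Analysis-population eligibility
#'
#' Children and adolescents aged 2 to 17 with one reliable in-person
#' dietary recall and no physician diagnosis of diabetes.
#'
#' @param participants validated participant table.
#' @return logical vector, one element per participant.
#' @export
eligibility_filter <- function(participants) {
  participants$age_years >= 2 & participants$age_years <= 17 &
    participants$reliable_recall & !participants$diabetes_dx
}

#' Plain-water intake with discrepancy flagging
#'
#' Plain water comes from the dietary questionnaire variable (total plain
#' water drunk on the recall day, in grams), converted at the plain-water
#' density of 29.6 g/fl oz. As a data-quality check, the questionnaire
#' value is compared against the sum of recall grams over the three
#' plain-water foodcodes; in national data the two disagree for a small
#' share of recalls, so mismatches beyond `tolerance_g` are flagged rather
#' than silently accepted.
#'
#' @param participants validated participant table.
#' @param recalls validated recall items (may be `NULL` to skip the check).
#' @param water_codes foodcodes whose recall grams should equal the
#'   questionnaire value (tap, bottled, and nursery water).
#' @param th [thresholds()] (supplies the water density).
#' @param tolerance_g absolute tolerance in grams for the discrepancy flag.
#' @return data.frame with `participant_id`, `oz_water`, and
#'   `water_discrepancy`.
#' @export
water_intake <- function(participants, recalls = NULL,
                         water_codes = c("94000100", "94100100", "94300100"),
                         th = thresholds(), tolerance_g = 1) {
  q <- participants$questionnaire_water_g
  if (anyNA(q) || any(q < 0)) {
    bc_stop("water_intake: questionnaire plain-water grams must be present and >= 0")
  }
  oz <- grams_to_floz(q, th$water_g_per_floz)
  flag <- rep(FALSE, nrow(participants))
  if (!is.null(recalls)) {
    wr <- recalls[recalls$code %in% as.character(water_codes), , drop = FALSE]
    sums <- tapply(wr$grams, wr$participant_id, sum)
    recalled <- unname(sums[match(participants$participant_id, names(sums))])
    recalled[is.na(recalled)] <- 0
    flag <- abs(q - recalled) > tolerance_g
  }
  data.frame(participant_id = participants$participant_id,
             oz_water = oz, water_discrepancy = flag,
             stringsAsFactors = FALSE)
}

#' Per-participant beverage volumes by sweetener class
#'
#' Sums each participant's recall items into fluid-ounce totals per
#' ingredient class (`LCSB`, `SB`, `MIXED`), converting every item with its
#' own foodcode-specific factor. Items on `NONSWEETENED` codes contribute
#' nothing (plain water is measured from the questionnaire instead, and
#' unsweetened carbonated water is deliberately not counted as water).
#'
#' @param recalls validated recall items.
#' @param tab `classification_table` for the same cycle.
#' @param foodcodes validated foodcode table (source of conversion factors).
#' @return data.frame with one row per participant appearing in `recalls`:
#'   `participant_id`, `oz_lcsb`, `oz_sb`, `oz_mixed`.
#' @export
beverage_totals <- function(recalls, tab, foodcodes) {
  orphans <- setdiff(unique(recalls$code), tab$code)
  if (length(orphans) > 0) {
    bc_stop("beverage_totals: recall foodcode(s) absent from the classification table: %s",
            paste(sort(orphans), collapse = ", "))
  }
  no_factor <- setdiff(unique(recalls$code), foodcodes$code)
  if (length(no_factor) > 0) {
    bc_stop("beverage_totals: no conversion factor for foodcode(s): %s",
            paste(sort(no_factor), collapse = ", "))
  }
  cls <- tab$class[match(recalls$code, tab$code)]
  fac <- foodcodes$grams_per_floz[match(recalls$code, foodcodes$code)]
  oz <- grams_to_floz(recalls$grams, fac)

  ids <- unique(recalls$participant_id)
  sum_class <- function(which_class) {
    keep <- !is.na(cls) & cls == which_class
    s <- tapply(oz[keep], recalls$participant_id[keep], sum)
    out <- unname(s[match(ids, names(s))])
    out[is.na(out)] <- 0
    out
  }
  data.frame(participant_id = ids,
             oz_lcsb = sum_class("LCSB"),
             oz_sb = sum_class("SB"),
             oz_mixed = sum_class("MIXED"),
             stringsAsFactors = FALSE)
}

#' Consumer-group assignment
#'
#' Applies the published 4-group rule at the 4-oz threshold, under one of
#' two treatments of mixed-code volume: `MIXED_AS_LCSB` adds it to the
#' LCSB side, `MIXED_AS_SB` to the SB side. With effective volumes L and S:
#' `LCSB_SB` if both are at least 4 oz; `LCSB` if L >= 4 and S < 4; `SB` if
#' S >= 4 and L < 4; `WATER` if both are < 4 and plain water is at least
#' 4 oz; otherwise `UNGROUPED` (excluded from outcome models).
#'
#' @param day data.frame with columns `oz_lcsb`, `oz_sb`, `oz_mixed`,
#'   `oz_water` (e.g. a merge of [beverage_totals()] and [water_intake()]).
#' @param scenario `"MIXED_AS_LCSB"` or `"MIXED_AS_SB"`.
#' @param th [thresholds()].
#' @return factor with levels `WATER`, `LCSB`, `SB`, `LCSB_SB`, `UNGROUPED`.
#' @export
assign_group <- function(day, scenario = c("MIXED_AS_LCSB", "MIXED_AS_SB"),
                         th = thresholds()) {
  scenario <- match.arg(scenario)
  vols <- day[, c("oz_lcsb", "oz_sb", "oz_mixed", "oz_water")]
  if (any(!is.finite(as.matrix(vols))) || any(as.matrix(vols) < 0)) {
    bc_stop("assign_group: volumes must be finite and >= 0")
  }
  lcsb <- day$oz_lcsb + if (scenario == "MIXED_AS_LCSB") day$oz_mixed else 0
  sb <- day$oz_sb + if (scenario == "MIXED_AS_SB") day$oz_mixed else 0
  m <- th$group_min_oz
  g <- ifelse(lcsb >= m & sb >= m, "LCSB_SB",
       ifelse(lcsb >= m, "LCSB",
       ifelse(sb >= m, "SB",
       ifelse(day$oz_water >= m, "WATER", "UNGROUPED"))))
  factor(g, levels = c("WATER", "LCSB", "SB", "LCSB_SB", "UNGROUPED"))
}

#' Build participant-day records for one scenario
#'
#' Convenience wrapper: filters to the eligible population, computes
#' beverage and water volumes, and assigns consumer groups.
#'
#' @param participants validated participant table.
#' @param recalls validated recall items.
#' @param tab `classification_table`.
#' @param foodcodes validated foodcode table.
#' @param scenario mixed-code treatment, see [assign_group()].
#' @param th [thresholds()].
#' @param water_codes see [water_intake()].
#' @return data.frame with `participant_id`, the four volume columns,
#'   `group`, and `water_discrepancy`, one row per eligible participant.
#' @export
participant_days <- function(participants, recalls, tab, foodcodes,
                             scenario = c("MIXED_AS_LCSB", "MIXED_AS_SB"),
                             th = thresholds(),
                             water_codes = c("94000100", "94100100",
                                             "94300100")) {
  scenario <- match.arg(scenario)
  elig <- participants[eligibility_filter(participants), , drop = FALSE]
  keep <- recalls$participant_id %in% elig$participant_id
  bev <- beverage_totals(recalls[keep, , drop = FALSE], tab, foodcodes)
  wat <- water_intake(elig, recalls[keep, , drop = FALSE],
                      water_codes = water_codes, th = th)
  day <- merge(wat, bev, by = "participant_id", all.x = TRUE)
  for (col in c("oz_lcsb", "oz_sb", "oz_mixed")) {
    day[[col]][is.na(day[[col]])] <- 0
  }
  day$group <- assign_group(day, scenario, th)
  day[order(day$participant_id),
      c("participant_id", "oz_lcsb", "oz_sb", "oz_mixed", "oz_water",
        "group", "water_discrepancy")]
}
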