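#' Classification thresholds
#'
#' Bundles the numeric cut-offs used throughout the pipeline. Caloric-density
#' criteria are per serving: the FDA low-calorie (<40 kcal) and no-calorie
#' (<5 kcal) definitions use an 8 fl oz (237 mL) serving, the Leahy criterion
#' is <6.7 kcal/8 fl oz, and the Maillot criterion is <50 kcal per 240 g of
#' beverage (a mass, not a volume, basis). All comparisons are strict.
#'
#' @param group_min_oz minimum fluid ounces for consumer-group membership
#'   ("at least 4 oz"). Default 4.
#' @param fda_low_kcal_per_8floz FDA low-calorie bound, kcal/8 fl oz. Default 40.
#' @param fda_no_kcal_per_8floz FDA no-calorie bound, kcal/8 fl oz. Default 5.
#' @param leahy_kcal_per_8floz Leahy et al. bound, kcal/8 fl oz. Default 6.7.
#' @param maillot_kcal_per_240g Maillot et al. bound, kcal/240 g. Default 50.
#' @param water_g_per_floz density of plain water, g per fl oz. Default 29.6.
#' @return an object of class `bev_thresholds` (a named list).
#' @export
#' @examples
#' th <- thresholds()
#' th$leahy_kcal_per_8floz
thresholds <- function(group_min_oz = 4,
                       fda_low_kcal_per_8floz = 40,
                       fda_no_kcal_per_8floz = 5,
                       leahy_kcal_per_8floz = 6.7,
                       maillot_kcal_per_240g = 50,
                       water_g_per_floz = 29.6) {
  th <- list(group_min_oz = group_min_oz,
             fda_low_kcal_per_8floz = fda_low_kcal_per_8floz,
             fda_no_kcal_per_8floz = fda_no_kcal_per_8floz,
             leahy_kcal_per_8floz = leahy_kcal_per_8floz,
             maillot_kcal_per_240g = maillot_kcal_per_240g,
             water_g_per_floz = water_g_per_floz)
  if (!all(vapply(th, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1)))) {
    bc_stop("all thresholds must be single positive numbers")
  }
  if (!(th$fda_no_kcal_per_8floz < th$leahy_kcal_per_8floz &&
        th$leahy_kcal_per_8floz < th$fda_low_kcal_per_8floz &&
        th$fda_low_kcal_per_8floz < th$maillot_kcal_per_240g)) {
    bc_stop("thresholds must satisfy fda_no < leahy < fda_low < maillot")
  }
  structure(th, class = "bev_thresholds")
}

# ---------------------------------------------------------------------------
# Foodcode tables
# ---------------------------------------------------------------------------

#' Validate a foodcode table
#'
#' Enforces the invariants of a per-cycle foodcode table: 8-digit codes,
#' non-negative energy density, a positive grams-per-fluid-ounce conversion
#' factor within the plausible beverage range `[10, 40]`, and uniqueness of
#' `(code, cycle)`.
#'
#' @param df data.frame with columns `code`, `cycle`, `main_description`,
#'   `additional_description`, `wweia_category`, `kcal_per_100g`,
#'   `grams_per_floz`.
#' @param path optional source path used in error messages.
#' @return the validated data.frame, with `code` as character.
#' @export
validate_foodcode_table <- function(df, path = "<data>") {
  cols <- c("code", "cycle", "main_description", "additional_description",
            "wweia_category", "kcal_per_100g", "grams_per_floz")
  check_columns(df, cols, path)
  df$code <- trimws(as.character(df$code))
  bad <- !grepl("^[0-9]{8}$", df$code)
  if (any(bad)) {
    i <- which(bad)[1]
    bc_stop("%s: row %d: malformed foodcode '%s' (must be exactly 8 digits)",
            path, i, df$code[i])
  }
  df$wweia_category <- as.integer(df$wweia_category)
  df$kcal_per_100g <- as.numeric(df$kcal_per_100g)
  df$grams_per_floz <- as.numeric(df$grams_per_floz)
  if (anyNA(df$kcal_per_100g) || any(df$kcal_per_100g < 0)) {
    i <- which(is.na(df$kcal_per_100g) | df$kcal_per_100g < 0)[1]
    bc_stop("%s: foodcode %s has missing or negative kcal_per_100g",
            path, df$code[i])
  }
  if (anyNA(df$grams_per_floz)) {
    bc_stop("%s: foodcode %s is missing its grams-per-fl-oz conversion factor",
            path, df$code[which(is.na(df$grams_per_floz))[1]])
  }
  if (any(df$grams_per_floz <= 0 | df$grams_per_floz < 10 |
          df$grams_per_floz > 40)) {
    i <- which(df$grams_per_floz <= 0 | df$grams_per_floz < 10 |
               df$grams_per_floz > 40)[1]
    bc_stop("%s: foodcode %s has conversion factor %g outside [10, 40] g/fl oz",
            path, df$code[i], df$grams_per_floz[i])
  }
  key <- paste(df$code, df$cycle)
  if (anyDuplicated(key)) {
    bc_stop("%s: duplicated (code, cycle): %s", path, key[anyDuplicated(key)])
  }
  df$main_description <- as.character(df$main_description)
  df$additional_description <- as.character(df$additional_description)
  df$additional_description[is.na(df$additional_description)] <- ""
  rownames(df) <- NULL
  df
}

#' Read a per-cycle foodcode table from CSV
#'
#' Expected columns: `code,cycle,main_description,additional_description,`
#' `wweia_category,kcal_per_100g,grams_per_floz`. Rows whose `cycle` differs
#' from the requested cycle are rejected (dropped with a warning), since
#' foodcode attributes are only meaningful within one survey cycle.
#'
#' @param path CSV file path.
#' @param cycle survey-cycle label to keep (e.g. `"2013-2014"`). `NULL`
#'   keeps all rows.
#' @return validated foodcode table (data.frame).
#' @export
read_foodcode_table <- function(path, cycle = NULL) {
  if (!file.exists(path)) bc_stop("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(code = "character"),
                        stringsAsFactors = FALSE)
  if (!is.null(cycle)) {
    drop <- df$cycle != cycle
    if (any(drop)) {
      warning(sprintf("%s: dropped %d row(s) with cycle other than '%s'",
                      path, sum(drop), cycle), call. = FALSE)
      df <- df[!drop, , drop = FALSE]
    }
  }
  validate_foodcode_table(df, path)
}

#' Write a foodcode table to CSV
#'
#' @param df validated foodcode table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_foodcode_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Branded products
# ---------------------------------------------------------------------------

#' Read branded-product ingredient records from CSV
#'
#' Expected columns: `brand,code,cycle,ingredients,kcal_per_8floz_mfr,`
#' `ingredients_known`. The `ingredients` field is a semicolon-delimited
#' list. A product whose ingredient list could not be located has
#' `ingredients_known = FALSE`; its (empty) list is then *unknown*, not
#' evidence of absence. A missing manufacturer energy value is stored as
#' `NA`, never as 0.
#'
#' @param path CSV file path.
#' @param cycle optional cycle filter, as in [read_foodcode_table()].
#' @return data.frame of products with a derived `lcs_found` column
#'   (semicolon-joined recognized LCS names; `NA` when ingredients unknown)
#'   populated lazily by [find_lcs()].
#' @export
read_products <- function(path, cycle = NULL) {
  if (!file.exists(path)) bc_stop("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(code = "character"),
                        stringsAsFactors = FALSE)
  if (!is.null(cycle)) df <- df[df$cycle == cycle, , drop = FALSE]
  validate_products(df, path)
}

#' Validate a branded-product table
#' @param df data.frame of products.
#' @param path optional source path used in error messages.
#' @return validated data.frame.
#' @export
validate_products <- function(df, path = "<data>") {
  cols <- c("brand", "code", "cycle", "ingredients", "kcal_per_8floz_mfr",
            "ingredients_known")
  check_columns(df, cols, path)
  df$code <- trimws(as.character(df$code))
  bad <- !grepl("^[0-9]{8}$", df$code)
  if (any(bad)) {
    bc_stop("%s: row %d: malformed foodcode '%s'", path, which(bad)[1],
            df$code[which(bad)[1]])
  }
  df$ingredients <- as.character(df$ingredients)
  df$ingredients[is.na(df$ingredients)] <- ""
  df$ingredients_known <- as.logical(df$ingredients_known)
  if (anyNA(df$ingredients_known)) {
    bc_stop("%s: ingredients_known must be TRUE/FALSE", path)
  }
  df$kcal_per_8floz_mfr <- as.numeric(df$kcal_per_8floz_mfr)
  if (any(!is.na(df$kcal_per_8floz_mfr) & df$kcal_per_8floz_mfr < 0)) {
    bc_stop("%s: negative manufacturer kcal", path)
  }
  rownames(df) <- NULL
  df
}

#' Write a branded-product table to CSV
#' @param df validated product table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_products <- function(df, path) {
  df$lcs_found <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Recall items and participants
# ---------------------------------------------------------------------------

#' Read per-participant recall items from CSV
#'
#' Expected columns: `participant_id,code,grams`. Amounts are stored by
#' mass (grams), as released in the survey's dietary files.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_recalls <- function(path) {
  if (!file.exists(path)) bc_stop("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(code = "character"),
                        stringsAsFactors = FALSE)
  validate_recalls(df, path)
}

#' Validate recall items
#' @param df data.frame of recall items.
#' @param path optional source path used in error messages.
#' @return validated data.frame.
#' @export
validate_recalls <- function(df, path = "<data>") {
  check_columns(df, c("participant_id", "code", "grams"), path)
  df$code <- trimws(as.character(df$code))
  bad <- !grepl("^[0-9]{8}$", df$code)
  if (any(bad)) {
    bc_stop("%s: row %d: malformed foodcode '%s'", path, which(bad)[1],
            df$code[which(bad)[1]])
  }
  df$grams <- as.numeric(df$grams)
  if (anyNA(df$grams) || any(df$grams < 0)) {
    bc_stop("%s: recall grams must be present and >= 0", path)
  }
  rownames(df) <- NULL
  df
}

#' Write recall items to CSV
#' @param df validated recall items.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recalls <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read participant records from CSV
#'
#' Expected columns: `participant_id,age_years,sex,race_ethnicity,income,`
#' `physical_activity,bmi_percentile,diabetes_dx,reliable_recall,`
#' `questionnaire_water_g,stratum_id,psu_id,weight`. Additional columns
#' (e.g. dietary outcome totals) are preserved.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) bc_stop("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_participants(df, path)
}

#' Validate participant records
#' @param df data.frame of participants.
#' @param path optional source path used in error messages.
#' @return validated data.frame.
#' @export
validate_participants <- function(df, path = "<data>") {
  cols <- c("participant_id", "age_years", "sex", "race_ethnicity", "income",
            "physical_activity", "bmi_percentile", "diabetes_dx",
            "reliable_recall", "questionnaire_water_g", "stratum_id",
            "psu_id", "weight")
  check_columns(df, cols, path)
  if (anyDuplicated(df$participant_id)) {
    bc_stop("%s: duplicated participant_id", path)
  }
  df$diabetes_dx <- as.logical(df$diabetes_dx)
  df$reliable_recall <- as.logical(df$reliable_recall)
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight) || any(df$weight <= 0) || any(!is.finite(df$weight))) {
    bc_stop("%s: survey weights must be finite and > 0", path)
  }
  df$questionnaire_water_g <- as.numeric(df$questionnaire_water_g)
  if (any(df$questionnaire_water_g < 0, na.rm = TRUE)) {
    bc_stop("%s: negative questionnaire plain-water value", path)
  }
  bmi <- df$bmi_percentile
  if (any(bmi < 0 | bmi > 100, na.rm = TRUE)) {
    bc_stop("%s: bmi_percentile outside [0, 100]", path)
  }
  rownames(df) <- NULL
  df
}

#' Write participant records to CSV
#' @param df validated participant records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cross-cycle audit
# ---------------------------------------------------------------------------

#' Audit foodcode tables across survey cycles
#'
#' Foodcode inventories, descriptions, and category assignments drift
#' between 2-year survey cycles, so classifications must be made per cycle.
#' This audit reports codes present in only some cycles, codes whose
#' description or category changed, and (optionally) the number of distinct
#' codes ever assigned to a given category set across all cycles.
#'
#' @param tables named list of validated foodcode tables, one per cycle;
#'   names are cycle labels (falls back to each table's `cycle` column).
#' @param categories optional integer vector of category codes; when given,
#'   the report includes `category_union_count`, the number of distinct
#'   foodcodes belonging to any of these categories in any cycle.
#' @return a list of class `cycle_audit` with elements `cycles`,
#'   `presence` (data.frame code x cycle membership, only codes not present
#'   everywhere), `description_drift`, `category_drift` (character vectors
#'   of codes), and `category_union_count` (or `NA`).
#' @export
audit_cycles <- function(tables, categories = NULL) {
  if (!is.list(tables) || length(tables) < 2) {
    bc_stop("audit_cycles() needs at least 2 cycles")
  }
  labels <- names(tables)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(tables, function(t) as.character(t$cycle[1]), character(1))
  }
  tables <- lapply(tables, validate_foodcode_table)
  all_codes <- sort(unique(unlist(lapply(tables, `[[`, "code"))))
  member <- vapply(tables, function(t) all_codes %in% t$code,
                   logical(length(all_codes)))
  member <- matrix(member, nrow = length(all_codes),
                   dimnames = list(all_codes, labels))
  partial <- all_codes[rowSums(member) < length(tables)]
  presence <- data.frame(code = partial,
                         member[partial, , drop = FALSE],
                         check.names = FALSE, row.names = NULL)

  shared <- all_codes[rowSums(member) == length(tables)]
  field_drift <- function(field) {
    drifted <- vapply(shared, function(cd) {
      vals <- vapply(tables, function(t) t[[field]][t$code == cd][1], tables[[1]][[field]][1])
      length(unique(vals)) > 1
    }, logical(1))
    shared[drifted]
  }
  description_drift <- unique(c(field_drift("main_description"),
                                field_drift("additional_description")))
  category_drift <- field_drift("wweia_category")

  union_count <- NA_integer_
  if (!is.null(categories)) {
    in_cat <- unlist(lapply(tables, function(t) {
      t$code[t$wweia_category %in% as.integer(categories)]
    }))
    union_count <- length(unique(in_cat))
  }
  structure(list(cycles = labels, presence = presence,
                 description_drift = sort(description_drift),
                 category_drift = sort(category_drift),
                 category_union_count = union_count),
            class = "cycle_audit")
}

#' @export
print.cycle_audit <- function(x, ...) {
  cat("Cross-cycle foodcode audit (", length(x$cycles), " cycles)\n", sep = "")
  cat("  codes not present in every cycle:", nrow(x$presence), "\n")
  cat("  codes with description drift:   ", length(x$description_drift), "\n")
  cat("  codes with category drift:      ", length(x$category_drift), "\n")
  if (!is.na(x$category_union_count)) {
    cat("  union of codes ever in category set:", x$category_union_count, "\n")
  }
  invisible(x)
}
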