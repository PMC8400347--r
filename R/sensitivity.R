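#' Covariates for the two outcome models
#'
#' Model 1 adjusts for demographics, physical activity, and BMI percentile;
#' Model 2 additionally adjusts for total energy intake (so it is not
#' applicable when energy itself is the outcome).
#'
#' @param model 1 or 2.
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(model) {
  base <- c("age_years", "sex", "race_ethnicity", "income",
            "physical_activity", "bmi_percentile")
  if (model == 1) base else if (model == 2) c(base, "energy_kcal")
  else bc_stop("model must be 1 or 2")
}

#' Run the full pipeline under one mixed-code scenario
#'
#' Classifies the foodcode universe, computes eligible participants'
#' beverage volumes and consumer groups under the given treatment of mixed
#' foodcodes, and fits the outcome models: for each outcome and model, a
#' residual-normalizing transform is selected, Tukey-adjusted pairwise
#' comparisons are computed on the transformed scale, and least-squares
#' means with standard errors are reported on the untransformed scale.
#' The pipeline is deterministic given its inputs.
#'
#' @param inputs list with elements `foodcodes`, `products`, `recalls`,
#'   `participants`, and optionally `nonsweetened_codes` and `water_codes`.
#' @param scenario `"MIXED_AS_LCSB"` or `"MIXED_AS_SB"`.
#' @param outcomes outcome column names present in `participants`.
#' @param models integer vector, subset of `1:2`.
#' @param cfg [strategy_config()].
#' @param th [thresholds()].
#' @return object of class `scenario_result`: `scenario`, `n_by_group`,
#'   `class_counts`, `days`, and `results[[outcome]][[model]]` each holding
#'   `lsm` (untransformed scale), `pairs`, `letters`, `transform`, `df`.
#' @export
run_scenario <- function(inputs,
                         scenario = c("MIXED_AS_LCSB", "MIXED_AS_SB"),
                         outcomes = c("energy_kcal", "carbohydrate_g",
                                      "total_sugar_g", "added_sugar_g"),
                         models = 1:2,
                         cfg = strategy_config(),
                         th = thresholds()) {
  scenario <- match.arg(scenario)
  nonsw <- inputs$nonsweetened_codes %||% character(0)
  water_codes <- inputs$water_codes %||% c("94000100", "94100100", "94300100")

  tab <- build_classification_table(inputs$foodcodes, inputs$products,
                                    cfg, th, nonsweetened_codes = nonsw)
  days <- participant_days(inputs$participants, inputs$recalls, tab,
                           inputs$foodcodes, scenario, th, water_codes)
  modeled <- days[days$group != "UNGROUPED", , drop = FALSE]
  modeled$group <- droplevels(modeled$group)
  dat <- merge(modeled, inputs$participants, by = "participant_id")

  outcomes <- intersect(outcomes, names(dat))
  results <- list()
  for (oc in outcomes) {
    results[[oc]] <- list()
    for (mdl in models) {
      covs <- model_covariates(mdl)
      if (oc %in% covs) next  # energy cannot adjust for itself
      rhs <- paste(c("group", covs), collapse = " + ")
      fml <- stats::as.formula(paste(oc, "~", rhs))
      norm <- normalize_residuals(fml, dat)
      pw <- tukey_pairwise(lsm(norm$fit, "group"))
      fit_raw <- fit_survey_wls(fml, dat)
      lsm_raw <- lsm(fit_raw, "group")
      results[[oc]][[paste0("model", mdl)]] <- list(
        lsm = lsm_raw, pairs = pw$pairs, letters = pw$letters,
        transform = norm$transform, transform_accepted = norm$accepted,
        df = fit_raw$df)
    }
  }

  structure(list(
    scenario = scenario,
    n_by_group = table(days$group),
    class_counts = table(factor(tab$class,
                                levels = c("LCSB", "SB", "MIXED",
                                           "NONSWEETENED"))),
    days = days,
    results = results
  ), class = "scenario_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contrast two scenario results
#'
#' Reports per-group changes in sample size, per-pair flips in adjusted
#' significance at 0.05, and the largest absolute change in least-squares
#' means per outcome and model. Differences are reported as `b - a`.
#' Errors if total group counts or classification counts are not conserved
#' between the scenarios, since the mixed-code treatment can only move
#' participants between groups, not create or destroy them.
#'
#' @param a,b `scenario_result` objects for the two mixed-code treatments.
#' @param alpha significance level for flip detection. Default 0.05.
#' @return object of class `scenario_diff`: `delta_n` (named vector),
#'   `flips` (data.frame of outcome/model/pair with significance under
#'   each scenario), `max_abs_delta_lsm` (data.frame outcome/model/value).
#' @export
diff_scenarios <- function(a, b, alpha = 0.05) {
  if (sum(a$n_by_group) != sum(b$n_by_group)) {
    bc_stop("diff_scenarios: total participant count differs between scenarios")
  }
  if (!identical(as.integer(a$class_counts), as.integer(b$class_counts))) {
    bc_stop("diff_scenarios: classification counts differ between scenarios")
  }
  delta_n <- as.integer(b$n_by_group) - as.integer(a$n_by_group)
  names(delta_n) <- names(a$n_by_group)

  flips <- data.frame(outcome = character(0), model = character(0),
                      group1 = character(0), group2 = character(0),
                      significant_a = logical(0), significant_b = logical(0),
                      stringsAsFactors = FALSE)
  deltas <- data.frame(outcome = character(0), model = character(0),
                       max_abs_delta_lsm = numeric(0),
                       stringsAsFactors = FALSE)
  for (oc in intersect(names(a$results), names(b$results))) {
    for (mdl in intersect(names(a$results[[oc]]), names(b$results[[oc]]))) {
      ra <- a$results[[oc]][[mdl]]
      rb <- b$results[[oc]][[mdl]]
      key_a <- paste(ra$pairs$group1, ra$pairs$group2)
      key_b <- paste(rb$pairs$group1, rb$pairs$group2)
      common <- intersect(key_a, key_b)
      sa <- ra$pairs$p_adjusted[match(common, key_a)] < alpha
      sb <- rb$pairs$p_adjusted[match(common, key_b)] < alpha
      flip <- sa != sb
      if (any(flip)) {
        parts <- do.call(rbind, strsplit(common[flip], " "))
        flips <- rbind(flips, data.frame(
          outcome = oc, model = mdl,
          group1 = parts[, 1], group2 = parts[, 2],
          significant_a = sa[flip], significant_b = sb[flip],
          stringsAsFactors = FALSE))
      }
      shared_groups <- intersect(ra$lsm$group, rb$lsm$group)
      dl <- rb$lsm$lsm[match(shared_groups, rb$lsm$group)] -
            ra$lsm$lsm[match(shared_groups, ra$lsm$group)]
      deltas <- rbind(deltas, data.frame(
        outcome = oc, model = mdl,
        max_abs_delta_lsm = if (length(dl)) max(abs(dl)) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(scenario_a = a$scenario, scenario_b = b$scenario,
                 delta_n = delta_n, flips = flips,
                 max_abs_delta_lsm = deltas, alpha = alpha),
            class = "scenario_diff")
}

#' @export
print.scenario_diff <- function(x, ...) {
  cat(sprintf("Scenario contrast: %s -> %s\n", x$scenario_a, x$scenario_b))
  cat("  group size changes:\n")
  print(x$delta_n)
  cat(sprintf("  significance flips at alpha = %.2f: %d\n", x$alpha,
              nrow(x$flips)))
  invisible(x)
}
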