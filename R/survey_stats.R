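#' Design-based weighted linear regression
#'
#' Fits weighted least squares and estimates the coefficient covariance by
#' Taylor-series linearization for a stratified cluster sample with a
#' with-replacement approximation at the first stage: score vectors
#' `u_i = w_i * x_i * e_i` are totaled within primary sampling units
#' (PSUs), and the between-PSU covariance within each stratum (scaled by
#' `n_h / (n_h - 1)`) is accumulated and sandwiched between `(X'WX)^-1`.
#' The design degrees of freedom are `#PSUs - #strata`.
#'
#' Strata containing a single PSU cannot contribute a within-stratum
#' variance; by default their PSU total is centered at the grand mean of
#' all PSU totals (`lonely = "center"`), a conservative standard device.
#' `lonely = "fail"` errors instead.
#'
#' @param formula model formula.
#' @param data data.frame holding outcome, covariates, and design columns.
#' @param weights name of the sampling-weight column.
#' @param strata name of the stratum-id column.
#' @param psu name of the PSU-id column (PSU ids may repeat across strata).
#' @param lonely `"center"` or `"fail"`.
#' @return object of class `svy_fit`: coefficients, covariance matrix,
#'   design df, the model frame pieces needed for [lsm()], and the ids of
#'   any lonely strata encountered.
#' @export
fit_survey_wls <- function(formula, data, weights = "weight",
                           strata = "stratum_id", psu = "psu_id",
                           lonely = c("center", "fail")) {
  lonely <- match.arg(lonely)
  for (col in c(weights, strata, psu)) {
    if (!col %in% names(data)) bc_stop("fit_survey_wls: no column '%s'", col)
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  if (!all(keep)) {
    message(sprintf("fit_survey_wls: dropped %d row(s) with missing values",
                    sum(!keep)))
  }
  mf <- mf[keep, , drop = FALSE]
  data <- data[keep, , drop = FALSE]
  w <- as.numeric(data[[weights]])
  if (any(!is.finite(w) | w <= 0)) {
    bc_stop("fit_survey_wls: weights must be finite and > 0")
  }
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  y <- stats::model.response(mf)

  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    bc_stop("fit_survey_wls: singular design matrix; aliased column(s): %s",
            paste(aliased, collapse = ", "))
  }

  A <- crossprod(X, w * X)
  b <- solve(A, crossprod(X, w * y))
  e <- as.numeric(y - X %*% b)

  scores <- X * (w * e)
  sid <- as.character(data[[strata]])
  pid <- paste(sid, as.character(data[[psu]]), sep = "\r")
  psu_tot <- rowsum(scores, pid)
  psu_str <- sub("\r.*$", "", rownames(psu_tot))

  strata_ids <- unique(psu_str)
  n_psu <- nrow(psu_tot)
  n_strata <- length(strata_ids)
  p <- ncol(X)
  V_scores <- matrix(0, p, p)
  lonely_strata <- character(0)
  grand_mean <- colMeans(psu_tot)
  for (h in strata_ids) {
    Z <- psu_tot[psu_str == h, , drop = FALSE]
    nh <- nrow(Z)
    if (nh == 1) {
      if (lonely == "fail") {
        bc_stop("fit_survey_wls: stratum '%s' has a single PSU", h)
      }
      lonely_strata <- c(lonely_strata, h)
      d <- Z[1, ] - grand_mean
      V_scores <- V_scores + tcrossprod(d)
    } else {
      Zc <- sweep(Z, 2, colMeans(Z))
      V_scores <- V_scores + (nh / (nh - 1)) * crossprod(Zc)
    }
  }
  Ainv <- solve(A)
  V <- Ainv %*% V_scores %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = stats::setNames(as.numeric(b), colnames(X)),
    vcov = V,
    df = n_psu - n_strata,
    n = nrow(X), n_psu = n_psu, n_strata = n_strata,
    residuals = e, fitted = as.numeric(X %*% b),
    X = X, y = y, w = w,
    terms = tt, xlevels = stats::.getXlevels(tt, mf),
    assign = attr(X, "assign"),
    formula = formula,
    lonely_strata = lonely_strata
  ), class = "svy_fit")
}

#' @export
coef.svy_fit <- function(object, ...) object$coefficients

#' @export
vcov.svy_fit <- function(object, ...) object$vcov

#' @export
print.svy_fit <- function(x, ...) {
  cat("Design-based weighted linear model\n")
  cat(sprintf("  n = %d obs, %d PSUs in %d strata (df = %d)\n",
              x$n, x$n_psu, x$n_strata, x$df))
  se <- sqrt(diag(x$vcov))
  print(cbind(Estimate = x$coefficients, SE = se))
  invisible(x)
}

#' Weighted skewness
#'
#' Third standardized moment with observation weights (normalized to sum
#' to 1). Returns 0 for degenerate (zero-variance) input.
#'
#' @param x numeric vector.
#' @param w weights (default uniform).
#' @return scalar skewness.
#' @export
weighted_skewness <- function(x, w = rep(1, length(x))) {
  w <- w / sum(w)
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  if (m2 <= .Machine$double.eps * max(1, mu^2)) return(0)
  m3 <- sum(w * (x - mu)^3)
  m3 / m2^1.5
}

# The transform ladder, in acceptance order. Power transforms with
# non-positive exponents (and log) require strictly positive outcomes;
# sqrt requires non-negative ones. Reversing transforms (negative powers)
# are sign-flipped so that larger y stays larger, keeping comparison
# directions interpretable.
transform_ladder <- function() {
  list(
    identity = list(fun = identity, requires = function(y) TRUE),
    sqrt = list(fun = sqrt, requires = function(y) all(y >= 0)),
    log = list(fun = log, requires = function(y) all(y > 0)),
    inv_sqrt = list(fun = function(y) -1 / sqrt(y),
                    requires = function(y) all(y > 0)),
    inverse = list(fun = function(y) -1 / y,
                   requires = function(y) all(y > 0))
  )
}

#' Residual-normalizing transform selection
#'
#' Walks the power ladder (identity, square root, log, reciprocal square
#' root, reciprocal) and accepts the first transform under which the
#' weighted skewness of the fitted model's residuals has magnitude below
#' `skew_threshold`. Transforms that are undefined for the observed
#' outcome range (log of a non-positive value, ...) are rejected. If no
#' rung qualifies, the rung with the smallest absolute skewness is used
#' and reported.
#'
#' @param formula model formula (outcome on the left).
#' @param data data.frame.
#' @param weights,strata,psu design column names, as in [fit_survey_wls()].
#' @param skew_threshold absolute residual skewness below which residuals
#'   are accepted as normal enough. Default 0.5.
#' @return list with `transform` (name), `fun`, `fit` (the `svy_fit` on the
#'   transformed scale), `skewness` (named vector over tried rungs), and
#'   `accepted` (logical: did any rung meet the threshold).
#' @export
normalize_residuals <- function(formula, data, weights = "weight",
                                strata = "stratum_id", psu = "psu_id",
                                skew_threshold = 0.5) {
  yname <- all.vars(formula)[1]
  y <- data[[yname]]
  ladder <- transform_ladder()
  skews <- stats::setNames(rep(NA_real_, length(ladder)), names(ladder))
  fits <- vector("list", length(ladder))
  for (i in seq_along(ladder)) {
    rung <- ladder[[i]]
    if (!rung$requires(y)) next
    d2 <- data
    d2[[yname]] <- rung$fun(y)
    fit <- fit_survey_wls(formula, d2, weights, strata, psu)
    skews[i] <- weighted_skewness(fit$residuals, fit$w)
    fits[[i]] <- fit
    if (abs(skews[i]) < skew_threshold) {
      return(list(transform = names(ladder)[i], fun = rung$fun, fit = fit,
                  skewness = skews[seq_len(i)], accepted = TRUE))
    }
  }
  tried <- which(!is.na(skews))
  if (length(tried) == 0) bc_stop("normalize_residuals: no transform applicable")
  best <- tried[which.min(abs(skews[tried]))]
  list(transform = names(ladder)[best], fun = ladder[[best]]$fun,
       fit = fits[[best]], skewness = skews, accepted = FALSE)
}

#' Least-squares means by group
#'
#' Model-predicted outcome per group level, evaluated at the
#' survey-weighted mean of the other model columns (weighted means of
#' continuous covariates, weighted proportions of categorical dummies).
#' Standard errors follow from the coefficient covariance by the delta
#' method (the profile is treated as fixed).
#'
#' @param fit a `svy_fit`.
#' @param group name of the factor term whose levels are compared.
#' @return data.frame of class `lsm_result` with columns `group`, `lsm`,
#'   `se`; attributes `vcov` (covariance of the LSM vector), `df`, and
#'   `group_var`.
#' @export
lsm <- function(fit, group = "group") {
  labels <- attr(fit$terms, "term.labels")
  gi <- which(labels == group)
  if (length(gi) != 1) {
    bc_stop("lsm: term '%s' not in the model", group)
  }
  levs <- fit$xlevels[[group]]
  if (is.null(levs) || length(levs) < 1) {
    bc_stop("lsm: '%s' is not a factor in the model frame", group)
  }
  gcols <- which(fit$assign == gi)
  profile <- colSums(fit$X * fit$w) / sum(fit$w)

  P <- matrix(rep(profile, length(levs)), nrow = length(levs), byrow = TRUE,
              dimnames = list(levs, names(profile)))
  P[, gcols] <- 0
  # treatment contrasts: the reference level has all group dummies 0
  for (lv in levs[-1]) {
    colname <- paste0(group, lv)
    if (!colname %in% colnames(P)) {
      bc_stop("lsm: cannot locate dummy column '%s' (non-treatment contrasts?)",
              colname)
    }
    P[lv, colname] <- 1
  }
  est <- as.numeric(P %*% fit$coefficients)
  Vl <- P %*% fit$vcov %*% t(P)
  out <- data.frame(group = levs, lsm = est, se = sqrt(diag(Vl)),
                    stringsAsFactors = FALSE)
  class(out) <- c("lsm_result", "data.frame")
  attr(out, "vcov") <- Vl
  attr(out, "df") <- fit$df
  attr(out, "group_var") <- group
  out
}

#' Tukey-Kramer adjusted pairwise comparisons
#'
#' All pairwise differences between group least-squares means, with
#' standard errors from the LSM covariance and p-values adjusted through
#' the studentized-range distribution with the design degrees of freedom
#' (`p = P(q_{k, df} >= |t| * sqrt(2))`). Also assigns compact letters:
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param lsm_res an `lsm_result` (typically computed on the transformed
#'   scale).
#' @param alpha significance level for the letter display. Default 0.05.
#' @return list with `pairs` (data.frame: `group1`, `group2`, `estimate`,
#'   `se`, `t`, `p_unadjusted`, `p_adjusted`) and `letters` (named
#'   character vector over groups).
#' @export
tukey_pairwise <- function(lsm_res, alpha = 0.05) {
  k <- nrow(lsm_res)
  if (k < 2) bc_stop("tukey_pairwise: need at least 2 groups")
  V <- attr(lsm_res, "vcov")
  df <- attr(lsm_res, "df")
  if (df < 1) bc_stop("tukey_pairwise: non-positive design df")
  combs <- utils::combn(k, 2)
  np <- ncol(combs)
  out <- data.frame(group1 = lsm_res$group[combs[1, ]],
                    group2 = lsm_res$group[combs[2, ]],
                    estimate = NA_real_, se = NA_real_, t = NA_real_,
                    p_unadjusted = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (m in seq_len(np)) {
    i <- combs[1, m]; j <- combs[2, m]
    d <- lsm_res$lsm[i] - lsm_res$lsm[j]
    v <- V[i, i] + V[j, j] - 2 * V[i, j]
    se <- sqrt(max(v, 0))
    tval <- if (se > 0) abs(d) / se else ifelse(abs(d) > 0, Inf, 0)
    out$estimate[m] <- d
    out$se[m] <- se
    out$t[m] <- tval
    out$p_unadjusted[m] <- 2 * stats::pt(tval, df, lower.tail = FALSE)
    out$p_adjusted[m] <- stats::ptukey(tval * sqrt(2), nmeans = k, df = df,
                                       lower.tail = FALSE)
  }
  sig <- matrix(FALSE, k, k)
  for (m in seq_len(np)) {
    i <- combs[1, m]; j <- combs[2, m]
    sig[i, j] <- sig[j, i] <- out$p_adjusted[m] < alpha
  }
  letters_vec <- cld_letters(order(lsm_res$lsm), sig)
  names(letters_vec) <- lsm_res$group
  list(pairs = out, letters = letters_vec, alpha = alpha)
}

# Compact letter display by insert-and-absorb: start from one set holding
# all groups; split sets containing a significantly different pair; drop
# sets contained in others; letter sets in order of the smallest mean they
# contain.
cld_letters <- function(order_by_mean, sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  rank_of <- match(seq_len(k), order_by_mean)
  set_rank <- vapply(sets, function(s) min(rank_of[s]), numeric(1))
  sets <- sets[order(set_rank)]
  out <- rep("", k)
  for (si in seq_along(sets)) {
    lab <- letters[(si - 1) %% 26 + 1]
    for (g in sets[[si]]) out[g] <- paste0(out[g], lab)
  }
  out
}
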