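#' Sex structures and variance weightings of the regression grid
#'
#' Age is always an explanatory variable; sex enters the mean in one of five
#' ways: (i) not considered; (ii) different intercepts, common slope;
#' (iii) common intercept, different slopes; (iv) different intercepts and
#' slopes; (v) as (iv) but fully separate models per sex, including separate
#' residual variance. The observation variance is `sigma^2 * v(age)` with
#' `v` one of `constant` (1), `age`, or `inv_age` (1/age); fitting uses
#' weighted least squares with weights `1/v(age)`.
#'
#' @return character vectors of the valid levels.
#' @export
sex_structures <- function() c("i", "ii", "iii", "iv", "v")

#' @rdname sex_structures
#' @export
variance_weightings <- function() c("constant", "age", "inv_age")

variance_fn <- function(weighting) {
  switch(match.arg(weighting, variance_weightings()),
         constant = function(age) rep(1, length(age)),
         age      = function(age) age,
         inv_age  = function(age) 1 / age)
}

# Design row(s) for the per-sex-slope parameterization. Structures iii/iv
# carry one slope column per sex so that each sex's age effect has its own
# t-test; ii/iv use a male-offset intercept.
design_matrix <- function(age, sex, structure) {
  f <- as.numeric(sex == "F"); m <- as.numeric(sex == "M")
  switch(structure,
    i   = cbind("(Intercept)" = rep(1, length(age)), "age" = age),
    ii  = cbind("(Intercept)" = rep(1, length(age)), "sexM" = m, "age" = age),
    iii = cbind("(Intercept)" = rep(1, length(age)),
                "age:sexF" = age * f, "age:sexM" = age * m),
    iv  = cbind("(Intercept)" = rep(1, length(age)), "sexM" = m,
                "age:sexF" = age * f, "age:sexM" = age * m),
    stop("unknown sex structure: ", structure, call. = FALSE))
}

# Closed-form weighted least squares with Gaussian ML log-likelihood.
# Var(eps_i) = sigma^2 * v_i, weights w_i = 1/v_i;
# sigma2_ml = sum(w r^2)/n enters logLik, sigma2 (= sum(w r^2)/(n-p))
# scales vcov, SEs and prediction.
wls_core <- function(y, X, w, label = "model") {
  n <- length(y); p <- ncol(X)
  if (n < p)
    stop("too few observations (", n, ") for ", label, " with ", p,
         " mean parameters", call. = FALSE)
  sw <- sqrt(w)
  qr_ <- qr(X * sw)
  if (qr_$rank < p)
    stop("singular design in ", label,
         " (a sex level is missing or a column is constant)", call. = FALSE)
  beta <- qr.coef(qr_, y * sw)
  r <- y - drop(X %*% beta)
  rss_w <- sum(w * r^2)
  sigma2_ml <- rss_w / n
  # exact interpolation (n == p) leaves no residual df: coefficients are
  # still defined, but scale, tests and likelihood are not
  sigma2 <- if (n > p) rss_w / (n - p) else NaN
  XtWXinv <- solve(crossprod(X * sw))
  dimnames(XtWXinv) <- list(colnames(X), colnames(X))
  vcov <- sigma2 * XtWXinv
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  logLik <- -n / 2 * (log(2 * pi) + 1 + log(sigma2_ml)) + sum(log(w)) / 2
  list(coef = beta, vcov = vcov, se = se, p = pval,
       sigma2 = sigma2, sigma2_ml = sigma2_ml, df_resid = n - p, n = n,
       logLik = logLik, k = p + 1L)
}

#' Build the per-participant regression response for a tooth set
#'
#' The response is the natural log of the chosen transformation outcome; for
#' a multi-tooth combination each participant contributes the mean of the
#' log-outcomes over their available teeth in the set (one row per
#' participant, so the combination still yields a single age p-value per
#' sex). Participants with no qualifying tooth are excluded.
#'
#' @param cohort validated cohort data frame ([validate_cohort()]).
#' @param outcome one of [outcome_codes()].
#' @param tooth_set integer vector of FDI codes (e.g. `47` or `c(17, 47)`).
#' @return data frame with columns `participant_id`, `sex`, `age`, `y`,
#'   plus attributes `outcome`, `tooth_set` and `n_by_sex`.
#' @export
build_response <- function(cohort, outcome, tooth_set) {
  cohort <- validate_cohort(cohort)
  outcome <- match.arg(as.character(outcome), outcome_codes())
  sub <- cohort[cohort$tooth_fdi %in% as.integer(tooth_set), , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no usable observations: no tooth from {",
         paste(tooth_set, collapse = ","), "} present", call. = FALSE)
  ly <- compute_outcomes(sub, log = TRUE)[, outcome]
  agg <- stats::aggregate(ly, by = list(participant_id = sub$participant_id),
                          FUN = mean)
  meta <- unique(sub[, c("participant_id", "sex", "age_years")])
  out <- merge(meta, agg, by = "participant_id")
  names(out) <- c("participant_id", "sex", "age", "y")
  out <- out[order(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "tooth_set") <- sort(as.integer(tooth_set))
  attr(out, "n_by_sex") <- c(F = sum(out$sex == "F"), M = sum(out$sex == "M"))
  out
}

#' Fit one cell of the regression grid
#'
#' Weighted least squares fit of `E[y] = mu(age, sex)` under one of the five
#' sex structures with observation variance `sigma^2 * v(age)`. The
#' log-likelihood uses the ML variance estimate and includes the
#' `-1/2 sum(log v)` heteroscedasticity term; AIC counts every mean
#' parameter plus each free `sigma`. Per-sex age p-values come from the
#' per-sex-slope parameterization (structures iii/iv/v); structures i/ii
#' report the common slope's p-value for both sexes.
#'
#' @param responses response table from [build_response()], or any data
#'   frame with columns `sex`, `age`, `y`.
#' @param sex_structure one of [sex_structures()].
#' @param variance_weighting one of [variance_weightings()].
#' @return object of class `molar_fit`.
#' @export
fit_wls <- function(responses, sex_structure = "i",
                    variance_weighting = "constant") {
  sex_structure <- match.arg(sex_structure, sex_structures())
  variance_weighting <- match.arg(variance_weighting, variance_weightings())
  stopifnot(all(c("sex", "age", "y") %in% names(responses)))
  if (any(responses$age <= 0)) stop("ages must be positive", call. = FALSE)
  v <- variance_fn(variance_weighting)
  w <- 1 / v(responses$age)

  if (sex_structure == "v") {
    fits <- list()
    for (s in c("F", "M")) {
      idx <- responses$sex == s
      if (!any(idx))
        stop("singular design in structure v: no observations for sex ", s,
             call. = FALSE)
      fits[[s]] <- wls_core(responses$y[idx],
                            design_matrix(responses$age[idx], responses$sex[idx], "i"),
                            w[idx], label = paste0("structure v, sex ", s))
    }
    logLik <- fits$F$logLik + fits$M$logLik
    k <- fits$F$k + fits$M$k
    age_p <- c(F = unname(fits$F$p["age"]), M = unname(fits$M$p["age"]))
    slopes <- c(F = unname(fits$F$coef["age"]), M = unname(fits$M$coef["age"]))
    slope_se <- c(F = unname(fits$F$se["age"]), M = unname(fits$M$se["age"]))
    p_common <- FALSE
  } else {
    X <- design_matrix(responses$age, responses$sex, sex_structure)
    core <- wls_core(responses$y, X, w,
                     label = paste("structure", sex_structure))
    fits <- list(all = core)
    logLik <- core$logLik; k <- core$k
    if (sex_structure %in% c("i", "ii")) {
      age_p <- c(F = unname(core$p["age"]), M = unname(core$p["age"]))
      slopes <- c(F = unname(core$coef["age"]), M = unname(core$coef["age"]))
      slope_se <- c(F = unname(core$se["age"]), M = unname(core$se["age"]))
      p_common <- TRUE
    } else {
      age_p <- c(F = unname(core$p["age:sexF"]), M = unname(core$p["age:sexM"]))
      slopes <- c(F = unname(core$coef["age:sexF"]),
                  M = unname(core$coef["age:sexM"]))
      slope_se <- c(F = unname(core$se["age:sexF"]),
                    M = unname(core$se["age:sexM"]))
      p_common <- FALSE
    }
  }

  structure(list(
    structure = sex_structure, weighting = variance_weighting,
    outcome = attr(responses, "outcome"),
    tooth_set = attr(responses, "tooth_set"),
    fits = fits, logLik = logLik, k = k, aic = 2 * k - 2 * logLik,
    n = nrow(responses),
    n_by_sex = c(F = sum(responses$sex == "F"), M = sum(responses$sex == "M")),
    age_pvalues = age_p, p_common = p_common,
    slopes = slopes, slope_se = slope_se,
    age_range = range(responses$age), y_range = range(responses$y)
  ), class = "molar_fit")
}

#' @export
print.molar_fit <- function(x, ...) {
  cat("<molar_fit> structure ", x$structure, ", variance ~ ", x$weighting,
      if (!is.null(x$outcome)) paste0(", outcome ", x$outcome),
      if (!is.null(x$tooth_set))
        paste0(", teeth ", paste(x$tooth_set, collapse = "+")),
      "\n", sep = "")
  cat("  n =", x$n, "(F", x$n_by_sex[["F"]], "/ M", x$n_by_sex[["M"]],
      ") logLik =", format(x$logLik, digits = 6),
      " AIC =", format(x$aic, digits = 6), "\n")
  cat(sprintf("  age slope F: %.4g (p = %.3g)  M: %.4g (p = %.3g)%s\n",
              x$slopes[["F"]], x$age_pvalues[["F"]],
              x$slopes[["M"]], x$age_pvalues[["M"]],
              if (x$p_common) "  [common slope]" else ""))
  invisible(x)
}

# Sub-fit and design row for one sex; used by prediction and the posterior.
sub_fit_for <- function(fit, sex) {
  if (fit$structure == "v") fit$fits[[sex]] else fit$fits$all
}

design_row_for <- function(fit, age, sex) {
  if (fit$structure == "v")
    design_matrix(age, rep(sex, length(age)), "i")
  else
    design_matrix(age, rep(sex, length(age)), fit$structure)
}

#' Predictive moments of a fitted model
#'
#' Mean and variance of a new log-outcome observation at given ages, for one
#' sex: `mu = x' beta`, `var = sigma2 * v(age)` plus (optionally) the
#' parameter-uncertainty term `x' Cov(beta) x`.
#'
#' @param fit a `molar_fit`.
#' @param age vector of ages (years).
#' @param sex `"F"` or `"M"`.
#' @param include_param_uncertainty add `x' Cov(beta) x` (default `TRUE`).
#' @return list with vectors `mean`, `var` and scalar `df` (residual df of
#'   the relevant sub-fit).
#' @export
predictive_moments <- function(fit, age, sex,
                               include_param_uncertainty = TRUE) {
  stopifnot(inherits(fit, "molar_fit"), sex %in% c("F", "M"))
  sf <- sub_fit_for(fit, sex)
  X <- design_row_for(fit, age, sex)
  mu <- drop(X %*% sf$coef)
  vv <- variance_fn(fit$weighting)(age)
  var <- sf$sigma2 * vv
  if (include_param_uncertainty)
    var <- var + rowSums((X %*% sf$vcov) * X)
  list(mean = mu, var = var, df = sf$df_resid)
}

#' Prediction interval for a new observation
#'
#' Student-t interval `mu +/- t * sqrt(sigma2 * v(age) + x' Cov(beta) x)`
#' with the residual degrees of freedom, matching the classical
#' prediction-interval construction for a weighted linear model.
#'
#' @inheritParams predictive_moments
#' @param level coverage level, default 0.95.
#' @return data frame with columns `age`, `fit`, `lwr`, `upr`.
#' @export
prediction_interval <- function(fit, age, sex, level = 0.95) {
  pm <- predictive_moments(fit, age, sex, include_param_uncertainty = TRUE)
  tq <- stats::qt(1 - (1 - level) / 2, df = pm$df)
  data.frame(age = age, fit = pm$mean,
             lwr = pm$mean - tq * sqrt(pm$var),
             upr = pm$mean + tq * sqrt(pm$var))
}

#' Select sex structure and variance weighting by AIC
#'
#' Fits every cell of the (structure x weighting) grid and returns the fit
#' with the smallest AIC. For structure v the AIC is the sum over the two
#' per-sex fits. Unfittable cells are skipped with a warning. Ties (AIC
#' difference below 1e-9) go to the fewer-parameter model, then to the fixed
#' enumeration order of [sex_structures()] x [variance_weightings()].
#'
#' @param responses response table from [build_response()].
#' @param structures,weightings subsets of the grid to consider.
#' @return list with `fit` (the selected `molar_fit`) and `grid` (a data
#'   frame of all attempted cells with their AIC).
#' @export
select_structure <- function(responses, structures = sex_structures(),
                             weightings = variance_weightings()) {
  structures <- match.arg(structures, sex_structures(), several.ok = TRUE)
  weightings <- match.arg(weightings, variance_weightings(), several.ok = TRUE)
  rows <- list(); fits <- list()
  for (s in structures) for (wt in weightings) {
    f <- tryCatch(fit_wls(responses, s, wt), error = function(e) e)
    if (inherits(f, "error")) {
      warning("skipping (", s, ", ", wt, "): ", conditionMessage(f),
              call. = FALSE)
      next
    }
    key <- paste(s, wt)
    fits[[key]] <- f
    rows[[key]] <- data.frame(structure = s, weighting = wt,
                              k = f$k, logLik = f$logLik, aic = f$aic)
  }
  if (!length(fits)) stop("no fittable grid cell", call. = FALSE)
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, integer(1), "k")
  best <- which(aic <= min(aic) + 1e-9)
  if (length(best) > 1L) best <- best[order(k[best], best)][1L]
  list(fit = fits[[best]], grid = grid)
}

#' The seven printed tooth combinations (plus singles) for one molar type
#'
#' Within a molar type the four teeth were evaluated singly and in seven
#' combinations: upper both sides, lower both sides, right side, left side,
#' the two diagonals, and all four.
#'
#' @param type `"m1"` (1st molars, FDI x6) or `"m2"` (2nd molars, FDI x7).
#' @return named list of integer FDI vectors.
#' @export
standard_tooth_sets <- function(type = c("m2", "m1")) {
  type <- match.arg(type)
  d <- if (type == "m1") 6L else 7L
  ur <- 10L + d; ul <- 20L + d; ll <- 30L + d; lr <- 40L + d
  sets <- c(as.list(c(ur, ul, ll, lr)),
            list(c(ur, ul), c(ll, lr), c(ur, lr), c(ul, ll),
                 c(ur, ll), c(ul, lr), c(ur, ul, ll, lr)))
  names(sets) <- vapply(sets, function(s) paste(s, collapse = "+"), "")
  sets
}

#' Rank outcome / tooth-set candidates by the age p-value
#'
#' For every (outcome, tooth set) candidate the AIC-selected model is fitted
#' and its per-sex age p-values recorded; candidates are ranked by the
#' smallest age p-value across sexes (the model with the lowest p-value is
#' the selected one).
#'
#' @param cohort validated cohort data frame.
#' @param outcomes character vector of outcome codes.
#' @param tooth_sets list of integer FDI vectors (named or not).
#' @param structures,weightings grid restriction passed to
#'   [select_structure()].
#' @return data frame, one row per candidate, sorted by `p_min`, with the
#'   selected structure/weighting, AIC, per-sex p-values and sample sizes.
#' @export
rank_candidates <- function(cohort, outcomes, tooth_sets,
                            structures = sex_structures(),
                            weightings = variance_weightings()) {
  if (!is.list(tooth_sets)) tooth_sets <- list(tooth_sets)
  if (length(outcomes) < 1L || length(tooth_sets) < 1L)
    stop("need at least one candidate", call. = FALSE)
  labs <- names(tooth_sets)
  if (is.null(labs))
    labs <- vapply(tooth_sets, function(s) paste(s, collapse = "+"), "")
  rows <- list()
  for (oc in outcomes) for (i in seq_along(tooth_sets)) {
    resp <- build_response(cohort, oc, tooth_sets[[i]])
    sel <- select_structure(resp, structures, weightings)
    f <- sel$fit
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, teeth = labs[i],
      structure = f$structure, weighting = f$weighting,
      aic = f$aic, p_F = f$age_pvalues[["F"]], p_M = f$age_pvalues[["M"]],
      p_min = min(f$age_pvalues),
      n = f$n, n_F = f$n_by_sex[["F"]], n_M = f$n_by_sex[["M"]])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_min), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
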