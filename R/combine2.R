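as_marginal_spec <- function(x, who) {
  if (inherits(x, "molar_fit")) {
    if (is.null(x$outcome) || is.null(x$tooth_set))
      stop(who, ": fitted model lacks outcome/tooth_set metadata; refit from",
           " a build_response() table", call. = FALSE)
    x <- list(outcome = x$outcome, tooth_set = x$tooth_set,
              structure = x$structure, weighting = x$weighting)
  }
  stopifnot(is.list(x),
            all(c("outcome", "tooth_set", "structure", "weighting") %in% names(x)))
  if (x$structure == "v")
    stop(who, ": structure v (separate per-sex models) is not supported in ",
         "the combination model; both sexes enter one joint model",
         call. = FALSE)
  x
}

biv_norm_logpdf <- function(r1, r2, rho) {
  # standardized bivariate normal log-density (unit margins)
  -log(2 * pi) - 0.5 * log(1 - rho^2) -
    (r1^2 - 2 * rho * r1 * r2 + r2^2) / (2 * (1 - rho^2))
}

#' Fit the two-molar bivariate normal combination model
#'
#' Joint maximum-likelihood fit for the pair of log transformation outcomes
#' of two teeth (typically a 1st and a 2nd molar). Each tooth keeps its own
#' mean structure and variance weighting (adopted from the per-tooth AIC
#' selection); the joint model adds a single correlation parameter `rho`
#' for the dependency between the two teeth of the same participant.
#' Participants with both teeth contribute a bivariate normal density;
#' participants with only one tooth contribute that tooth's marginal
#' density, so no one is discarded. All parameters (both mean vectors, both
#' scales and `rho`) are maximized together; `rho` is optimized on the
#' Fisher-z scale and the scales on the log scale for stability.
#'
#' @param cohort validated cohort data frame.
#' @param specA,specB marginal specifications: either a `molar_fit` from
#'   [select_structure()] / [fit_wls()] (its outcome, tooth set, structure
#'   and weighting are reused) or a list with elements `outcome`,
#'   `tooth_set`, `structure` (not `"v"`), `weighting`.
#' @return object of class `bivariate_fit`.
#' @export
fit_bivariate <- function(cohort, specA, specB) {
  specA <- as_marginal_spec(specA, "specA")
  specB <- as_marginal_spec(specB, "specB")
  respA <- build_response(cohort, specA$outcome, specA$tooth_set)
  respB <- build_response(cohort, specB$outcome, specB$tooth_set)
  names(respA)[names(respA) == "y"] <- "yA"
  names(respB)[names(respB) == "y"] <- "yB"
  merged <- merge(respA, respB,
                  by = c("participant_id", "sex", "age"), all = TRUE)
  n_pairs <- sum(!is.na(merged$yA) & !is.na(merged$yB))
  if (n_pairs < 3L)
    stop("need at least 3 participants with both teeth", call. = FALSE)

  # initialize from the separate marginal fits and a moment estimate of rho
  initA <- fit_wls(stats::setNames(respA[, c("participant_id", "sex", "age", "yA")],
                                   c("participant_id", "sex", "age", "y")),
                   specA$structure, specA$weighting)
  initB <- fit_wls(stats::setNames(respB[, c("participant_id", "sex", "age", "yB")],
                                   c("participant_id", "sex", "age", "y")),
                   specB$structure, specB$weighting)
  pA <- length(initA$fits$all$coef); pB <- length(initB$fits$all$coef)
  vA <- variance_fn(specA$weighting); vB <- variance_fn(specB$weighting)

  both <- !is.na(merged$yA) & !is.na(merged$yB)
  rA0 <- (merged$yA - drop(design_matrix(merged$age, merged$sex, specA$structure) %*%
                             initA$fits$all$coef)) / sqrt(vA(merged$age))
  rB0 <- (merged$yB - drop(design_matrix(merged$age, merged$sex, specB$structure) %*%
                             initB$fits$all$coef)) / sqrt(vB(merged$age))
  rho0 <- suppressWarnings(stats::cor(rA0[both], rB0[both]))
  if (!is.finite(rho0)) rho0 <- 0
  rho0 <- max(min(rho0, 0.95), -0.95)

  theta0 <- c(initA$fits$all$coef, initB$fits$all$coef,
              log(sqrt(initA$fits$all$sigma2_ml)),
              log(sqrt(initB$fits$all$sigma2_ml)),
              atanh(rho0))

  XA <- design_matrix(merged$age, merged$sex, specA$structure)
  XB <- design_matrix(merged$age, merged$sex, specB$structure)
  vaA <- vA(merged$age); vaB <- vB(merged$age)
  onlyA <- !is.na(merged$yA) & is.na(merged$yB)
  onlyB <- is.na(merged$yA) & !is.na(merged$yB)

  negll <- function(theta) {
    bA <- theta[seq_len(pA)]
    bB <- theta[pA + seq_len(pB)]
    sA <- exp(theta[pA + pB + 1L]); sB <- exp(theta[pA + pB + 2L])
    rho <- tanh(theta[pA + pB + 3L])
    muA <- drop(XA %*% bA); muB <- drop(XB %*% bB)
    sdA <- sA * sqrt(vaA); sdB <- sB * sqrt(vaB)
    ll <- 0
    if (any(both)) {
      r1 <- (merged$yA[both] - muA[both]) / sdA[both]
      r2 <- (merged$yB[both] - muB[both]) / sdB[both]
      ll <- ll + sum(biv_norm_logpdf(r1, r2, rho) -
                       log(sdA[both]) - log(sdB[both]))
    }
    if (any(onlyA))
      ll <- ll + sum(stats::dnorm(merged$yA[onlyA], muA[onlyA], sdA[onlyA],
                                  log = TRUE))
    if (any(onlyB))
      ll <- ll + sum(stats::dnorm(merged$yB[onlyB], muB[onlyB], sdB[onlyB],
                                  log = TRUE))
    -ll
  }

  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("bivariate ML did not converge (optim code ", opt$convergence,
         "): ", opt$message, call. = FALSE)
  th <- opt$par
  rho_hat <- tanh(th[pA + pB + 3L])
  if (abs(rho_hat) > 0.99)
    warning("estimated correlation at/near boundary: rho = ",
            format(rho_hat, digits = 4))

  coefA <- stats::setNames(th[seq_len(pA)], names(initA$fits$all$coef))
  coefB <- stats::setNames(th[pA + seq_len(pB)], names(initB$fits$all$coef))
  structure(list(
    specA = specA, specB = specB,
    coefA = coefA, coefB = coefB,
    sigmaA = unname(exp(th[pA + pB + 1L])),
    sigmaB = unname(exp(th[pA + pB + 2L])),
    rho = unname(rho_hat), logLik = -opt$value,
    n_pairs = n_pairs, n_A_only = sum(onlyA), n_B_only = sum(onlyB),
    y_range_A = range(merged$yA, na.rm = TRUE),
    y_range_B = range(merged$yB, na.rm = TRUE),
    convergence = opt$convergence
  ), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("<bivariate_fit> A: outcome ", x$specA$outcome, ", teeth ",
      paste(x$specA$tooth_set, collapse = "+"), " (", x$specA$structure, ", ",
      x$specA$weighting, ")  B: outcome ", x$specB$outcome, ", teeth ",
      paste(x$specB$tooth_set, collapse = "+"), " (", x$specB$structure, ", ",
      x$specB$weighting, ")\n", sep = "")
  cat(sprintf("  rho = %.3f  logLik = %.4f  pairs %d, A-only %d, B-only %d\n",
              x$rho, x$logLik, x$n_pairs, x$n_A_only, x$n_B_only))
  invisible(x)
}

#' Extract a marginal plug-in model from a bivariate fit
#'
#' Returns a `molar_fit`-shaped object carrying the jointly estimated
#' marginal mean and scale for one tooth, usable with [posterior_age()]
#' (plug-in: no parameter-uncertainty term is available, so use
#' `include_param_uncertainty = FALSE`).
#'
#' @param fit a `bivariate_fit`.
#' @param which `"A"` or `"B"`.
#' @return a `molar_fit`.
#' @export
marginal_model <- function(fit, which = c("A", "B")) {
  which <- match.arg(which)
  spec <- if (which == "A") fit$specA else fit$specB
  coef <- if (which == "A") fit$coefA else fit$coefB
  sigma <- if (which == "A") fit$sigmaA else fit$sigmaB
  n <- fit$n_pairs + fit$n_A_only + fit$n_B_only
  p <- length(coef)
  core <- list(coef = coef,
               vcov = matrix(0, p, p, dimnames = list(names(coef), names(coef))),
               se = rep(NA_real_, p), p = rep(NA_real_, p),
               sigma2 = sigma^2, sigma2_ml = sigma^2,
               df_resid = max(n - p, 1L), n = n, logLik = NA_real_, k = p + 1L)
  structure(list(structure = spec$structure, weighting = spec$weighting,
                 outcome = spec$outcome, tooth_set = spec$tooth_set,
                 fits = list(all = core), logLik = NA_real_, k = p + 1L,
                 aic = NA_real_, n = n,
                 n_by_sex = c(F = NA_integer_, M = NA_integer_),
                 age_pvalues = c(F = NA_real_, M = NA_real_),
                 p_common = FALSE,
                 slopes = c(F = NA_real_, M = NA_real_),
                 slope_se = c(F = NA_real_, M = NA_real_),
                 y_range = if (which == "A") fit$y_range_A else fit$y_range_B),
            class = "molar_fit")
}

#' Combined posterior age density from two molars
#'
#' Bayesian age assessment using both teeth at once: the likelihood at each
#' candidate age is the bivariate normal density of the observed pair
#' `(yA, yB)` under the jointly fitted combination model (or the marginal
#' density if one observation is missing), multiplied by the uniform prior
#' and normalized. The single-tooth probabilities from each marginal alone
#' are reported alongside for comparison.
#'
#' @param fit a `bivariate_fit`.
#' @param yA,yB observed log-outcomes; exactly one may be `NA`.
#' @param sex `"F"` or `"M"`.
#' @param prior an [age_prior()].
#' @param grid_step grid resolution in years (default 0.01).
#' @return an `age_posterior` with an extra field `p_over_single`
#'   (named numeric, entries `A` and `B`, `NA` if that tooth was missing).
#' @export
posterior_age_combined <- function(fit, yA, yB, sex, prior = age_prior(),
                                   grid_step = 0.01) {
  stopifnot(inherits(fit, "bivariate_fit"), inherits(prior, "age_prior"))
  if (grid_step > 0.05) stop("grid_step must be <= 0.05 years", call. = FALSE)
  hasA <- !is.null(yA) && length(yA) == 1L && is.finite(yA)
  hasB <- !is.null(yB) && length(yB) == 1L && is.finite(yB)
  if (!hasA && !hasB)
    stop("both observations missing: need at least one of yA, yB",
         call. = FALSE)
  ages <- posterior_grid(prior, grid_step)
  mA <- marginal_model(fit, "A"); mB <- marginal_model(fit, "B")
  pmA <- predictive_moments(mA, ages, sex, include_param_uncertainty = FALSE)
  pmB <- predictive_moments(mB, ages, sex, include_param_uncertainty = FALSE)
  if (hasA && hasB) {
    r1 <- (yA - pmA$mean) / sqrt(pmA$var)
    r2 <- (yB - pmB$mean) / sqrt(pmB$var)
    dens <- exp(biv_norm_logpdf(r1, r2, fit$rho) -
                  0.5 * log(pmA$var) - 0.5 * log(pmB$var))
  } else if (hasA) {
    dens <- stats::dnorm(yA, pmA$mean, sqrt(pmA$var))
  } else {
    dens <- stats::dnorm(yB, pmB$mean, sqrt(pmB$var))
  }
  single <- c(A = NA_real_, B = NA_real_)
  if (hasA)
    single[["A"]] <- posterior_age(mA, yA, sex, prior, grid_step,
                                   include_param_uncertainty = FALSE)$p_over
  if (hasB)
    single[["B"]] <- posterior_age(mB, yB, sex, prior, grid_step,
                                   include_param_uncertainty = FALSE)$p_over
  finish_posterior(ages, dens, prior,
                   y = c(A = if (hasA) yA else NA_real_,
                         B = if (hasB) yB else NA_real_),
                   sex = sex,
                   extra = list(p_over_single = single, rho = fit$rho))
}

#' Evaluate the joint log-likelihood of a bivariate fit
#'
#' Recomputes the combination model's joint log-likelihood on a cohort at
#' the fitted parameters, optionally overriding the correlation; useful for
#' profile checks around the ML estimate.
#'
#' @param fit a `bivariate_fit`.
#' @param cohort the cohort the fit was (or could have been) computed on.
#' @param rho correlation at which to evaluate (default: the fitted value).
#' @return scalar log-likelihood.
#' @export
bivariate_loglik <- function(fit, cohort, rho = fit$rho) {
  stopifnot(inherits(fit, "bivariate_fit"), abs(rho) < 1)
  cohort <- validate_cohort(cohort)
  respA <- build_response(cohort, fit$specA$outcome, fit$specA$tooth_set)
  respB <- build_response(cohort, fit$specB$outcome, fit$specB$tooth_set)
  names(respA)[names(respA) == "y"] <- "yA"
  names(respB)[names(respB) == "y"] <- "yB"
  merged <- merge(respA, respB,
                  by = c("participant_id", "sex", "age"), all = TRUE)
  muA <- drop(design_matrix(merged$age, merged$sex, fit$specA$structure) %*%
                fit$coefA)
  muB <- drop(design_matrix(merged$age, merged$sex, fit$specB$structure) %*%
                fit$coefB)
  sdA <- fit$sigmaA * sqrt(variance_fn(fit$specA$weighting)(merged$age))
  sdB <- fit$sigmaB * sqrt(variance_fn(fit$specB$weighting)(merged$age))
  both <- !is.na(merged$yA) & !is.na(merged$yB)
  onlyA <- !is.na(merged$yA) & is.na(merged$yB)
  onlyB <- is.na(merged$yA) & !is.na(merged$yB)
  ll <- 0
  if (any(both)) {
    r1 <- (merged$yA[both] - muA[both]) / sdA[both]
    r2 <- (merged$yB[both] - muB[both]) / sdB[both]
    ll <- ll + sum(biv_norm_logpdf(r1, r2, rho) -
                     log(sdA[both]) - log(sdB[both]))
  }
  if (any(onlyA))
    ll <- ll + sum(stats::dnorm(merged$yA[onlyA], muA[onlyA], sdA[onlyA],
                                log = TRUE))
  if (any(onlyB))
    ll <- ll + sum(stats::dnorm(merged$yB[onlyB], muB[onlyB], sdB[onlyB],
                                log = TRUE))
  ll
}
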