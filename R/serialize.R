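SCHEMA_VERSION <- "1.0"

named_to_list <- function(x) as.list(x)
list_to_named <- function(x) {
  out <- unlist(x)
  storage.mode(out) <- "double"
  out
}

core_to_list <- function(core) {
  list(coef = named_to_list(core$coef),
       vcov = apply(core$vcov, 1, as.list, simplify = FALSE),
       vcov_names = colnames(core$vcov),
       sigma2 = core$sigma2, sigma2_ml = core$sigma2_ml,
       df_resid = core$df_resid, n = core$n,
       logLik = core$logLik, k = core$k,
       se = named_to_list(core$se), p = named_to_list(core$p))
}

core_from_list <- function(x) {
  nm <- unlist(x$vcov_names)
  V <- matrix(unlist(x$vcov), nrow = length(nm), byrow = TRUE,
              dimnames = list(nm, nm))
  list(coef = list_to_named(x$coef), vcov = V,
       se = list_to_named(x$se), p = list_to_named(x$p),
       sigma2 = x$sigma2, sigma2_ml = x$sigma2_ml,
       df_resid = x$df_resid, n = x$n, logLik = x$logLik, k = x$k)
}

#' Serialize fitted models to JSON
#'
#' Human-diffable JSON representations of `molar_fit` and `bivariate_fit`
#' objects, with a `schema_version` field; `read_model_json()` restores an
#' object usable for prediction.
#'
#' @param fit a `molar_fit` or `bivariate_fit`.
#' @param path output file.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the restored object.
#' @export
write_model_json <- function(fit, path) {
  if (inherits(fit, "molar_fit")) {
    obj <- list(schema_version = SCHEMA_VERSION, kind = "molar_fit",
                structure = fit$structure, weighting = fit$weighting,
                outcome = fit$outcome, tooth_set = fit$tooth_set,
                fits = lapply(fit$fits, core_to_list),
                logLik = fit$logLik, k = fit$k, aic = fit$aic, n = fit$n,
                n_by_sex = named_to_list(fit$n_by_sex),
                age_pvalues = named_to_list(fit$age_pvalues),
                p_common = fit$p_common,
                slopes = named_to_list(fit$slopes),
                slope_se = named_to_list(fit$slope_se),
                age_range = fit$age_range, y_range = fit$y_range)
  } else if (inherits(fit, "bivariate_fit")) {
    obj <- list(schema_version = SCHEMA_VERSION, kind = "bivariate_fit",
                specA = fit$specA, specB = fit$specB,
                coefA = named_to_list(fit$coefA),
                coefB = named_to_list(fit$coefB),
                sigmaA = fit$sigmaA, sigmaB = fit$sigmaB, rho = fit$rho,
                logLik = fit$logLik, n_pairs = fit$n_pairs,
                n_A_only = fit$n_A_only, n_B_only = fit$n_B_only,
                y_range_A = fit$y_range_A, y_range_B = fit$y_range_B,
                convergence = fit$convergence)
  } else stop("unsupported object class", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$kind) || is.null(x$schema_version))
    stop("not a model JSON (missing kind/schema_version)", call. = FALSE)
  if (x$kind == "molar_fit") {
    structure(list(
      structure = x$structure, weighting = x$weighting,
      outcome = x$outcome,
      tooth_set = as.integer(unlist(x$tooth_set)),
      fits = lapply(x$fits, core_from_list),
      logLik = x$logLik, k = x$k, aic = x$aic, n = x$n,
      n_by_sex = list_to_named(x$n_by_sex),
      age_pvalues = list_to_named(x$age_pvalues),
      p_common = isTRUE(x$p_common),
      slopes = list_to_named(x$slopes),
      slope_se = list_to_named(x$slope_se),
      age_range = as.numeric(unlist(x$age_range)),
      y_range = as.numeric(unlist(x$y_range))), class = "molar_fit")
  } else if (x$kind == "bivariate_fit") {
    fix_spec <- function(s) {
      s$tooth_set <- as.integer(unlist(s$tooth_set)); s
    }
    structure(list(
      specA = fix_spec(x$specA), specB = fix_spec(x$specB),
      coefA = list_to_named(x$coefA), coefB = list_to_named(x$coefB),
      sigmaA = x$sigmaA, sigmaB = x$sigmaB, rho = x$rho,
      logLik = x$logLik, n_pairs = x$n_pairs,
      n_A_only = x$n_A_only, n_B_only = x$n_B_only,
      y_range_A = as.numeric(unlist(x$y_range_A)),
      y_range_B = as.numeric(unlist(x$y_range_B)),
      convergence = x$convergence), class = "bivariate_fit")
  } else stop("unknown model kind: ", x$kind, call. = FALSE)
}

posterior_to_list <- function(post) {
  list(schema_version = SCHEMA_VERSION, kind = "age_posterior",
       sex = post$sex, y = named_to_list(post$y),
       prior = list(lower = post$prior$lower, upper = post$prior$upper,
                    threshold = post$prior$threshold),
       p_over = post$p_over,
       p_over_single = if (!is.null(post$p_over_single))
         named_to_list(post$p_over_single),
       ages = post$ages, density = post$density)
}

#' Write a posterior result to JSON
#'
#' @param post an `age_posterior`.
#' @param path output file.
#' @export
write_posterior_json <- function(post, path) {
  jsonlite::write_json(posterior_to_list(post), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
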