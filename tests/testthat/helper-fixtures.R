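# Small fixtures built in code; no data files.

# hand-built cohort: 3 participants, lower-right molars
tiny_cohort <- function() {
  data.frame(
    participant_id = c("P1", "P1", "P2", "P2", "P3"),
    sex = c("F", "F", "M", "M", "F"),
    age_years = c(16.5, 16.5, 20.25, 20.25, 18.0),
    tooth_fdi = c(46L, 47L, 46L, 47L, 47L),
    hard_ml = c(1.10, 1.00, 1.20, 1.10, 0.95),
    hsst_ml = c(0.041, 0.047, 0.058, 0.070, 0.050),
    lsst_ml = c(0.021, 0.021, 0.028, 0.028, 0.020))
}

# response table for direct fit_wls use
make_response <- function(age, sex, y) {
  data.frame(participant_id = sprintf("P%03d", seq_along(age)),
             sex = sex, age = age, y = y)
}

# volumes with a given 4a fraction and hsst:lsst ratio, unit total
volumes_for_4a <- function(p4a, ratio = 2) {
  soft <- p4a
  data.frame(hard_ml = 1 - soft,
             hsst_ml = soft * ratio / (1 + ratio),
             lsst_ml = soft / (1 + ratio))
}

# a plug-in molar_fit built by hand (known coefficients, no vcov),
# mirroring the internal structure; used to create exact scenarios such as
# a zero slope
manual_fit <- function(intercept, slope, sigma2, weighting = "constant",
                       structure = "i", df_resid = 50) {
  coef <- c("(Intercept)" = intercept, "age" = slope)
  p <- length(coef)
  core <- list(coef = coef,
               vcov = matrix(0, p, p, dimnames = list(names(coef), names(coef))),
               se = rep(NA_real_, p), p = rep(NA_real_, p),
               sigma2 = sigma2, sigma2_ml = sigma2, df_resid = df_resid,
               n = df_resid + p, logLik = NA_real_, k = p + 1L)
  structure(list(structure = structure, weighting = weighting,
                 outcome = "4a", tooth_set = 47L,
                 fits = list(all = core), logLik = NA_real_, k = p + 1L,
                 aic = NA_real_, n = df_resid + p,
                 n_by_sex = c(F = NA_integer_, M = NA_integer_),
                 age_pvalues = c(F = NA_real_, M = NA_real_),
                 p_common = FALSE, slopes = c(F = slope, M = slope),
                 slope_se = c(F = NA_real_, M = NA_real_),
                 y_range = c(intercept + slope * 23, intercept + slope * 14)),
            class = "molar_fit")
}

# generating parameters with a strong sex difference on the 2nd molar,
# used by structure-recovery simulations
strong_sexdiff_params <- function() {
  p <- molarAge:::default_type_params()
  p$m2$intercept <- c(F = -2.0, M = -1.0)
  p$m2$slope <- c(F = -0.03, M = -0.09)
  p
}
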