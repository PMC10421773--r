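#' Uniform age prior
#'
#' The prior age distribution for Bayesian age assessment: uniform between a
#' lower bound given by 3rd-molar development (14 years) and a deliberately
#' conservative upper bound (23 years). Raising the upper bound raises the
#' risk of falsely classifying a minor as older than 18, so both bounds must
#' straddle the 18-year threshold.
#'
#' @param lower,upper prior support in years (defaults 14 and 23).
#' @param threshold the legal adulthood threshold in years (default 18);
#'   must lie strictly inside the support.
#' @return object of class `age_prior`.
#' @export
age_prior <- function(lower = 14, upper = 23, threshold = 18) {
  if (!(lower < threshold && threshold < upper))
    stop("prior must satisfy lower < threshold < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper, threshold = threshold),
            class = "age_prior")
}

#' Likelihood of an observed log-outcome given age
#'
#' Gaussian predictive density of the observed log transformation outcome
#' `y` at candidate age `a`: mean from the fitted mean structure, variance
#' `sigma2 * v(age)` plus (by default) the parameter-uncertainty term
#' `x' Cov(beta) x`, so that the likelihood's width is consistent with the
#' model's 95% prediction interval.
#'
#' @param fit a `molar_fit`.
#' @param y observed log-outcome (scalar).
#' @param age vector of candidate ages.
#' @param sex `"F"` or `"M"`.
#' @param include_param_uncertainty include `x' Cov(beta) x` (default
#'   `TRUE`).
#' @return vector of density values.
#' @export
obs_likelihood <- function(fit, y, age, sex, include_param_uncertainty = TRUE) {
  pm <- predictive_moments(fit, age, sex, include_param_uncertainty)
  stats::dnorm(y, mean = pm$mean, sd = sqrt(pm$var))
}

# trapezoid rule on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

posterior_grid <- function(prior, grid_step) {
  sort(unique(c(seq(prior$lower, prior$upper, by = grid_step),
                prior$threshold, prior$upper)))
}

finish_posterior <- function(ages, dens, prior, y, sex, extra = list()) {
  z <- trapz(ages, dens)
  if (!is.finite(z) || z <= 0)
    stop("observation incompatible with model support over the prior range",
         call. = FALSE)
  dens <- dens / z
  # the grid always contains the threshold, so the tail integral is exact
  idx <- which(ages >= prior$threshold)
  p_over <- trapz(ages[idx], dens[idx])
  structure(c(list(ages = ages, density = dens, p_over = p_over,
                   prior = prior, y = y, sex = sex), extra),
            class = "age_posterior")
}

#' Posterior age density and the probability of being older than 18
#'
#' Applies Bayes' theorem on a uniform age grid: posterior density
#' proportional to `obs_likelihood(y | age, sex)` times the uniform prior,
#' normalized by the trapezoid rule; `P(age > threshold)` is the trapezoid
#' integral above the threshold. The grid is anchored so that the threshold
#' is a grid point.
#'
#' @inheritParams obs_likelihood
#' @param prior an [age_prior()].
#' @param grid_step grid resolution in years, at most 0.05 (default 0.01).
#' @return object of class `age_posterior` with fields `ages`, `density`,
#'   `p_over`, `prior`, `y`, `sex`.
#' @export
posterior_age <- function(fit, y, sex, prior = age_prior(),
                          grid_step = 0.01, include_param_uncertainty = TRUE) {
  stopifnot(inherits(prior, "age_prior"))
  if (grid_step > 0.05) stop("grid_step must be <= 0.05 years", call. = FALSE)
  ages <- posterior_grid(prior, grid_step)
  dens <- obs_likelihood(fit, y, ages, sex, include_param_uncertainty)
  finish_posterior(ages, dens, prior, y, sex)
}

#' @export
print.age_posterior <- function(x, ...) {
  ys <- paste(formatC(x$y, digits = 4, format = "g"), collapse = ", ")
  cat(sprintf("<age_posterior> sex %s, y = %s, prior U(%.1f, %.1f)\n",
              x$sex, ys, x$prior$lower, x$prior$upper))
  cat(sprintf("  P(age > %g) = %.3f\n", x$prior$threshold, x$p_over))
  if (!is.null(x$p_over_single)) {
    cat("  single-tooth P(>", x$prior$threshold, "): ",
        paste(sprintf("%s = %.3f", names(x$p_over_single), x$p_over_single),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Hypothetical observations spaced between observed extremes
#'
#' For illustrating age assessment, hypothetical log-outcome observations
#' are placed in uniform intervals between the minimum and maximum observed
#' response values.
#'
#' @param y_range numeric length-2: observed min and max of the log-outcome
#'   (a `molar_fit` carries this as `$y_range`).
#' @param n number of hypothetical observations (default 4).
#' @return numeric vector of length `n`.
#' @export
hypothetical_observations <- function(y_range, n = 4) {
  stopifnot(length(y_range) == 2, n >= 1)
  seq(y_range[1], y_range[2], length.out = n + 2)[2:(n + 1)]
}
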