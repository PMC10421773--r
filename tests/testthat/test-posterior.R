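test_that("likelihood matches a direct normal-density evaluation", {
  co <- generate_cohort(synthetic_config(teeth = 47), seed = 73)
  f <- fit_wls(build_response(co, "4a", 47), "iii", "inv_age")
  ages <- c(14.5, 18, 22.75)
  y <- -2.6
  for (inc in c(TRUE, FALSE)) {
    got <- obs_likelihood(f, y, ages, "M", include_param_uncertainty = inc)
    # direct evaluation from the stored coefficients
    x <- cbind(1, 0 * ages, ages)  # (Intercept), age:sexF, age:sexM for males
    mu <- drop(x %*% f$fits$all$coef)
    v <- f$fits$all$sigma2 / ages
    if (inc) v <- v + diag(x %*% f$fits$all$vcov %*% t(x))
    expect_equal(got, dnorm(y, mu, sqrt(v)), tolerance = 1e-12)
  }
})

test_that("flat likelihood gives a uniform posterior and P(>18) = 5/9", {
  f0 <- manual_fit(intercept = -2.5, slope = 0, sigma2 = 0.04)
  post <- posterior_age(f0, y = -2.5, sex = "F",
                        include_param_uncertainty = FALSE)
  expect_equal(post$p_over, 5 / 9, tolerance = 1e-12)
  expect_equal(diff(range(post$density)), 0, tolerance = 1e-12)
  expect_equal(post$density[1], 1 / 9, tolerance = 1e-12)
})

test_that("posterior normalizes to one and respects bounds", {
  co <- generate_cohort(synthetic_config(teeth = 47), seed = 79)
  f <- fit_wls(build_response(co, "4a", 47), "iii", "inv_age")
  for (y in hypothetical_observations(f$y_range)) {
    post <- posterior_age(f, y, "F")
    integral <- sum(diff(post$ages) *
                      (head(post$density, -1) + tail(post$density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-6)
    expect_true(all(post$density >= 0))
    expect_gte(post$p_over, 0); expect_lte(post$p_over, 1)
    expect_equal(range(post$ages), c(14, 23))
  }
})

test_that("with a negative slope, smaller observations mean older", {
  f <- manual_fit(intercept = -1.4, slope = -0.065, sigma2 = 0.02)
  ys <- seq(-3.1, -2.3, by = 0.2)
  p <- vapply(ys, function(y)
    posterior_age(f, y, "M", include_param_uncertainty = FALSE)$p_over, 0)
  expect_true(all(diff(p) < 0))
})

test_that("grid refinement converges: default step vs 1e-4 within 1e-4", {
  f <- manual_fit(intercept = -1.4, slope = -0.065, sigma2 = 0.02)
  for (y in c(-2.9, -2.6, -2.4)) {
    p_coarse <- posterior_age(f, y, "M", grid_step = 0.01,
                              include_param_uncertainty = FALSE)$p_over
    p_fine <- posterior_age(f, y, "M", grid_step = 1e-4,
                            include_param_uncertainty = FALSE)$p_over
    expect_equal(p_coarse, p_fine, tolerance = 1e-4)
    p_half <- posterior_age(f, y, "M", grid_step = 0.005,
                            include_param_uncertainty = FALSE)$p_over
    expect_lt(abs(p_coarse - p_half), 1e-5)
  }
})

test_that("raising the prior upper bound never lowers P(>18)", {
  f <- manual_fit(intercept = -1.4, slope = -0.065, sigma2 = 0.02)
  for (y in c(-2.9, -2.6, -2.4)) {
    p23 <- posterior_age(f, y, "M", age_prior(14, 23))$p_over
    p24 <- posterior_age(f, y, "M", age_prior(14, 24))$p_over
    expect_gte(p24, p23 - 1e-12)
  }
})

test_that("posterior input contracts are enforced", {
  f <- manual_fit(intercept = -1.4, slope = -0.065, sigma2 = 0.02)
  expect_error(posterior_age(f, -2.6, "M", grid_step = 0.1), "grid_step")
  expect_error(age_prior(19, 23), "lower < threshold < upper")
  expect_error(age_prior(14, 17.9), "lower < threshold < upper")
  # an observation impossibly far from the model support
  f_tight <- manual_fit(intercept = -1.4, slope = -0.065, sigma2 = 1e-12)
  expect_error(posterior_age(f_tight, 10, "M"), "incompatible")
})

test_that("hypothetical observations sit in uniform interior intervals", {
  h <- hypothetical_observations(c(0, 1), n = 4)
  expect_equal(h, c(0.2, 0.4, 0.6, 0.8), tolerance = 1e-12)
  expect_equal(diff(h), rep(h[1], 3), tolerance = 1e-12)
})

test_that("prediction interval brackets the point fit symmetrically", {
  co <- generate_cohort(synthetic_config(teeth = 47), seed = 83)
  f <- fit_wls(build_response(co, "4a", 47), "iii", "inv_age")
  pi95 <- prediction_interval(f, c(15, 18, 21), "F")
  expect_true(all(pi95$lwr < pi95$fit & pi95$fit < pi95$upr))
  expect_equal(pi95$upr - pi95$fit, pi95$fit - pi95$lwr, tolerance = 1e-12)
  pi80 <- prediction_interval(f, c(15, 18, 21), "F", level = 0.8)
  expect_true(all(pi80$upr - pi80$lwr < pi95$upr - pi95$lwr))
})
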