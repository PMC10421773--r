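test_that("build_response aggregates per participant and tracks counts", {
  co <- tiny_cohort()
  r47 <- build_response(co, "4a", 47)
  expect_equal(nrow(r47), 3L)
  expect_equal(r47$y, compute_outcomes(co[co$tooth_fdi == 47, ],
                                       log = TRUE)[, "4a"],
               ignore_attr = TRUE)
  # two teeth -> mean of log outcomes
  rboth <- build_response(co, "4a", c(46, 47))
  y46 <- compute_outcomes(co[co$tooth_fdi == 46, ], log = TRUE)[, "4a"]
  expect_equal(rboth$y[rboth$participant_id == "P1"],
               mean(c(y46[1], r47$y[r47$participant_id == "P1"])))
  expect_equal(attr(rboth, "n_by_sex"), c(F = 2L, M = 1L))
  expect_error(build_response(co, "4a", 16), "no usable observations")
})

test_that("replica cohort reproduces the reference per-tooth counts", {
  co <- generate_cohort(fig4_replica_config(), seed = 5)
  cnt <- reference_tooth_counts()
  for (key in c("M47", "M46", "F47", "F16")) {
    s <- substr(key, 1, 1); fdi <- as.integer(substr(key, 2, 3))
    r <- build_response(co[co$sex == s, ], "4a", fdi)
    expect_equal(nrow(r), unname(cnt[[key]]))
  }
})

test_that("two points are interpolated exactly", {
  resp <- make_response(c(14, 23), c("F", "F"), c(0, 9))
  f <- fit_wls(resp, "i", "constant")
  expect_equal(unname(f$fits$all$coef), c(-14, 1))
  expect_equal(f$fits$all$sigma2_ml, 0)
})

test_that("WLS matches lm() and a generic numerical minimizer", {
  set.seed(41)
  n <- 40
  resp <- make_response(runif(n, 14, 24), sample(c("F", "M"), n, TRUE),
                        rnorm(n))
  for (wt in variance_weightings()) {
    w <- switch(wt, constant = rep(1, n), age = 1 / resp$age,
                inv_age = resp$age)
    f <- fit_wls(resp, "ii", wt)
    lmf <- lm(y ~ sex + age, data = resp, weights = w)
    expect_equal(unname(f$fits$all$coef), unname(coef(lmf)), tolerance = 1e-10)
    expect_equal(f$logLik, as.numeric(logLik(lmf)), tolerance = 1e-8)
    expect_equal(f$aic, AIC(lmf), tolerance = 1e-8)
    expect_equal(f$age_pvalues[["M"]],
                 summary(lmf)$coefficients["age", 4], tolerance = 1e-10)
    # generic numerical weighted least squares agrees with the closed form
    X <- cbind(1, as.numeric(resp$sex == "M"), resp$age)
    rss <- function(b) sum(w * (resp$y - X %*% b)^2)
    num <- optim(c(0, 0, 0), rss, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(unname(f$fits$all$coef), num$par, tolerance = 1e-6)
  }
})

test_that("logLik equals a brute-force weighted Gaussian density sum", {
  resp <- make_response(c(14.2, 15.1, 16.3, 17.8, 18.4, 19.9, 20.5, 21.1,
                          22.6, 23.4),
                        rep(c("F", "M"), 5),
                        c(-2.1, -2.3, -2.2, -2.6, -2.4, -2.8, -2.7, -2.9,
                          -3.0, -3.1))
  f <- fit_wls(resp, "iii", "inv_age")
  mu <- ifelse(resp$sex == "F",
               f$fits$all$coef[["(Intercept)"]] +
                 f$fits$all$coef[["age:sexF"]] * resp$age,
               f$fits$all$coef[["(Intercept)"]] +
                 f$fits$all$coef[["age:sexM"]] * resp$age)
  sd_i <- sqrt(f$fits$all$sigma2_ml / resp$age)  # Var = sigma2 * (1/age)
  expect_equal(f$logLik, sum(dnorm(resp$y, mu, sd_i, log = TRUE)),
               tolerance = 1e-10)
  expect_equal(f$aic, 2 * f$k - 2 * f$logLik)
})

test_that("structure v sums the per-sex fits", {
  set.seed(43)
  resp <- make_response(runif(30, 14, 24), rep(c("F", "M"), 15), rnorm(30))
  fv <- fit_wls(resp, "v", "constant")
  fF <- fit_wls(resp[resp$sex == "F", ], "i", "constant")
  fM <- fit_wls(resp[resp$sex == "M", ], "i", "constant")
  expect_equal(fv$logLik, fF$logLik + fM$logLik)
  expect_equal(fv$aic, fF$aic + fM$aic)
  expect_equal(fv$age_pvalues,
               c(F = fF$age_pvalues[["F"]], M = fM$age_pvalues[["M"]]))
})

test_that("one-sex data breaks sex structures with a named error", {
  resp <- make_response(c(14, 17, 20, 23), rep("M", 4), c(1, 2, 3, 4))
  expect_error(fit_wls(resp, "iv", "constant"), "structure iv")
  expect_error(fit_wls(resp, "v", "constant"), "structure v")
  expect_silent(fit_wls(resp, "i", "constant"))
})

test_that("richer structures cannot fit worse in weighted RSS", {
  set.seed(47)
  n <- 60
  resp <- make_response(runif(n, 14, 24), rep(c("F", "M"), n / 2),
                        rnorm(n))
  rss_w <- function(f) f$fits$all$sigma2_ml * f$n
  expect_lte(rss_w(fit_wls(resp, "iv", "age")),
             rss_w(fit_wls(resp, "iii", "age")) + 1e-12)
  expect_lte(rss_w(fit_wls(resp, "iv", "age")),
             rss_w(fit_wls(resp, "ii", "age")) + 1e-12)
  # constant weighting is plain OLS
  f1 <- fit_wls(resp, "i", "constant")
  expect_equal(unname(f1$fits$all$coef),
               unname(coef(lm(y ~ age, data = resp))), tolerance = 1e-12)
})

test_that("parameter recovery within 3 SE under (iii, inv_age) at n=500", {
  p <- molarAge:::default_type_params()
  cfg <- synthetic_config(n_f = 250, n_m = 250, teeth = 47, params = p)
  co <- generate_cohort(cfg, seed = 53)
  f <- fit_wls(build_response(co, "4a", 47), "iii", "inv_age")
  truth <- c(p$m2$intercept[["F"]], p$m2$slope[["F"]], p$m2$slope[["M"]])
  est <- f$fits$all$coef[c("(Intercept)", "age:sexF", "age:sexM")]
  se <- f$fits$all$se[c("(Intercept)", "age:sexF", "age:sexM")]
  expect_true(all(abs(est - truth) < 3 * se))
  # sigma recovery: sigma2 is the weighted residual variance
  expect_equal(sqrt(f$fits$all$sigma2), p$m2$sigma[["F"]], tolerance = 0.15)
})

test_that("AIC selection: no sex signal keeps the sexless model", {
  set.seed(59)
  age <- runif(40, 14, 24)
  y <- -1 - 0.06 * age + rnorm(40, sd = 0.1)
  # duplicate the same observations under both sex labels
  resp <- make_response(c(age, age), rep(c("F", "M"), each = 40), c(y, y))
  sel <- select_structure(resp, weightings = "constant")
  expect_equal(sel$fit$structure, "i")
})

test_that("grid restriction and selection bookkeeping work", {
  set.seed(61)
  resp <- make_response(runif(30, 14, 24), rep(c("F", "M"), 15), rnorm(30))
  sel <- select_structure(resp, structures = "ii", weightings = "age")
  expect_equal(sel$fit$structure, "ii")
  expect_equal(sel$fit$weighting, "age")
  expect_equal(nrow(sel$grid), 1L)
  full <- select_structure(resp)
  expect_equal(nrow(full$grid), 15L)
  expect_equal(min(full$grid$aic), full$fit$aic)
})

test_that("ranking puts the informative outcome first and noise last", {
  co <- generate_cohort(synthetic_config(teeth = c(46, 47)), seed = 67)
  ranked <- rank_candidates(co, c("4a", "1"), list(47L))
  # 4a carries the age signal; outcome 1 (total) has none by construction
  expect_equal(ranked$outcome[1], "4a")
  expect_equal(ranked$outcome[2], "1")
  expect_lt(ranked$p_min[1], 1e-4)
  expect_gt(ranked$p_min[2], 0.01)
  expect_equal(ranked$rank, c(1L, 2L))
  single <- rank_candidates(co, "4a", list(c(46L, 47L)))
  expect_equal(nrow(single), 1L)
  expect_equal(single$rank, 1L)
})

test_that("age t-test holds its nominal 5% size under the null", {
  set.seed(71)
  reps <- 2000
  rej <- logical(reps)
  age <- runif(30, 14, 24)
  sex <- rep(c("F", "M"), 15)
  for (i in seq_len(reps)) {
    resp <- make_response(age, sex, rnorm(30))
    f <- fit_wls(resp, "i", "constant")
    rej[i] <- f$age_pvalues[["F"]] < 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 2 * mc_se + 1e-12)
})
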