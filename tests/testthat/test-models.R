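# Covariate construction and the multilinear reconfiguration models.

test_that("drinking score extracts a sign-fixed first principal component", {
  set.seed(51)
  base <- rnorm(20, 10, 3)
  # four copies of one variable: rank-1 correlation, all variance on PC1
  ds <- drinking_score(base, base, base, base)
  expect_equal(ds$variance_explained, 1)
  expect_gt(ds$loadings["audit"], 0)
  expect_equal(mean(ds$scores), 0, tolerance = 1e-10)
  # independent long columns: eigenvalues of an identity correlation
  n <- 20000
  ds2 <- drinking_score(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  expect_equal(ds2$variance_explained, 0.25, tolerance = 0.02)
  # negating every input leaves |scores| unchanged (sign convention reapplies)
  a <- rnorm(30); b <- a + rnorm(30, sd = .5); c1 <- a + rnorm(30, sd = .5)
  d1 <- a + rnorm(30, sd = .5)
  s_pos <- drinking_score(a, b, c1, d1)
  s_neg <- drinking_score(-a, -b, -c1, -d1)
  expect_equal(abs(s_pos$scores), abs(s_neg$scores), tolerance = 1e-10)
  expect_gt(s_neg$loadings["audit"], 0)
  expect_error(drinking_score(a, b, c1, rep(2, 30)), "drinks_per_drinking_day")
})

test_that("SSRT subtracts mean delay from the failure-rate Go percentile", {
  expect_equal(ssrt(rep(400, 10), ssds = 150, stop_failure_rate = 0.3), 250)
  expect_equal(ssrt(c(300, 350, 400, 450, 500), ssds = 200,
                    stop_failure_rate = 0.5), 200)
  # rate 0.5 equals the median-based estimate
  g <- c(310, 340, 360, 420, 480, 520, 700)
  expect_equal(ssrt(g, ssds = c(100, 200), stop_failure_rate = 0.5),
               median(g) - 150)
  # interpolated percentile
  expect_equal(ssrt(c(300, 400), ssds = 0, stop_failure_rate = 0.25), 325)
  expect_error(ssrt(numeric(0), 100, 0.5), "Empty")
  expect_error(ssrt(400, 100, 1), "between")
})

toy_covariates <- function(n, seed = 52) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    sex = rep_len(c(0, 1), n), age = rnorm(n, 22, 1.5),
    education = rnorm(n, 15, 1), ssrt = rnorm(n, 240, 50),
    cesd = pmax(rnorm(n, 6, 5), 0), drinking_score = rnorm(n),
    fha = rep_len(c(1, 0, 0), n)
  )
}

test_that("OLS fit matches the normal equations and reports additive R2", {
  X <- toy_covariates(20)
  ord <- c("sex", "age", "cesd")
  set.seed(53)
  y <- 0.2 + 0.05 * X$sex - 0.01 * X$age + 0.002 * X$cesd + rnorm(20, sd = 0.02)
  fit <- fit_reconfig_model(y, X, predictor_order = ord)
  D <- cbind(1, X$sex, X$age, X$cesd)
  beta_hat <- solve(t(D) %*% D, t(D) %*% y)
  expect_equal(unname(coef(fit)), drop(beta_hat), tolerance = 1e-10)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-10)
  # additive R2 nondecreasing, last equals full-model R2
  expect_true(all(diff(fit$additive_r2) >= -1e-12))
  expect_equal(unname(fit$additive_r2[length(ord)]), glance(fit)$r_squared)
  # exactly linear response: R2 = 1, residuals 0
  y0 <- 0.1 + 0.02 * X$sex + 0.003 * X$age - 0.001 * X$cesd
  suppressWarnings({   # summary.lm warns on an exact fit
    fit0 <- fit_reconfig_model(y0, X, predictor_order = ord)
    expect_equal(glance(fit0)$r_squared, 1)
  })
  expect_lt(max(abs(residuals(fit0))), 1e-12)
  # tidy/glance surface
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", ord))
  expect_true(all(c("estimate", "std_error", "p_value") %in% names(td)))
})

test_that("final-model coefficients do not depend on predictor order", {
  X <- toy_covariates(30)
  set.seed(54)
  y <- rnorm(30, 0.7, 0.05)
  ord1 <- c("sex", "age", "education", "ssrt", "cesd", "drinking_score", "fha")
  ord2 <- rev(ord1)
  f1 <- fit_reconfig_model(y, X, ord1)
  f2 <- fit_reconfig_model(y, X, ord2)
  expect_equal(coef(f1)[names(coef(f2))], coef(f2), tolerance = 1e-12)
  expect_equal(glance(f1)$r_squared, glance(f2)$r_squared)
  # only the additive sequence differs; both end at the same R2
  expect_equal(unname(f1$additive_r2[7]), unname(f2$additive_r2[7]))
  # appending a predictor never decreases R2
  expect_gte(glance(f1)$r_squared + 1e-12,
             unname(f1$additive_r2[3]))
  # collinear design errors with the offending column named
  X_bad <- X
  X_bad$dup <- 2 * X_bad$age
  expect_error(fit_reconfig_model(y, X_bad, c(ord1, "dup")), "collinear")
})

test_that("model leave-one-out flags influential folds and tightens with n", {
  X <- toy_covariates(30)
  set.seed(55)
  y <- 0.5 + 0.1 * X$drinking_score + rnorm(30, sd = 0.02)
  y[7] <- y[7] + 1   # gross outlier
  loo <- loo_model_stability(y, X, c("drinking_score", "age"))
  expect_equal(nrow(loo), 30 * 3)
  expect_identical(attr(loo, "mode"), "model_loo")
  # the outlier's own exclusion fold deviates most from the full fit
  full <- coef(fit_reconfig_model(y, X, c("drinking_score", "age")))
  dev <- dplyr::summarise(
    dplyr::group_by(loo, fold),
    d = sqrt(sum((estimate - full[term])^2)), .groups = "drop")
  expect_equal(dev$fold[which.max(dev$d)], "7")
  # coefficient spread shrinks as n grows
  spread <- function(n, seed) {
    Xn <- toy_covariates(n, seed)
    set.seed(seed + 1)
    yn <- 0.5 + 0.1 * Xn$drinking_score + rnorm(n, sd = 0.05)
    lo <- loo_model_stability(yn, Xn, c("drinking_score", "age"))
    sd(lo$estimate[lo$term == "drinking_score"])
  }
  expect_lt(spread(100, 60), spread(30, 60))
})

test_that("reference leave-one-out reprojects every participant per fold", {
  coh <- small_cohort(n = 6, p = 8, seed = 61)
  fc_tbl <- cohort_fc(coh$timeseries, coh$scheme)
  loo <- loo_reference_stability(fc_tbl, coh$covariates,
                                 transition = c("R1.2", "SST"),
                                 predictor_order = c("age", "cesd"),
                                 lambda = 0.01)
  expect_equal(nrow(loo), 6 * 3)  # 6 folds x (intercept + 2 predictors)
  expect_identical(attr(loo, "mode"), "reference_loo")
  shifts <- attr(loo, "reference_shift")
  expect_length(shifts, 6)
  expect_true(all(shifts > 0))
  # when every subject shares one R1.1 FC, all folds give the same reference
  fc_same <- fc_tbl
  shared <- fc_same$fc[fc_same$segment == "R1.1"][[1]]
  fc_same$fc[fc_same$segment == "R1.1"] <- rep(list(shared), 6)
  loo_same <- loo_reference_stability(fc_same, coh$covariates,
                                      transition = c("R1.2", "SST"),
                                      predictor_order = c("age", "cesd"),
                                      lambda = 0.01)
  expect_lt(max(attr(loo_same, "reference_shift")), 1e-6)
})

test_that("an aberrant reference-segment connectome moves the reference most when present", {
  coh <- small_cohort(n = 5, p = 8, seed = 62)
  fc_tbl <- cohort_fc(coh$timeseries, coh$scheme)
  # push subject 3 far from the rest in R1.1
  i3 <- which(fc_tbl$segment == "R1.1" & fc_tbl$subject_id == "S03")
  M <- fc_tbl$fc[[i3]]
  far <- stats::cov2cor(M + 5 * tcrossprod(rnorm(8)))
  fc_tbl$fc[[i3]] <- (far + t(far)) / 2
  loo <- loo_reference_stability(fc_tbl, coh$covariates,
                                 transition = c("R1.2", "SST"),
                                 predictor_order = c("age"),
                                 lambda = 0.01)
  shifts <- attr(loo, "reference_shift")
  expect_equal(names(which.max(shifts)), "S03")
})

test_that("regularization sweep shrinks tangent variance monotonically", {
  coh <- small_cohort(n = 9, p = 10, seed = 63)
  fc_tbl <- cohort_fc(coh$timeseries, coh$scheme)
  lams <- c(0.01, 0.1, 1, 10)
  sw <- regularization_sweep(fc_tbl, coh$covariates, lambdas = lams,
                             transitions = list(engaging = c("R1.2", "SST")),
                             predictor_order = c("age", "cesd"))
  tv <- unique(sw[, c("lambda", "tangent_variance")])
  expect_equal(tv$lambda, lams)
  expect_true(all(diff(tv$tangent_variance) < 0))
  # one row per lambda x term for the single transition
  expect_equal(nrow(sw), length(lams) * 3)
  # a single lambda reduces to the single-model pipeline
  sw1 <- regularization_sweep(fc_tbl, coh$covariates, lambdas = 0.01,
                              transitions = list(engaging = c("R1.2", "SST")),
                              predictor_order = c("age", "cesd"))
  expect_equal(sw1$estimate, sw$estimate[sw$lambda == 0.01])
  expect_error(regularization_sweep(fc_tbl, coh$covariates,
                                    lambdas = c(1, 0.1)), "increasing")
})
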