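test_that("an exact linear relation is recovered perfectly", {
  set.seed(1)
  d <- data.frame(x = rnorm(30), m = runif(30, 80, 300))
  d$y <- d$x
  ft <- fit_moderation(d, model_spec("y", "x", "m"))
  b <- setNames(ft$coefficients$beta, ft$coefficients$term)
  expect_equal(unname(b["x"]), 1, tolerance = 1e-10)
  expect_equal(max(abs(ft$residuals)), 0, tolerance = 1e-10)
  expect_equal(ft$r2_adj, 1, tolerance = 1e-10)
})

test_that("HC0 equals the element-wise loop oracle and the reference library", {
  set.seed(5)
  n <- 12; p <- 3
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  e <- rnorm(n)
  V <- hc0_covariance(X, e)
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, p, p)
  for (i in seq_len(n))
    meat <- meat + e[i]^2 * (X[i, ] %o% X[i, ])
  expect_lt(max(abs(V - bread %*% meat %*% bread)), 1e-12)

  ft <- random_fit(8)
  ref <- sandwich::vcovHC(ft$lm, type = "HC0")
  expect_lt(max(abs(unname(ft$vcov_hc0) - unname(ref))), 1e-10)
})

test_that("HC0 degenerate and identity cases", {
  set.seed(6)
  X <- cbind(1, rnorm(10))
  expect_equal(max(abs(hc0_covariance(X, rep(0, 10)))), 0)
  # orthonormal design with +/-c residuals: V = c^2 (X'X)^-1
  Q <- qr.Q(qr(matrix(rnorm(16), 8)))  # 8 x 2? build explicitly
  Q <- qr.Q(qr(matrix(rnorm(8 * 2), 8, 2)))
  e <- rep(c(0.3, -0.3), 4)
  # residuals of constant magnitude: meat = c^2 X'X, so V = c^2 (X'X)^-1
  expect_equal(hc0_covariance(Q, e), 0.09 * solve(crossprod(Q)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(hc0_covariance(X, rep(0, 9)), class = "mrsma_validation_error")
  expect_error(hc0_covariance(cbind(X, X[, 2]), rep(0, 10)),
               class = "mrsma_rank_error")
})

test_that("rank deficiency and insufficient cases raise informative errors", {
  set.seed(9)
  d <- data.frame(x = rnorm(20), m = runif(20, 80, 300))
  d$x2 <- d$x
  d$y <- d$x + rnorm(20)
  err <- expect_error(
    fit_moderation(d, model_spec("y", c("x", "x2"), "m")),
    class = "mrsma_rank_error")
  expect_match(conditionMessage(err), "x2")
  expect_error(fit_moderation(d[1:5, ], model_spec("y", "x", "m")),
               class = "mrsma_validation_error")
  expect_error(fit_moderation(d, model_spec("y", "absent_col", "m")),
               class = "mrsma_validation_error")
})

test_that("standardized fits are invariant to affine rescaling of inputs", {
  fr <- small_frame(seed = 13, n_per_group = 30)
  sp <- model_spec("ma_t1", "Glutamate_IPS_t1", "age_months_t1")
  a <- fit_moderation(fr, sp)
  fr2 <- fr
  fr2$age_months_t1 <- fr$age_months_t1 / 12 + 3     # months -> shifted years
  fr2$Glutamate_IPS_t1 <- fr$Glutamate_IPS_t1 * 100
  b <- fit_moderation(fr2, sp)
  expect_equal(a$coefficients$beta, b$coefficients$beta, tolerance = 1e-10)
  expect_equal(a$coefficients$se_hc0, b$coefficients$se_hc0, tolerance = 1e-10)
})

test_that("full-model R2 never falls below the reduced model's", {
  for (s in 1:5) {
    ft <- random_fit(40 + s)
    expect_gte(ft$r2 + 1e-12, ft$r2_reduced)
  }
})

test_that("an orthogonal covariate leaves the interaction untouched", {
  fr <- small_frame(seed = 17, n_per_group = 30, missing_rate = 0)
  fr <- fr[complete.cases(fr[c("ma_t1", "Glutamate_IPS_t1", "age_months_t1")]), ]
  sp <- model_spec("ma_t1", "Glutamate_IPS_t1", "age_months_t1")
  base <- fit_moderation(fr, sp)
  set.seed(99)
  v <- rnorm(nrow(fr))
  fr$orth <- residuals(lm(v ~ base$X[, -1] + base$lm$model$.y))
  with_cov <- fit_moderation(fr, model_spec("ma_t1", "Glutamate_IPS_t1",
                                            "age_months_t1",
                                            covariates = "orth"))
  gi <- function(f) f$coefficients$beta[grepl("_x_", f$coefficients$term)]
  expect_equal(gi(with_cov), gi(base), tolerance = 1e-6)
})

test_that("a covariate identical to the outcome is rejected, not absorbed", {
  fr <- small_frame(seed = 19, n_per_group = 25)
  expect_error(model_spec("ma_t1", "Glutamate_IPS_t1", "age_months_t1",
                          covariates = "ma_t1"),
               class = "mrsma_validation_error")
  fr$copy <- fr$ma_t1
  expect_error(
    fit_moderation(fr, model_spec("ma_t1", "Glutamate_IPS_t1",
                                  "age_months_t1", covariates = "copy")),
    class = "mrsma_degenerate_error")
})

test_that("specificity model needs all four measures and reports per term", {
  fr <- small_frame(seed = 23, n_per_group = 30)
  ft <- specificity_model(fr, 1)
  expect_equal(sum(grepl("_x_", ft$coefficients$term)), 4)
  expect_equal(nrow(ft$coefficients), 2 + 2 * 4)
  fr$Glutamate_MFG_t1 <- NULL
  expect_error(specificity_model(fr, 1), class = "mrsma_validation_error")
})

test_that("prediction model uses retained participants and the age covariate", {
  fr <- analysis_frame(generate_cohort(cohort_config(seed = 29, missing_rate = 0)))
  ft <- predict_future_ma(fr)
  # n within binomial 99% bounds of the retention rate
  bounds <- qbinom(c(0.005, 0.995), 255, 0.69)
  expect_gte(ft$n, bounds[1])
  expect_lte(ft$n, bounds[2])
  expect_true("age_months_t2" %in% ft$terms$covariates)
  expect_identical(ft$spec$vif_exempt, "age_months_t2")
  # listwise accounting: df = complete cases - parameters
  vars <- c("ma_t2", "Glutamate_IPS_t1", "age_months_t1", "age_months_t2")
  expect_equal(ft$df_residual, sum(complete.cases(fr[vars])) - 5)
})

test_that("robust and classical SEs converge without heteroscedasticity", {
  # all interaction effects zero: omitted measure-by-age interactions would
  # otherwise leave real age-dependent variance in the residual
  fr <- analysis_frame(generate_cohort(cohort_config(
    n_per_group = 1000, hetero_slope = 0, missing_rate = 0,
    beta_int = c(Glutamate_IPS = 0), seed = 77)))
  ft <- fit_moderation(fr, model_spec("ma_t1", "Glutamate_IPS_t1", "age_months_t1"))
  ratio <- ft$coefficients$se_hc0 / ft$coefficients$se
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("product re-standardization only rescales the interaction row", {
  fr <- small_frame(seed = 31, n_per_group = 30)
  sp <- model_spec("ma_t1", "GABA_IPS_t1", "age_months_t1")
  a <- fit_moderation(fr, sp)
  b <- fit_moderation(fr, sp, standardize_product = TRUE)
  ia <- grepl("_x_", a$coefficients$term)
  expect_equal(a$coefficients$t[ia], b$coefficients$t[ia], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(a$coefficients$beta[ia], b$coefficients$beta[ia])))
})
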