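test_that("correlation families are 1 at zero, bounded, and non-increasing", {
  fams <- c("exponential", "gaussian", "rational_quadratic", "spherical", "linear")
  d <- seq(0, 6, by = 0.05)
  for (fam in fams) {
    s <- cor_structure(fam, range = 1.3)
    v <- correlation_value(s, d)
    expect_equal(v[1], 1)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_equal(correlation_value(cor_structure("rational_quadratic", 2), 2), 0.5)
  expect_equal(correlation_value(cor_structure("spherical", 1.5), 3), 0)
  expect_equal(correlation_value(cor_structure("linear", 1), c(0.25, 2)), c(0.75, 0))
  expect_equal(correlation_value(cor_structure("exponential", 2), 2), exp(-1))
  expect_equal(correlation_value(cor_structure("independence"), c(0, 1)), c(1, 0))
  expect_error(correlation_value(cor_structure("exponential", 1), -1), "negative")
})

test_that("build_covariance assembles blocks and distance decay", {
  I2 <- build_covariance(cbind(c(0, 1), c(0, 0)), cor_structure("independence"))$V
  expect_equal(I2, diag(2))
  Vb <- build_covariance(cbind(c(0, 0.05), c(0, 0)), cor_structure("independence"),
                         variance_ratio = 0.5, window_ids = c(1, 1))$V
  expect_equal(Vb, matrix(c(1.5, 0.5, 0.5, 1.5), 2, 2))
  pts <- cbind(c(0, 3, 1), c(0, 4, 1))
  Ve <- build_covariance(pts, cor_structure("exponential", 1))$V
  D <- as.matrix(dist(pts))
  expect_equal(Ve, `dimnames<-`(exp(-D), NULL), tolerance = 1e-12)
})

test_that("GLS with independence reduces exactly to OLS", {
  set.seed(21)
  d <- data.frame(x = rnorm(80), z = rnorm(80))
  d$y <- 1 + 0.4 * d$x - 0.2 * d$z + rnorm(80)
  f <- fit_gls(y ~ x + z, d)
  ols <- lm(y ~ x + z, d)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-10)
})

test_that("GLS with a fixed known covariance matches the closed form to 1e-8", {
  set.seed(22)
  n <- 60
  coords <- cbind(runif(n, 0, 5), runif(n, 0, 5))
  V <- build_covariance(coords, cor_structure("exponential", 1.5))$V
  X <- cbind(1, rnorm(n), runif(n))
  y <- drop(X %*% c(2, 0.5, -1)) + drop(t(chol(V)) %*% rnorm(n))
  d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  f <- fit_gls(y ~ x1 + x2, d, V = V)
  expect_equal(unname(f$coefficients), drop(oracle_gls_beta(y, X, V)), tolerance = 1e-8)
})

test_that("estimated exponential GLS agrees with nlme::gls", {
  skip_if_not_installed("nlme")
  set.seed(23)
  n <- 120
  d <- data.frame(x = rnorm(n), lon = runif(n, 0, 10), lat = runif(n, 0, 10))
  d$y <- 1 + 0.5 * d$x + sim_spatial_y(matrix(0, n, 1), 0, d[, c("lon", "lat")], 2, 0.8)
  f1 <- fit_gls(y ~ x, d, coords = d[, c("lon", "lat")],
                structure = cor_structure("exponential"), method = "REML")
  f2 <- nlme::gls(y ~ x, d, correlation = nlme::corExp(form = ~ lon + lat),
                  method = "REML")
  expect_equal(unname(f1$coefficients), unname(coef(f2)), tolerance = 1e-6)
  expect_equal(unname(f1$se), unname(sqrt(diag(vcov(f2)))), tolerance = 1e-5)
  expect_equal(f1$structure$range,
               unname(coef(f2$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-4)
  expect_equal(f1$logLik_reml, as.numeric(logLik(f2)), tolerance = 1e-8)
})

test_that("the optimizer's likelihood beats random admissible parameter points", {
  set.seed(24)
  n <- 100
  d <- data.frame(x = rnorm(n), lon = runif(n, 0, 8), lat = runif(n, 0, 8))
  d$y <- 2 - 0.3 * d$x + sim_spatial_y(matrix(0, n, 1), 0, d[, c("lon", "lat")], 1.5, 1)
  best <- fit_gls(y ~ x, d, coords = d[, c("lon", "lat")],
                  structure = cor_structure("rational_quadratic"), method = "ML")
  for (r in exp(runif(25, log(0.01), log(50)))) {
    cand <- tryCatch(
      fit_gls(y ~ x, d, coords = d[, c("lon", "lat")],
              structure = cor_structure("rational_quadratic", range = r),
              method = "ML"),
      error = function(e) NULL)   # inadmissible range (ill-conditioned V)
    if (!is.null(cand)) expect_gte(best$logLik_ml + 1e-6, cand$logLik_ml)
  }
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  expect_equal(aicc(-7, 0, 50), 14)
  expect_error(aicc(-10, 5, 6), "n > k \\+ 1")
})

test_that("paired model under independence equals the paired t-test", {
  pr <- generate_pairs(synthetic_params(seed = 31), 120)
  for (v in c("dLST", "dET", "dAlbedo")) {
    f <- fit_paired_model(pr, v)
    tt <- t.test(pr[[paste0(v, "_foc")]], pr[[paste0(v, "_ref")]], paired = TRUE)
    expect_equal(f$coefficients[["cell_typefocal"]], unname(tt$estimate), tolerance = 1e-8)
    expect_equal(f$t[["cell_typefocal"]], unname(tt$statistic), tolerance = 1e-6)
    expect_equal(f$p[["cell_typefocal"]], tt$p.value, tolerance = 1e-6)
  }
})

test_that("paired model recovers an exact constant offset", {
  pr <- generate_pairs(synthetic_params(seed = 32), 60)
  pr$dLST_foc <- pr$dLST_ref + 0.7
  f <- fit_paired_model(pr, "dLST")
  expect_equal(f$coefficients[["cell_typefocal"]], 0.7, tolerance = 1e-8)
  expect_lt(f$sigma2, 1e-6)
  f2 <- fit_paired_model(pr, "dLST", structure = cor_structure("exponential", 1))
  expect_equal(f2$coefficients[["cell_typefocal"]], 0.7, tolerance = 1e-6)
})

test_that("paired model recovers a known effect under spatial noise", {
  p <- synthetic_params(seed = 33, s_FL = -0.3)
  pr <- generate_pairs(p, 500)
  # inject a known additive focal effect on LST
  pr$dLST_foc <- pr$dLST_ref + 0.4
  f <- fit_paired_model(pr, "dLST")
  expect_lt(abs(f$coefficients[["cell_typefocal"]] - 0.4),
            3 * f$se[["cell_typefocal"]] + 1e-9)
  expect_error(fit_paired_model(pr[1:5, ], "dLST"), "fewer than")
})

test_that("structure selection ranks by AICc with stable ties", {
  set.seed(34)
  n <- 90
  d <- data.frame(x = rnorm(n), lon = runif(n, 0, 6), lat = runif(n, 0, 6))
  d$y <- 1 + 0.5 * d$x + sim_spatial_y(matrix(0, n, 1), 0, d[, c("lon", "lat")], 2, 1)
  sel <- select_structure(y ~ x, d, d[, c("lon", "lat")],
                          families = c("exponential", "independence"))
  expect_equal(sel$table$family[1], "exponential")
  expect_true(all(diff(sel$table$AICc) >= 0))
  # identical candidates tie exactly and keep input order
  sel2 <- select_structure(y ~ x, d, d[, c("lon", "lat")],
                           families = c("gaussian", "gaussian"))
  expect_equal(sel2$table$AICc[1], sel2$table$AICc[2])
  expect_equal(sel2$table$family, c("gaussian", "gaussian"))
  expect_error(select_structure(y ~ x, d, d[, c("lon", "lat")], families = "gaussian"),
               "at least 2")
})
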