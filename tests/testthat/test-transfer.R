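test_that("forward prediction evaluates the published equations", {
  M1 <- cd_model("M1")
  expect_equal(round(predict(M1, data.frame(cd_total_mgkg = 0.488)), 3), 0.100)
  expect_equal(predict(M1, data.frame(cd_total_mgkg = 1.0)), 10^(-0.718),
               tolerance = 1e-12)
  expect_equal(predict(M1, data.frame(cd_total_mgkg = 1.0)), 0.1914256,
               tolerance = 1e-6)

  # null model: zero coefficients, zero intercept, 10^0 = 1
  null <- transfer_model("custom",
                         data.frame(feature = "ph", transform = "identity",
                                    coefficient = 0), 0)
  expect_equal(predict(null, data.frame(ph = 7.2)), 1.0)

  expect_error(predict(cd_model("M2"), data.frame(cd_total_mgkg = 1)),
               "missing feature 'ph'")
  expect_error(predict(M1, data.frame(cd_total_mgkg = -1)), "non-positive")

  # the quadratic-BCF model predicts BCF(pH) * cd_total
  M3 <- cd_model("M3")
  expect_equal(predict(M3, data.frame(ph = 6, cd_total_mgkg = 2)),
               (0.014 * 36 - 0.236 * 6 + 1.113) * 2, tolerance = 1e-12)
})

test_that("least-squares refitting recovers generating coefficients and guards pools", {
  d0 <- generate_dataset(noiseless_m2_config(seed = 2))
  m <- suppressWarnings(fit_transfer(d0, c("cd_total_mgkg", "ph", "cec_cmolkg")))
  expect_equal(unname(coef(m)), c(0.114, 0.955, -0.118, -0.010),
               tolerance = 1e-6)

  # two points, one feature: exact interpolation
  d2 <- make_dataset(c(0.1, 0.4), cd_total = c(0.5, 2.0))
  m2 <- suppressWarnings(fit_transfer(d2, "cd_total_mgkg"))
  expect_equal(m2$fit$r2, 1.0, tolerance = 1e-12)
  expect_equal(predict(m2, d2), d2$cd_wheat_mgkg, tolerance = 1e-9)

  expect_error(fit_transfer(d0, c("cd_total_mgkg", "cd_cacl2_mgkg")),
               "mix correlated Cd pools")
  # exact collinearity is refused
  dd <- as.data.frame(d0); dd$clay_pct <- 2 * dd$ph
  expect_error(suppressWarnings(fit_transfer(dd, c("ph", "clay_pct"))),
               "collinear")
})

test_that("transform consistency: predict equals 10^linear-predictor and lm fitted values", {
  d <- generate_dataset(synth_config(n = 80, seed = 6))
  m <- fit_transfer(d, c("cd_total_mgkg", "ph"))
  expect_equal(log10(predict(m, d)), unname(fitted(m$fit$lm)),
               tolerance = 1e-12)
})

test_that("coefficient estimates converge as noise shrinks and n grows", {
  err <- vapply(c(0.4, 0.1, 0.025), function(sd) {
    d <- generate_dataset(synth_config(
      n = 311, seed = 9,
      wheat = c(coef_log10cd = 0.955, coef_ph = -0.118, coef_cec = -0.010,
                intercept = 0.114, noise_sd = sd)))
    m <- fit_transfer(d, c("cd_total_mgkg", "ph", "cec_cmolkg"))
    max(abs(coef(m) - c(0.114, 0.955, -0.118, -0.010)))
  }, 0)
  expect_true(all(diff(err) < 0))  # monotone improvement as sigma drops

  err_n <- vapply(c(100, 400, 1600), function(n) {
    d <- generate_dataset(synth_config(n = n, seed = 10))
    m <- fit_transfer(d, c("cd_total_mgkg", "ph", "cec_cmolkg"))
    max(abs(coef(m) - c(0.114, 0.955, -0.118, -0.010)))
  }, 0)
  expect_lt(err_n[3], err_n[1])
})

test_that("the BCF-pH quadratic is recovered and declines on acid-to-neutral soils", {
  ph <- seq(4, 8.5, length.out = 40)
  bcf_true <- 0.014 * ph^2 - 0.236 * ph + 1.113
  d <- make_dataset(bcf_true, cd_total = 1, ph = ph)
  m <- suppressWarnings(fit_bcf_quadratic(d))
  expect_equal(unname(coef(m)), c(0.014, -0.236, 1.113), tolerance = 1e-9)

  # constant BCF: zero curvature and slope, intercept at the mean
  dc <- make_dataset(rep(0.25, 10), ph = seq(4, 7, length.out = 10))
  mc <- suppressWarnings(fit_bcf_quadratic(dc))
  expect_equal(unname(coef(mc)), c(0, 0, 0.25), tolerance = 1e-10)

  expect_error(fit_bcf_quadratic(make_dataset(c(0.2, 0.3), ph = c(5, 6))),
               "4 distinct pH")

  # default synthetic data encode a negative pH effect on transfer
  ds <- generate_dataset(synth_config(seed = 14))
  mf <- fit_bcf_quadratic(ds)
  grid <- seq(4, 7, by = 0.1)
  expect_true(all(diff(bcf_at(mf, grid)) < 0))
})

test_that("evaluation metrics follow their closed-form definitions on the log10 scale", {
  d <- make_dataset(c(0.1, 0.2, 0.4, 0.8), cd_total = c(0.5, 1, 2, 4))
  perfect <- suppressWarnings(fit_transfer(d, "cd_total_mgkg"))
  met <- evaluate_model(perfect, d, d)
  expect_equal(met$r2_test, 1.0, tolerance = 1e-9)
  expect_equal(met$rmse_test, 0, tolerance = 1e-9)
  expect_equal(met$mae_test, 0, tolerance = 1e-9)

  # residuals exactly {+0.1, -0.1} on log10 scale
  m0 <- transfer_model("custom",
                       data.frame(feature = "cd_total_mgkg",
                                  transform = "log10", coefficient = 1), 0)
  d2 <- make_dataset(c(10^0.1, 10^-0.1), cd_total = c(1, 1 + 1e-9))
  met2 <- evaluate_model(m0, d2, d2)
  expect_equal(met2$rmse_test, 0.1, tolerance = 1e-6)
  expect_equal(met2$mae_test, 0.1, tolerance = 1e-6)

  # a constant predictor scores r2 <= 0, reported unclamped
  dm <- generate_dataset(synth_config(n = 40, seed = 15))
  const <- transfer_model("custom",
                          data.frame(feature = "ph", transform = "identity",
                                     coefficient = 0),
                          mean(log10(dm$cd_wheat_mgkg)) - 0.5)
  expect_lt(evaluate_model(const, dm, dm)$r2_test, 0)
  expect_error(evaluate_model(m0, d2, d2[0, ]), "empty test")
})

test_that("rmse dominates mae on every evaluation", {
  for (s in 1:5) {
    d <- generate_dataset(synth_config(n = 60, seed = s))
    sp <- split_dataset(d, split_spec(n_repeats = 1, seed = s))[[1]]
    met <- evaluate_model(cd_model("M2"), sp$train, sp$test)
    expect_gte(met$rmse_test, met$mae_test)
    expect_gte(met$mae_test, 0)
  }
})

test_that("correlation analysis: exact, sign and degenerate behaviour", {
  # exact linear dependence on the log scale
  ct <- 10^seq(-1, 1, length.out = 20)
  d <- make_dataset(ct^2, cd_total = ct, ph = seq(4, 8, length.out = 20))
  cr <- pearson_correlations(d)
  expect_equal(cr$r["log10_cd_total", "log10_cd_wheat"], 1, tolerance = 1e-12)
  expect_lt(cr$p["log10_cd_total", "log10_cd_wheat"], 1e-12)

  # zero-variance columns are flagged, not an error
  dz <- make_dataset(ct^2, cd_total = ct, ph = 6)
  crz <- pearson_correlations(dz)
  expect_true("ph" %in% crz$degenerate)
  expect_true(is.na(crz$r["ph", "bcf"]))

  # noiseless defaults encode the negative pH-BCF relation
  d0 <- generate_dataset(noiseless_m2_config(seed = 4))
  cr0 <- pearson_correlations(d0)
  expect_lt(cr0$r["ph", "bcf"], 0)

  # independent columns: small correlation at n = 1000
  set.seed(99)
  big <- make_dataset(rlnorm(1000), cd_total = rlnorm(1000),
                      ph = runif(1000, 4, 8))
  crn <- pearson_correlations(big)
  expect_lt(abs(crn$r["ph", "log10_cd_wheat"]), 0.1)
})

test_that("model YAML serialization round-trips, and packaged model files load", {
  for (id in c("M2", "M3", "M5star")) {
    p <- tempfile(fileext = ".yml")
    write_model_yaml(cd_model(id), p)
    m <- read_model_yaml(p)
    nd <- data.frame(cd_total_mgkg = 1.5, cd_msm_mgL = 0.01, ph = 6,
                     cec_cmolkg = 12)
    expect_equal(predict(m, nd), predict(cd_model(id), nd), tolerance = 1e-12)
  }
  shipped <- system.file("models", "M4.yml", package = "cdwheat")
  expect_true(nzchar(shipped))
  expect_equal(coef(read_model_yaml(shipped))[["cd_cacl2_mgkg"]], 0.509)
})
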