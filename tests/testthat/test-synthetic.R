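test_that("generation is deterministic under a fixed seed and varies across seeds", {
  d1 <- generate_dataset(synth_config(n = 50, seed = 1))
  d2 <- generate_dataset(synth_config(n = 50, seed = 1))
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_dataset(synth_config(n = 50, seed = 2))
  expect_false(isTRUE(all.equal(d1$cd_wheat_mgkg, d3$cd_wheat_mgkg)))
})

test_that("soil properties respect their truncated marginals", {
  cfg <- synth_config(n = 1000, seed = 4)
  d <- generate_dataset(cfg)
  expect_true(all(d$ph >= 3.97 & d$ph <= 8.55))
  expect_true(all(d$cec_cmolkg >= 3.25 & d$cec_cmolkg <= 29.90))
  expect_true(all(d$clay_pct >= 1.46 & d$clay_pct <= 56.70))
  expect_true(all(d$som_gkg >= 0.605 & d$som_gkg <= 63.510))
  expect_true(all(d$fe_dcb_gkg >= 4.30 & d$fe_dcb_gkg <= 24.20))
  expect_true(all(d$fe_ox_gkg >= 0.31 & d$fe_ox_gkg <= 10.37))
  expect_true(all(d$cd_total_mgkg >= 0.068 & d$cd_total_mgkg <= 13.5))

  # degenerate law: sd 0 pins the property at its mean
  d0 <- generate_dataset(synth_config(n = 20, seed = 1,
                                      ph = c(mean = 5.65, sd = 0,
                                             min = 3.97, max = 8.55)))
  expect_true(all(d0$ph == 5.65))
  expect_error(synth_config(ph = c(mean = 5, sd = 1, min = 6, max = 4)),
               "infeasible truncation")
})

test_that("sample mean pH matches the truncated-normal mean at large n", {
  cfg <- synth_config(n = 5000, seed = 8)
  d <- generate_dataset(cfg)
  # analytic mean of the truncated normal (independent oracle)
  m <- 5.65; s <- 0.9; a <- (3.97 - m) / s; b <- (8.55 - m) / s
  mu_trunc <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(d$ph) - mu_trunc), 0.05)
  expect_lt(abs(mean(d$ph) - 5.65), 0.1)
})

test_that("bioavailable pools follow the partition law with the (+, -, -) sign structure", {
  cfg <- synth_config(seed = 1,
                      cacl2 = c(intercept = 0.70, coef_log10cd = 0.95,
                                coef_ph = -0.25, coef_cec = -0.02,
                                noise_sd = 0))
  soil <- data.frame(ph = c(5, 7), cec_cmolkg = 10, cd_total_mgkg = 1,
                     clay_pct = 20, som_gkg = 20, fe_dcb_gkg = 10,
                     fe_ox_gkg = 5)
  out <- derive_bioavailable(cfg, soil)
  expect_gt(out$cd_cacl2_mgkg[1], out$cd_cacl2_mgkg[2])  # lower pH, more Cd

  # all-zero coefficients with intercept log10(0.01) pin both pools at 0.01
  cfg0 <- synth_config(seed = 1,
                       cacl2 = c(intercept = log10(0.01), coef_log10cd = 0,
                                 coef_ph = 0, coef_cec = 0, noise_sd = 0),
                       msm = c(intercept = log10(0.01), coef_log10cd = 0,
                               coef_ph = 0, coef_cec = 0, noise_sd = 0))
  out0 <- derive_bioavailable(cfg0, soil)
  expect_equal(out0$cd_cacl2_mgkg, rep(0.01, 2))
  expect_equal(out0$cd_msm_mgL, rep(0.01, 2))

  # extractable pool sits below the total on the geometric-mean scale
  d <- generate_dataset(synth_config(n = 311, seed = 13))
  expect_lt(exp(mean(log(d$cd_cacl2_mgkg))), exp(mean(log(d$cd_total_mgkg))))
  expect_true(all(d$cd_cacl2_mgkg <= d$cd_total_mgkg))
})

test_that("noiseless grain response reproduces the configured transfer equation", {
  cfg <- noiseless_m2_config()
  soil <- data.frame(ph = 5.65, cec_cmolkg = 14, cd_total_mgkg = 1)
  out <- simulate_wheat(cfg, soil)
  expect_equal(out$cd_wheat_mgkg, 10^(0.114 - 0.118 * 5.65 - 0.010 * 14),
               tolerance = 1e-12)

  # refitting on noiseless output recovers the generating coefficients
  d0 <- generate_dataset(noiseless_m2_config(seed = 3))
  m <- suppressWarnings(fit_transfer(d0, c("cd_total_mgkg", "ph", "cec_cmolkg")))
  expect_equal(unname(coef(m)), c(0.114, 0.955, -0.118, -0.010),
               tolerance = 1e-6)
})

test_that("default noise level yields a refitted model R2 in the calibrated band", {
  r2 <- vapply(1:5, function(s) {
    d <- generate_dataset(synth_config(seed = s))
    fit_transfer(d, c("cd_total_mgkg", "ph", "cec_cmolkg"))$fit$r2
  }, 0)
  expect_true(all(r2 > 0.6 & r2 < 0.85))
})

test_that("noiseless partial effects match the path-sign structure", {
  d0 <- generate_dataset(noiseless_m2_config(
    seed = 5,
    cacl2 = c(intercept = 0.70, coef_log10cd = 0.95, coef_ph = -0.25,
              coef_cec = -0.02, noise_sd = 0)))
  mw <- suppressWarnings(fit_transfer(d0, c("cd_total_mgkg", "ph", "cec_cmolkg")))
  cw <- coef(mw)
  expect_gt(cw[["cd_total_mgkg"]], 0)
  expect_lt(cw[["ph"]], 0)
  expect_lt(cw[["cec_cmolkg"]], 0)
  cb <- coef(lm(log10(cd_cacl2_mgkg) ~ log10(cd_total_mgkg) + ph + cec_cmolkg,
                data = d0))
  expect_gt(cb[[2]], 0); expect_lt(cb[[3]], 0); expect_lt(cb[[4]], 0)
})

test_that("planted outliers are flagged in meta and removed by cleaning", {
  d <- generate_dataset(synth_config(n = 100, seed = 21, n_outliers = 3))
  planted <- attr(d, "meta")$planted_outliers
  expect_length(planted, 3)
  expect_equal(nrow(d), 103)
  cl <- clean_dataset(d)
  expect_setequal(attr(cl, "cleaning")$.id, planted)
  expect_equal(nrow(cl), 100)
})

test_that("generated records pass validation with clipping in under 1% of draws", {
  clipped <- vapply(1:5, function(s) {
    d <- generate_dataset(synth_config(n = 311, seed = s))
    attr(d, "meta")$n_clipped / 311
  }, 0)
  expect_true(all(clipped < 0.01))
})
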