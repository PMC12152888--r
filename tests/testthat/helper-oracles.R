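# Shared test helpers: independent oracles and small dataset builders.

# Bisection inversion oracle: finds the soil Cd value in [1e-4, 100] (model
# units) at which predicted grain Cd equals `limit`, using only predict().
# Independent of the closed-form inversion it is used to check.
oracle_invert <- function(model, limit = 0.1, ph = NULL, cec = NULL,
                          lower = 1e-4, upper = 100, iter = 60) {
  cd_col <- if (inherits(model, "bcf_model")) "cd_total_mgkg"
    else intersect(model$terms$feature,
                   c("cd_total_mgkg", "cd_cacl2_mgkg", "cd_msm_mgL"))
  pred_at <- function(x) {
    nd <- data.frame(x)
    names(nd) <- cd_col
    if (!is.null(ph)) nd$ph <- ph
    if (!is.null(cec)) nd$cec_cmolkg <- cec
    predict(model, nd)
  }
  lo <- lower; hi <- upper
  stopifnot(pred_at(lo) < limit, pred_at(hi) > limit)
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)  # bisect on the log scale
    if (pred_at(mid) < limit) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Minimal valid paired dataset from vectors (defaults fill required fields).
make_dataset <- function(cd_wheat, cd_total = 1, ph = 6, cec = 10, ...) {
  n <- max(lengths(list(cd_wheat, cd_total, ph, cec)))
  as_cd_dataset(data.frame(ph = rep_len(ph, n),
                           cec_cmolkg = rep_len(cec, n),
                           cd_total_mgkg = rep_len(cd_total, n),
                           cd_wheat_mgkg = rep_len(cd_wheat, n), ...))
}

# Noiseless generator config with the published total-Cd transfer response.
noiseless_m2_config <- function(seed = 1, n = 311, ...) {
  synth_config(n = n, seed = seed,
               wheat = c(coef_log10cd = 0.955, coef_ph = -0.118,
                         coef_cec = -0.010, intercept = 0.114, noise_sd = 0),
               ...)
}
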