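# Log-linear soil-to-wheat Cd transfer models: declarative model objects with
# the published coefficient sets, least-squares refitting, the BCF-pH
# quadratic, evaluation metrics, and correlation analysis.

.cd_pool_cols <- c("cd_total_mgkg", "cd_cacl2_mgkg", "cd_msm_mgL")
.log10_default_cols <- c(.cd_pool_cols, "cd_wheat_mgkg")

#' Declarative log-linear transfer model
#'
#' A transfer model predicts wheat-grain Cd from soil variables through a
#' linear predictor on (optionally log10-transformed) features, with the
#' response on the log10 scale by default:
#' `log10(cd_wheat) = intercept + sum(coef_i * transform_i(feature_i))`.
#'
#' @param id model label, e.g. `"M1"` or `"custom"`.
#' @param terms data.frame with columns `feature` (a numeric column name of
#'   [cd_schema()]), `transform` (`"log10"` or `"identity"`) and
#'   `coefficient`.
#' @param intercept the constant term.
#' @param response_transform `"log10"` (default) or `"identity"`.
#' @param units units of the Cd pool the model predicts from, `"mg/kg"` or
#'   `"mg/L"`.
#' @param fit optional list of fit diagnostics (attached by [fit_transfer()]).
#' @return An object of class `transfer_model`.
#' @seealso [cd_model()] for the published model suite, [fit_transfer()] to
#'   estimate one from data, [predict.transfer_model()], [invert_threshold()].
#' @export
transfer_model <- function(id, terms, intercept,
                           response_transform = c("log10", "identity"),
                           units = "mg/kg", fit = NULL) {
  response_transform <- match.arg(response_transform)
  terms <- as.data.frame(terms)
  stopifnot(all(c("feature", "transform", "coefficient") %in% names(terms)))
  if (!all(terms$feature %in% setdiff(cd_schema(), "source")))
    stop("unknown feature(s): ",
         paste(setdiff(terms$feature, cd_schema()), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(terms$feature)) stop("repeated feature", call. = FALSE)
  if (!all(terms$transform %in% c("log10", "identity")))
    stop("transform must be 'log10' or 'identity'", call. = FALSE)
  if (!all(is.finite(terms$coefficient)) || !is.finite(intercept))
    stop("coefficients must be finite", call. = FALSE)
  structure(list(id = id, terms = terms, intercept = intercept,
                 response_transform = response_transform, units = units,
                 fit = fit),
            class = "transfer_model")
}

.tm <- function(id, features, coefs, intercept, units = "mg/kg") {
  transfer_model(id,
                 data.frame(feature = features,
                            transform = ifelse(features %in% .log10_default_cols,
                                               "log10", "identity"),
                            coefficient = coefs),
                 intercept, units = units)
}

#' The published transfer-model suite
#'
#' Returns the fixed-coefficient models of the soil-wheat Cd transfer suite
#' (base-10 logs, Cd pools in mg/kg except the dissolved pool in mg/L):
#' \describe{
#'   \item{M1}{log10 Cd_wheat = 0.906 log10 Cd_soil - 0.718}
#'   \item{M2}{log10 Cd_wheat = 0.955 log10 Cd_soil - 0.118 pH - 0.010 CEC + 0.114}
#'   \item{M3}{Cd_wheat = BCF(pH) x Cd_soil with
#'     BCF = 0.014 pH^2 - 0.236 pH + 1.113 (a [bcf_model])}
#'   \item{M4}{log10 Cd_wheat = 0.509 log10 Cd_CaCl2 + 0.104 pH - 0.768}
#'   \item{M5}{log10 Cd_wheat = 0.572 log10 Cd_MSM + 0.106 pH - 0.257}
#'   \item{M5star}{log10 Cd_wheat = 0.690 log10 Cd_MSM + 0.020 pH + 0.385
#'     (complete-property subset refit)}
#' }
#'
#' @param id one of `"M1"`, `"M2"`, `"M3"`, `"M4"`, `"M5"`, `"M5star"`; if
#'   missing, the whole named list is returned.
#' @return A `transfer_model` (or `bcf_model` for M3), or a named list of all
#'   six.
#' @export
cd_model <- function(id) {
  suite <- list(
    M1 = .tm("M1", "cd_total_mgkg", 0.906, -0.718),
    M2 = .tm("M2", c("cd_total_mgkg", "ph", "cec_cmolkg"),
             c(0.955, -0.118, -0.010), 0.114),
    M3 = bcf_model(0.014, -0.236, 1.113, id = "M3"),
    M4 = .tm("M4", c("cd_cacl2_mgkg", "ph"), c(0.509, 0.104), -0.768),
    M5 = .tm("M5", c("cd_msm_mgL", "ph"), c(0.572, 0.106), -0.257,
             units = "mg/L"),
    M5star = .tm("M5star", c("cd_msm_mgL", "ph"), c(0.690, 0.020), 0.385,
                 units = "mg/L"))
  if (missing(id)) return(suite)
  if (!id %in% names(suite)) stop("unknown model id '", id, "'", call. = FALSE)
  suite[[id]]
}

#' Quadratic BCF-pH model
#'
#' Describes the bioconcentration factor as a quadratic in soil pH,
#' `BCF(pH) = a pH^2 + b pH + c`; grain Cd is then `BCF(pH) x Cd_soil`.
#' The published coefficients are (0.014, -0.236, 1.113), a curve that
#' declines up to about pH 7 and flattens in alkaline soils.
#'
#' @param a,b,c quadratic coefficients.
#' @param id label (default "M3").
#' @param domain pH interval of declared validity.
#' @param fit optional fit diagnostics.
#' @return An object of class `bcf_model`.
#' @export
bcf_model <- function(a, b, c, id = "M3", domain = c(3.97, 8.55), fit = NULL) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  m <- structure(list(id = id, a = a, b = b, c = c, domain = domain,
                      units = "mg/kg", fit = fit),
                 class = "bcf_model")
  grid <- seq(domain[1], domain[2], length.out = 200)
  if (any(bcf_at(m, grid) <= 0))
    warning("BCF(pH) is not positive over the whole declared domain")
  m
}

#' Evaluate a quadratic BCF curve at given pH values
#' @param model a [bcf_model()].
#' @param ph numeric vector of pH values.
#' @return BCF values (unitless).
#' @export
bcf_at <- function(model, ph) {
  stopifnot(inherits(model, "bcf_model"))
  model$a * ph^2 + model$b * ph + model$c
}

# Pull and transform the feature columns a model needs; errors name the
# missing feature or the offending non-positive value.
.model_matrix <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  vapply(seq_len(nrow(model$terms)), function(i) {
    f <- model$terms$feature[i]
    if (is.null(newdata[[f]]) || anyNA(newdata[[f]]))
      stop("missing feature '", f, "'", call. = FALSE)
    x <- newdata[[f]]
    if (model$terms$transform[i] == "log10") {
      if (any(x <= 0))
        stop("non-positive value for log10 feature '", f, "'", call. = FALSE)
      x <- log10(x)
    }
    x
  }, numeric(nrow(newdata)))
}

#' Predict wheat-grain Cd from a transfer model
#'
#' Evaluates the linear predictor on the transformed features and inverts the
#' response transform (`10^lp` for log10-response models).
#'
#' @param object a `transfer_model`.
#' @param newdata data.frame supplying every feature the model references
#'   (see [cd_schema()]).
#' @param ... unused.
#' @return Predicted grain Cd, mg/kg.
#' @examples
#' predict(cd_model("M1"), data.frame(cd_total_mgkg = 0.488))
#' @export
predict.transfer_model <- function(object, newdata, ...) {
  X <- .model_matrix(object, newdata)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  lp <- drop(X %*% object$terms$coefficient) + object$intercept
  if (object$response_transform == "log10") 10^lp else lp
}

#' Predict wheat-grain Cd (or BCF) from a quadratic BCF model
#'
#' With a `cd_total_mgkg` column in `newdata`, returns
#' `BCF(pH) x cd_total` (grain Cd, mg/kg); with only `ph`, returns the BCF
#' values themselves.
#'
#' @param object a `bcf_model`.
#' @param newdata data.frame with `ph` (and usually `cd_total_mgkg`).
#' @param ... unused.
#' @return Grain Cd (mg/kg) or BCF (unitless).
#' @export
predict.bcf_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (is.null(newdata$ph) || anyNA(newdata$ph))
    stop("missing feature 'ph'", call. = FALSE)
  b <- bcf_at(object, newdata$ph)
  if (is.null(newdata$cd_total_mgkg)) return(b)
  if (any(newdata$cd_total_mgkg <= 0))
    stop("non-positive value for feature 'cd_total_mgkg'", call. = FALSE)
  b * newdata$cd_total_mgkg
}

#' @export
print.transfer_model <- function(x, ...) {
  lhs <- if (x$response_transform == "log10") "log10(Cd_wheat)" else "Cd_wheat"
  rhs <- paste(sprintf("%+.4g*%s", x$terms$coefficient,
                       ifelse(x$terms$transform == "log10",
                              paste0("log10(", x$terms$feature, ")"),
                              x$terms$feature)),
               collapse = " ")
  cat("Transfer model ", x$id, " [", x$units, "]\n  ", lhs, " = ", rhs,
      sprintf(" %+.4g", x$intercept), "\n", sep = "")
  if (!is.null(x$fit))
    cat(sprintf("  fitted on n = %d, R2 = %.3f\n", x$fit$n, x$fit$r2))
  invisible(x)
}

#' @export
print.bcf_model <- function(x, ...) {
  cat("BCF-pH quadratic ", x$id, ": BCF = ",
      sprintf("%.4g*pH^2 %+.4g*pH %+.4g", x$a, x$b, x$c),
      "\n  Cd_wheat = BCF(pH) * cd_total; pH domain [",
      x$domain[1], ", ", x$domain[2], "]\n", sep = "")
  if (!is.null(x$fit))
    cat(sprintf("  fitted on n = %d, R2 = %.3f\n", x$fit$n, x$fit$r2))
  invisible(x)
}

#' @export
coef.transfer_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$terms$coefficient),
                  c("(Intercept)", object$terms$feature))
}

#' @export
coef.bcf_model <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
summary.transfer_model <- function(object, ...) {
  out <- list(model = object, coef_table = NULL)
  if (!is.null(object$fit) && !is.null(object$fit$se)) {
    est <- coef(object)
    se <- object$fit$se
    tval <- est / se
    out$coef_table <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
                            `Pr(>|t|)` = 2 * stats::pt(-abs(tval),
                                                       object$fit$df_residual))
    out$r2 <- object$fit$r2
    out$n <- object$fit$n
  }
  class(out) <- "summary.transfer_model"
  out
}

#' @export
print.summary.transfer_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$coef_table)) {
    stats::printCoefmat(x$coef_table)
    cat(sprintf("R2 = %.4f on n = %d records\n", x$r2, x$n))
  }
  invisible(x)
}

# Refuse specs that mix the highly correlated Cd pools in one model.
.check_pool_guard <- function(features) {
  pools <- intersect(features, .cd_pool_cols)
  if (length(pools) > 1)
    stop("features mix correlated Cd pools (", paste(pools, collapse = ", "),
         "); use a single soil Cd variable per model", call. = FALSE)
}

#' Fit a log-linear transfer model by ordinary least squares
#'
#' Regresses `log10(cd_wheat)` on the requested features, log10-transforming
#' the Cd pool variables (and any feature listed in `log10_features`) and
#' leaving the others untransformed. Refuses feature sets mixing more than one
#' of the highly correlated soil Cd pools (total, CaCl2-extractable,
#' model-dissolved), which invites collinear overfitting.
#'
#' @param data a `cd_dataset` (or data.frame with the needed columns).
#' @param features character vector of predictor column names.
#' @param log10_features features to log10-transform; defaults to the Cd pool
#'   columns among `features`.
#' @param id label for the fitted model.
#' @return A `transfer_model` carrying coefficient standard errors, R^2,
#'   residual sigma and the underlying `lm` fit in `$fit`.
#' @export
fit_transfer <- function(data, features,
                         log10_features = intersect(features, .log10_default_cols),
                         id = "custom") {
  data <- as.data.frame(data)
  .check_pool_guard(features)
  if (is.null(data$cd_wheat_mgkg)) stop("missing column cd_wheat_mgkg",
                                        call. = FALSE)
  cols <- c(features, "cd_wheat_mgkg")
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing feature '", miss[1], "'", call. = FALSE)
  use <- stats::complete.cases(data[cols])
  d <- data[use, cols, drop = FALSE]
  if (nrow(d) < length(features) + 1)
    stop("too few records to identify the coefficients", call. = FALSE)
  X <- d[features]
  for (f in intersect(log10_features, features)) {
    if (any(X[[f]] <= 0))
      stop("non-positive value for log10 feature '", f, "'", call. = FALSE)
    X[[f]] <- log10(X[[f]])
  }
  y <- log10(d$cd_wheat_mgkg)
  df_fit <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = df_fit)
  if (fit$rank < length(features) + 1) stop("collinear features", call. = FALSE)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  transfer_model(id,
                 data.frame(feature = features,
                            transform = ifelse(features %in% log10_features,
                                               "log10", "identity"),
                            coefficient = unname(cf[features])),
                 intercept = unname(cf["(Intercept)"]),
                 fit = list(lm = fit, n = nrow(d), r2 = sm$r.squared,
                            sigma = sm$sigma,
                            se = stats::setNames(sm$coefficients[c("(Intercept)",
                                                                   features),
                                                                 "Std. Error"],
                                                 c("(Intercept)", features)),
                            df_residual = fit$df.residual))
}

#' Fit the quadratic BCF-pH relation by least squares
#'
#' @param data a `cd_dataset` with `bcf` and `ph` columns (or any data.frame
#'   with them).
#' @return A [bcf_model()] with R^2 in `$fit`.
#' @export
fit_bcf_quadratic <- function(data) {
  data <- as.data.frame(data)
  use <- stats::complete.cases(data[c("ph", "bcf")])
  d <- data[use, , drop = FALSE]
  if (length(unique(d$ph)) < 4)
    stop("need at least 4 distinct pH values", call. = FALSE)
  fit <- stats::lm(bcf ~ I(ph^2) + ph, data = d)
  cf <- stats::coef(fit)
  bcf_model(unname(cf["I(ph^2)"]), unname(cf["ph"]), unname(cf["(Intercept)"]),
            id = "bcf_fit", domain = range(d$ph),
            fit = list(n = nrow(d), r2 = summary(fit)$r.squared, lm = fit))
}

#' Evaluate a transfer model on train and test sets
#'
#' All metrics are computed on the log10(mg/kg) scale: R^2 is the ordinary
#' coefficient of determination `1 - SSE/SST` per set (reported as-is, which
#' may be negative for a bad model); RMSE and MAE are the root-mean-square and
#' mean absolute log10-residuals on the test set.
#'
#' @param model a `transfer_model` or `bcf_model`.
#' @param train,test datasets with the model's features and `cd_wheat_mgkg`.
#' @return List of class `fit_metrics`: `r2_train`, `r2_test`, `rmse_test`,
#'   `mae_test`.
#' @export
evaluate_model <- function(model, train, test) {
  if (NROW(test) == 0L) stop("empty test set", call. = FALSE)
  if (NROW(train) == 0L) stop("empty train set", call. = FALSE)
  log_resid <- function(d) {
    pred <- predict(model, d)
    log10(d$cd_wheat_mgkg) - log10(pred)
  }
  r2 <- function(d) {
    y <- log10(d$cd_wheat_mgkg)
    1 - sum(log_resid(d)^2) / sum((y - mean(y))^2)
  }
  res <- log_resid(test)
  structure(list(r2_train = r2(train), r2_test = r2(test),
                 rmse_test = sqrt(mean(res^2)), mae_test = mean(abs(res))),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("R2 train %.3f | R2 test %.3f | RMSE test %.3f | MAE test %.3f (log10 scale)\n",
              x$r2_train, x$r2_test, x$rmse_test, x$mae_test))
  invisible(x)
}

#' Pairwise Pearson correlations of the analysis variables
#'
#' Correlates the standard variable set: log10-transformed Cd pools and grain
#' Cd, the BCF, and the untransformed soil properties. Two-tailed p-values
#' use the t approximation `t = r * sqrt((n-2)/(1-r^2))`; no multiplicity
#' correction is applied. Zero-variance variables get `NA` correlations and
#' are listed in `$degenerate`.
#'
#' @param data a `cd_dataset` (>= 3 records).
#' @return List of class `cd_correlations` with symmetric matrices `r`, `p`,
#'   `n` (pairwise complete counts) and a `degenerate` character vector.
#' @export
pearson_correlations <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) < 3) stop("need at least 3 records", call. = FALSE)
  vars <- list(log10_cd_total = log10(data$cd_total_mgkg),
               log10_cd_cacl2 = log10(data$cd_cacl2_mgkg),
               log10_cd_msm = log10(data$cd_msm_mgL),
               log10_cd_wheat = log10(data$cd_wheat_mgkg),
               bcf = data$bcf, ph = data$ph, cec = data$cec_cmolkg,
               clay = data$clay_pct, som = data$som_gkg,
               fe_dcb = data$fe_dcb_gkg, fe_ox = data$fe_ox_gkg)
  vars <- vars[!vapply(vars, function(v) is.null(v) || all(is.na(v)), TRUE)]
  M <- do.call(cbind, vars)
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  degenerate <- colnames(M)[!is.na(sds) & sds == 0]
  r <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  r[degenerate, ] <- NA; r[, degenerate] <- NA
  n <- crossprod(!is.na(M))
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), pmax(n - 2, 1))
  diag(p) <- 0
  structure(list(r = r, p = p, n = n, degenerate = degenerate),
            class = "cd_correlations")
}

#' @export
print.cd_correlations <- function(x, digits = 3, ...) {
  cat("Pearson correlations (lower triangle r, upper triangle two-tailed p):\n")
  out <- x$r
  out[upper.tri(out)] <- x$p[upper.tri(x$p)]
  print(round(out, digits))
  if (length(x$degenerate))
    cat("zero-variance variables:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a transfer model to a YAML file
#' @param model a `transfer_model` or `bcf_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  if (inherits(model, "bcf_model")) {
    obj <- list(kind = "bcf_model", id = model$id, a = model$a, b = model$b,
                c = model$c, domain = model$domain)
  } else {
    stopifnot(inherits(model, "transfer_model"))
    obj <- list(kind = "transfer_model", id = model$id,
                response_transform = model$response_transform,
                units = model$units, intercept = model$intercept,
                terms = lapply(seq_len(nrow(model$terms)), function(i)
                  as.list(model$terms[i, ])))
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a transfer model from a YAML file
#' @param path YAML file written by [write_model_yaml()].
#' @return A `transfer_model` or `bcf_model`.
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (identical(obj$kind, "bcf_model"))
    return(bcf_model(obj$a, obj$b, obj$c, id = obj$id,
                     domain = unlist(obj$domain)))
  terms <- do.call(rbind, lapply(obj$terms, as.data.frame))
  transfer_model(obj$id, terms, obj$intercept,
                 response_transform = obj$response_transform,
                 units = obj$units)
}
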