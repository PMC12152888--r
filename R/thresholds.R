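# Soil Cd thresholds for safe wheat production: closed-form inversion of a
# transfer model at the grain food-safety limit, stepwise pH-band standards,
# and protection-accuracy (confusion-matrix) scoring.

#' Back-calculate the soil Cd threshold at a grain limit
#'
#' Solves a transfer model for the soil Cd variable at which predicted grain
#' Cd equals `grain_limit`. For a log-linear model with Cd coefficient `b`,
#' the closed form is `10^((log10(L) - intercept - other_terms) / b)`; for the
#' quadratic BCF model it is `L / BCF(pH)`. The result satisfies
#' `predict(model, threshold, covariates) == grain_limit` to machine
#' precision. Vectorised over `ph`.
#'
#' @param model a `transfer_model` or `bcf_model`.
#' @param grain_limit grain Cd limit, mg/kg (default 0.1, the wheat
#'   food-safety limit).
#' @param ph soil pH; required when the model references pH.
#' @param cec cation exchange capacity, cmol/kg; required when the model
#'   references CEC.
#' @return Threshold in the model's Cd units (mg/kg, or mg/L for the
#'   dissolved-Cd models).
#' @examples
#' invert_threshold(cd_model("M1"), 0.1)                    # 0.488 mg/kg
#' invert_threshold(cd_model("M4"), 0.1, ph = 6.5)          # 0.016 mg/kg
#' @export
invert_threshold <- function(model, grain_limit = 0.1, ph = NULL, cec = NULL) {
  stopifnot(grain_limit > 0)
  if (inherits(model, "bcf_model")) {
    if (is.null(ph)) stop("missing feature 'ph'", call. = FALSE)
    b <- bcf_at(model, ph)
    if (any(b <= 0)) stop("BCF(pH) is not positive at the requested pH",
                          call. = FALSE)
    return(grain_limit / b)
  }
  stopifnot(inherits(model, "transfer_model"))
  if (model$response_transform != "log10")
    stop("only log10-response models can be inverted in closed form",
         call. = FALSE)
  cd_i <- which(model$terms$feature %in% .cd_pool_cols)
  if (length(cd_i) != 1L || model$terms$transform[cd_i] != "log10" ||
      model$terms$coefficient[cd_i] == 0)
    stop("model has no invertible soil Cd term", call. = FALSE)
  other <- 0
  n_ph <- if (is.null(ph)) 1L else length(ph)
  for (i in setdiff(seq_len(nrow(model$terms)), cd_i)) {
    f <- model$terms$feature[i]
    val <- switch(f, ph = ph, cec_cmolkg = cec,
                  stop("no covariate value supplied for '", f, "'",
                       call. = FALSE))
    if (is.null(val)) stop("missing covariate '", if (f == "ph") "ph" else "cec",
                           "' required by model ", model$id, call. = FALSE)
    if (model$terms$transform[i] == "log10") val <- log10(val)
    other <- other + model$terms$coefficient[i] * val
  }
  lp <- (log10(grain_limit) - model$intercept - other) /
    model$terms$coefficient[cd_i]
  rep_len(10^lp, max(n_ph, length(lp)))
}

#' Threshold curve: a transfer model inverted at a grain limit
#'
#' Packages a model, a grain limit and the covariate defaults into a curve
#' mapping soil pH to the soil Cd threshold for safe production.
#'
#' @param model a `transfer_model` or `bcf_model`.
#' @param grain_limit grain Cd limit, mg/kg (default 0.1).
#' @param cec CEC value used when the model requires it (conventionally the
#'   mean CEC of the dataset in use). Leave `NULL` to defer: the curve then
#'   needs a `cec` at evaluation time, and [classify_exceedance()] will use
#'   each record's own CEC.
#' @param domain pH interval of declared validity.
#' @return An object of class `threshold_curve`; evaluate it with
#'   `predict(curve, ph)`.
#' @export
threshold_curve <- function(model, grain_limit = 0.1, cec = NULL,
                            domain = c(3.97, 8.55)) {
  stopifnot(grain_limit > 0)
  needs_cec <- inherits(model, "transfer_model") &&
    "cec_cmolkg" %in% model$terms$feature
  structure(list(model = model, grain_limit = grain_limit, cec = cec,
                 needs_cec = needs_cec, domain = domain, units = model$units),
            class = "threshold_curve")
}

#' @export
predict.threshold_curve <- function(object, ph, cec = object$cec, ...) {
  if (isTRUE(object$needs_cec) && is.null(cec))
    stop("model ", object$model$id, " requires a 'cec' covariate",
         call. = FALSE)
  invert_threshold(object$model, object$grain_limit, ph = ph, cec = cec)
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("Threshold curve from model ", x$model$id, " at grain limit ",
      x$grain_limit, " mg/kg [", x$units, "], pH domain [", x$domain[1], ", ",
      x$domain[2], "]\n", sep = "")
  if (!is.null(x$cec)) cat("  CEC fixed at", x$cec, "cmol/kg\n")
  invisible(x)
}

.band_labels <- c("pH<=5.5", "5.5<pH<=6.5", "6.5<pH<=7.5", "pH>7.5")

#' Stepwise pH-band soil quality standard
#'
#' Encodes a standard that assigns a soil total Cd limit per pH band, with
#' the half-open bands pH<=5.5, 5.5<pH<=6.5, 6.5<pH<=7.5, pH>7.5 (boundary
#' values belong to the lower band). Built-in standards:
#' `"GB 15618-2018"` (0.30, 0.30, 0.30, 0.60 mg/kg) and
#' `"GB/T 41685-2022"` (0.20, 0.23, 0.30, 0.36 mg/kg).
#'
#' @param name standard name; one of the built-ins above, or `"custom"` with
#'   explicit `values`.
#' @param values four positive band values, mg/kg (ignored for built-ins).
#' @param edges three strictly increasing pH band edges (default 5.5, 6.5,
#'   7.5).
#' @return An object of class `step_standard`.
#' @export
step_standard <- function(name = c("GB 15618-2018", "GB/T 41685-2022", "custom"),
                          values = NULL, edges = c(5.5, 6.5, 7.5)) {
  name <- match.arg(name)
  if (name == "GB 15618-2018") values <- c(0.30, 0.30, 0.30, 0.60)
  if (name == "GB/T 41685-2022") values <- c(0.20, 0.23, 0.30, 0.36)
  if (is.null(values) || length(values) != 4 || any(values <= 0))
    stop("need four positive band values", call. = FALSE)
  if (length(edges) != 3 || any(diff(edges) <= 0))
    stop("band edges must be three strictly increasing pH values",
         call. = FALSE)
  structure(list(name = name, values = values, edges = edges,
                 units = "mg/kg"),
            class = "step_standard")
}

#' Soil Cd limit of a stepwise standard at given pH
#'
#' @param std a [step_standard()].
#' @param ph soil pH values in (0, 14).
#' @return Band limit values, mg/kg.
#' @examples
#' standard_threshold(step_standard("GB 15618-2018"), 8.0)  # 0.60
#' @export
standard_threshold <- function(std, ph) {
  stopifnot(inherits(std, "step_standard"), all(ph > 0), all(ph < 14))
  # left.open=TRUE keeps ph == edge in the lower band, per the band notation
  band <- findInterval(ph, std$edges, left.open = TRUE) + 1L
  std$values[band]
}

#' @export
predict.step_standard <- function(object, ph, ...) standard_threshold(object, ph)

#' @export
print.step_standard <- function(x, ...) {
  cat("Stepwise soil Cd standard ", x$name, " (mg/kg):\n", sep = "")
  print(stats::setNames(x$values, .band_labels))
  invisible(x)
}

#' Representative per-band threshold table
#'
#' Evaluates a threshold curve at one representative pH per band of the
#' stepwise standards, for side-by-side comparison with them. The default
#' convention takes each band's lower boundary (5.5, 6.5, 7.5) and pH 4.0 for
#' the open acid band; the convention is explicit in the output and can be
#' overridden.
#'
#' @param curve a [threshold_curve()].
#' @param rep_ph four representative pH values, one per band.
#' @return data.frame with columns `band`, `rep_ph`, `threshold` (full
#'   precision) and `threshold_3dp`; the convention and units are attached as
#'   attributes.
#' @export
threshold_table <- function(curve, rep_ph = c(4.0, 5.5, 6.5, 7.5)) {
  stopifnot(inherits(curve, "threshold_curve"), length(rep_ph) == 4)
  outside <- rep_ph < curve$domain[1] | rep_ph > curve$domain[2]
  if (any(outside))
    warning("representative pH outside the curve domain: ",
            paste(rep_ph[outside], collapse = ", "))
  th <- predict(curve, rep_ph)
  out <- data.frame(band = .band_labels, rep_ph = rep_ph, threshold = th,
                    threshold_3dp = round(th, 3))
  attr(out, "convention") <- "band lower boundary; open acid band at pH 4.0"
  attr(out, "units") <- curve$units
  out
}

#' Protection accuracy of a threshold rule against the grain limit
#'
#' Classifies every record by whether its tested soil Cd pool exceeds the
#' rule's threshold at the record's pH (predicted exceedance) and whether its
#' grain Cd exceeds the grain limit (actual exceedance):
#' TP = both exceed, FN = grain exceeds but soil does not, FP = soil exceeds
#' but grain does not, TN = neither. Accuracy is
#' `(TP + TN) / (TP + FN + FP + TN) * 100`.
#'
#' @param data a `cd_dataset`.
#' @param rule a [threshold_curve()] or [step_standard()].
#' @param grain_limit grain Cd limit, mg/kg (default 0.1).
#' @param cd_pool which soil Cd column the rule tests (default
#'   `"cd_total_mgkg"`; use `"cd_cacl2_mgkg"` or `"cd_msm_mgL"` for
#'   bioavailable-Cd rules).
#' @return List of class `confusion_summary`: counts `tp`, `fn`, `fp`, `tn`,
#'   total `n` and accuracy `acc` in percent.
#' @export
classify_exceedance <- function(data, rule, grain_limit = 0.1,
                                cd_pool = "cd_total_mgkg") {
  data <- as.data.frame(data)
  stopifnot(cd_pool %in% names(data))
  bad <- which(is.na(data[[cd_pool]]) | is.na(data$cd_wheat_mgkg) |
                 is.na(data$ph))
  if (length(bad))
    stop("records missing the tested Cd pool, grain Cd or pH: rows ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  per_record_cec <- inherits(rule, "threshold_curve") &&
    isTRUE(rule$needs_cec) && is.null(rule$cec)
  thr <- if (per_record_cec) {
    if (anyNA(data$cec_cmolkg))
      stop("records missing CEC for per-record threshold evaluation",
           call. = FALSE)
    predict(rule, data$ph, cec = data$cec_cmolkg)
  } else {
    predict(rule, data$ph)
  }
  pred_exceed <- data[[cd_pool]] > thr
  actual_exceed <- data$cd_wheat_mgkg > grain_limit
  tp <- sum(pred_exceed & actual_exceed)
  fn <- sum(!pred_exceed & actual_exceed)
  fp <- sum(pred_exceed & !actual_exceed)
  tn <- sum(!pred_exceed & !actual_exceed)
  confusion_summary(tp, fn, fp, tn)
}

#' Confusion summary with protection accuracy
#' @param tp,fn,fp,tn classification counts.
#' @return List of class `confusion_summary` with `acc` in percent.
#' @export
confusion_summary <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  n <- tp + fn + fp + tn
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, n = n,
                 acc = (tp + tn) / n * 100),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d | FN %d | FP %d | TN %d  (n = %d)\nAcc = %.2f%%\n",
              x$tp, x$fn, x$fp, x$tn, x$n, x$acc))
  invisible(x)
}
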