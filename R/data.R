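# Paired soil-wheat records: schema, validation, BCF, cleaning, splitting, CSV I/O.

#' Column schema for paired soil-wheat Cd records
#'
#' A dataset is an ordinary `data.frame` with one row per paired soil-wheat
#' sample and these columns (units encoded in the names):
#'
#' \describe{
#'   \item{ph}{soil pH (unitless), required, 0 < pH < 14}
#'   \item{cec_cmolkg}{cation exchange capacity, cmol/kg, required}
#'   \item{clay_pct}{clay fraction, percent, optional}
#'   \item{som_gkg}{soil organic matter, g/kg, optional}
#'   \item{fe_dcb_gkg}{dithionite-citrate-bicarbonate extractable Fe, g/kg, optional}
#'   \item{fe_ox_gkg}{oxalate-extractable (amorphous) Fe, g/kg, optional}
#'   \item{cd_total_mgkg}{total soil Cd, mg/kg, required, > 0}
#'   \item{cd_cacl2_mgkg}{0.01 M CaCl2-extractable Cd, mg/kg, optional, > 0}
#'   \item{cd_msm_mgL}{multi-surface-model dissolved Cd, mg/L at 1:10
#'     solid-liquid ratio, optional, > 0}
#'   \item{cd_wheat_mgkg}{wheat grain Cd, mg/kg, required, > 0}
#'   \item{source}{provenance tag: "literature", "survey" or "synthetic"}
#' }
#'
#' [as_cd_dataset()] adds a derived `bcf` column (grain Cd / soil total Cd)
#' and a unique `.id` identifier per record.
#'
#' @return Character vector of the canonical column names.
#' @export
cd_schema <- function() {
  c("ph", "cec_cmolkg", "clay_pct", "som_gkg", "fe_dcb_gkg", "fe_ox_gkg",
    "cd_total_mgkg", "cd_cacl2_mgkg", "cd_msm_mgL", "cd_wheat_mgkg", "source")
}

.required_cols <- c("ph", "cec_cmolkg", "cd_total_mgkg", "cd_wheat_mgkg")
.numeric_cols  <- setdiff(cd_schema(), "source")

#' Cadmium bioconcentration factor
#'
#' The ratio of wheat-grain Cd to soil total Cd, the dimensionless measure of
#' soil-to-grain transfer. Vectorised.
#'
#' @param cd_wheat wheat grain Cd, mg/kg; must be > 0.
#' @param cd_soil soil total Cd, mg/kg; must be > 0.
#' @return `cd_wheat / cd_soil`.
#' @examples
#' compute_bcf(0.298, 1.329)
#' @export
compute_bcf <- function(cd_wheat, cd_soil) {
  if (any(!is.finite(cd_wheat)) || any(cd_wheat <= 0))
    stop("compute_bcf: 'cd_wheat' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(cd_soil)) || any(cd_soil <= 0))
    stop("compute_bcf: 'cd_soil' must be finite and > 0", call. = FALSE)
  cd_wheat / cd_soil
}

# Row-wise invariant check. Returns character vector of violations ("" if ok).
.record_violation <- function(df) {
  msg <- rep("", nrow(df))
  bad <- function(cond, text) {
    cond[is.na(cond)] <- FALSE
    ifelse(cond & msg == "", text, msg)
  }
  msg <- bad(df$ph <= 0 | df$ph >= 14, "ph outside (0, 14)")
  msg <- bad(df$cec_cmolkg < 0, "negative cec")
  if ("clay_pct" %in% names(df)) {
    msg <- bad(df$clay_pct < 0 | df$clay_pct > 100, "clay outside [0, 100]")
  }
  for (col in intersect(c("som_gkg", "fe_dcb_gkg", "fe_ox_gkg"), names(df))) {
    msg <- bad(df[[col]] < 0, paste0("negative ", col))
  }
  for (col in intersect(c("cd_total_mgkg", "cd_cacl2_mgkg", "cd_msm_mgL",
                          "cd_wheat_mgkg"), names(df))) {
    msg <- bad(df[[col]] <= 0, paste0("non-positive ", col))
  }
  msg
}

#' Coerce a data.frame to a validated paired soil-wheat dataset
#'
#' Checks the column schema and per-record invariants (see [cd_schema()]),
#' computes the derived `bcf` column for rows with complete grain and soil Cd,
#' and assigns unique record identifiers in `.id`.
#'
#' Rows with missing required values are kept (tagged for removal by
#' [clean_dataset()]); rows with values that violate an invariant are an
#' error, reported with their row number.
#'
#' @param df data.frame following [cd_schema()]. Missing optional columns are
#'   added as `NA`.
#' @param meta named list of provenance metadata stored in `attr(, "meta")`.
#' @param id_prefix prefix for generated record identifiers.
#' @return A `data.frame` of class `cd_dataset`.
#' @export
as_cd_dataset <- function(df, meta = list(), id_prefix = "row") {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) stop("empty dataset", call. = FALSE)
  unknown <- setdiff(names(df), c(cd_schema(), "bcf", ".id"))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing_req <- setdiff(.required_cols, names(df))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(cd_schema(), names(df))) {
    df[[col]] <- if (col == "source") NA_character_ else NA_real_
  }
  for (col in .numeric_cols) {
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' is not numeric", call. = FALSE)
  }
  viol <- .record_violation(df)
  if (any(viol != "")) {
    i <- which(viol != "")[1L]
    stop("invalid record at row ", i, ": ", viol[i], call. = FALSE)
  }
  df$bcf <- ifelse(!is.na(df$cd_wheat_mgkg) & !is.na(df$cd_total_mgkg),
                   df$cd_wheat_mgkg / df$cd_total_mgkg, NA_real_)
  if (is.null(df$.id) || anyNA(df$.id)) {
    df$.id <- paste0(id_prefix, ":", seq_len(nrow(df)))
  }
  if (anyDuplicated(df$.id))
    stop("duplicated record identifiers", call. = FALSE)
  df <- df[c(cd_schema(), "bcf", ".id")]
  attr(df, "meta") <- meta
  class(df) <- c("cd_dataset", "data.frame")
  df
}

#' Clean a paired dataset: missing-value filter and 3-SD BCF outlier screen
#'
#' Applies, in one pass, the two screening rules used to assemble a modelling
#' dataset: (1) records missing any required field (pH, CEC, soil total Cd,
#' grain Cd) are dropped with reason `"missing value"`; (2) among the
#' survivors, records whose raw bioconcentration factor lies outside
#' mean ± 3 sample standard deviations of the survivors' BCF distribution are
#' dropped with reason `"bcf outlier"`. The mean and SD are computed once, on
#' the records that pass the missing-value filter, and not recomputed after
#' removals: the screen is one-pass, not iterated. A screened dataset carries
#' the screening record in its metadata and is not re-screened, so cleaning
#' is idempotent even for heavy-tailed BCF distributions (where recomputing
#' the SD after removals would otherwise flag ever more records).
#'
#' @param data a `cd_dataset` (see [as_cd_dataset()]).
#' @return The cleaned `cd_dataset`. The removal log (a data.frame with
#'   columns `.id` and `reason`) is attached as `attr(, "cleaning")`.
#' @export
clean_dataset <- function(data) {
  stopifnot(inherits(data, "cd_dataset"))
  missing_req <- Reduce(`|`, lapply(.required_cols, function(c) is.na(data[[c]])))
  removed <- data.frame(.id = data$.id[missing_req],
                        reason = rep("missing value", sum(missing_req)),
                        stringsAsFactors = FALSE)
  kept <- data[!missing_req, , drop = FALSE]
  if (nrow(kept) == 0L) stop("empty dataset after cleaning", call. = FALSE)
  meta <- attr(data, "meta")
  if (is.null(meta$bcf_screen)) {
    m <- mean(kept$bcf)
    s <- stats::sd(kept$bcf)
    if (is.na(s)) s <- 0  # single record: nothing to screen
    out <- abs(kept$bcf - m) > 3 * s
    removed <- rbind(removed,
                     data.frame(.id = kept$.id[out],
                                reason = rep("bcf outlier", sum(out)),
                                stringsAsFactors = FALSE))
    kept <- kept[!out, , drop = FALSE]
    if (nrow(kept) == 0L) stop("empty dataset after cleaning", call. = FALSE)
    meta$bcf_screen <- list(mean = m, sd = s)
  }
  meta$cleaning <- removed
  attr(kept, "meta") <- meta
  attr(kept, "cleaning") <- removed
  class(kept) <- c("cd_dataset", "data.frame")
  kept
}

#' Specification of the repeated train/test splitting protocol
#'
#' Captures the resampling protocol: independent random splits into training
#' and test sets at a 4:1 ratio by default, with k-fold cross-validation and a
#' pre-train/validation sub-split available inside each training set.
#'
#' @param test_fraction proportion of records held out per split (default 0.2,
#'   i.e. a 4:1 train:test ratio).
#' @param n_repeats number of independent random splits (default 10).
#' @param cv_folds folds for cross-validation within training (default 10).
#' @param pretrain_fraction share of the training set used for pre-training in
#'   the 9:1 pre-train/validation sub-split (default 0.9).
#' @param seed integer random seed fixing all splits.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, n_repeats = 10, cv_folds = 10,
                       pretrain_fraction = 0.9, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_repeats >= 1,
            cv_folds >= 2, pretrain_fraction > 0, pretrain_fraction < 1)
  structure(list(test_fraction = test_fraction, n_repeats = as.integer(n_repeats),
                 cv_folds = as.integer(cv_folds),
                 pretrain_fraction = pretrain_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

# Run expr with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Repeated random train/test splits
#'
#' Partitions the dataset into train and test sets `n_repeats` times. Each
#' repeat is an exhaustive, disjoint partition with the test size equal to
#' `round(n * test_fraction)`; identical seeds reproduce identical partitions.
#'
#' @param data a `cd_dataset` with at least 5 records.
#' @param spec a [split_spec()].
#' @return List of length `n_repeats`; each element has `train` and `test`
#'   (`cd_dataset` subsets) and the index vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(data, spec = split_spec()) {
  stopifnot(inherits(data, "cd_dataset"), inherits(spec, "split_spec"))
  n <- nrow(data)
  if (n < 5L) stop("need at least 5 records to split", call. = FALSE)
  n_test <- round(n * spec$test_fraction)
  if (n_test < 1L || n_test >= n)
    stop("test_fraction yields an empty train or test set", call. = FALSE)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_repeats), function(r) {
      test_idx <- sort(sample.int(n, n_test))
      train_idx <- setdiff(seq_len(n), test_idx)
      list(train = data[train_idx, , drop = FALSE],
           test = data[test_idx, , drop = FALSE],
           train_idx = train_idx, test_idx = test_idx)
    })
  })
}

#' Read a paired soil-wheat dataset from CSV
#'
#' Reads the canonical CSV layout (header row per [cd_schema()], one record
#' per row, UTF-8, decimal point, empty cell for missing optional values),
#' validates invariants with row-numbered errors, and applies per-column unit
#' conversion where declared.
#'
#' @param path CSV file path.
#' @param units optional named character vector remapping a column's units on
#'   load; currently supported: `c(cd_cacl2_mgkg = "ug/kg")` to convert
#'   microgram-per-kilogram values to the internal mg/kg.
#' @return A `cd_dataset`.
#' @export
read_cd_csv <- function(path, units = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  keep_id <- ".id" %in% names(raw)
  for (col in intersect(.numeric_cols, names(raw))) {
    if (!is.numeric(raw[[col]])) {
      nonnum <- which(!is.na(raw[[col]]) & is.na(suppressWarnings(as.numeric(raw[[col]]))))
      if (length(nonnum))
        stop("non-numeric value in column '", col, "' at row ", nonnum[1L],
             call. = FALSE)
      raw[[col]] <- as.numeric(raw[[col]])
    }
  }
  if (!is.null(units)) {
    for (col in names(units)) {
      if (!col %in% names(raw)) next
      raw[[col]] <- switch(units[[col]],
        "ug/kg" = , "ug/L" = raw[[col]] / 1000,
        "mg/kg" = , "mg/L" = raw[[col]],
        stop("unsupported unit declaration '", units[[col]], "' for ", col,
             call. = FALSE))
    }
  }
  raw$bcf <- NULL
  as_cd_dataset(raw, meta = list(path = path),
                id_prefix = if (keep_id) "row" else basename(path))
}

#' Write a paired soil-wheat dataset to CSV
#'
#' Values are written with 15 significant digits so that
#' `read_cd_csv(write_cd_csv(d))` round-trips numerically.
#'
#' @param data a `cd_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cd_csv <- function(data, path) {
  stopifnot(inherits(data, "cd_dataset"))
  out <- as.data.frame(data)[c(cd_schema(), ".id")]
  for (col in .numeric_cols) out[[col]] <- formatC(out[[col]], digits = 15,
                                                   format = "g")
  out[is.na(as.data.frame(data)[names(out)])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
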