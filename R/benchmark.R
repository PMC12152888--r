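# Repeated-split benchmark of eight regression learners for grain-Cd
# prediction, with k-fold CV hyperparameter choice inside each training set
# and impurity-based feature ranking for the tree ensembles.

.bench_algorithms <- c("ridge", "dt", "svr", "knn", "rf", "ert", "gbdt", "xgb")
.bench_ensembles <- c("rf", "ert", "gbdt", "xgb")

#' Benchmark specification
#'
#' Algorithms (by key): `ridge` (ridge regression, MASS), `dt` (decision
#' tree, rpart), `svr` (support-vector regression, e1071), `knn` (k-nearest
#' neighbours, caret), `rf` (random forest), `ert` (extremely randomized
#' trees, ranger), `gbdt` (gradient-boosted trees) and `xgb` (extreme
#' gradient boosting), the last two via the xgboost library with classic
#' unregularised and regularised configurations respectively.
#'
#' Hyperparameter grids are deliberately small and fixed: 100 trees for every
#' ensemble, tree depth in \{unlimited, 10\} for the decision tree, k in
#' \{3, 5, 7\}, ridge penalty in \{0.1, 1, 10\}. Grids with more than one
#' point are resolved by cross-validation within each training split.
#'
#' @param algorithms subset of the eight algorithm keys.
#' @param split a [split_spec()]; defaults to ten 4:1 splits with 10-fold CV.
#' @param features predictor columns; default the soil-property set plus
#'   total Cd (bioavailable pools excluded). Cd pools are log10-transformed
#'   in the design matrix.
#' @param n_trees ensemble size (default 100).
#' @param k_grid,ridge_grid,depth_grid the documented grids.
#' @return A list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(algorithms = .bench_algorithms,
                           split = split_spec(),
                           features = c("ph", "cec_cmolkg", "clay_pct",
                                        "som_gkg", "fe_dcb_gkg", "fe_ox_gkg",
                                        "cd_total_mgkg"),
                           n_trees = 100L, k_grid = c(3L, 5L, 7L),
                           ridge_grid = c(0.1, 1, 10),
                           depth_grid = c(30L, 10L)) {
  unknown <- setdiff(algorithms, .bench_algorithms)
  if (length(unknown))
    stop("unknown algorithm(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(algorithms) == 0) stop("no algorithms requested", call. = FALSE)
  stopifnot(n_trees >= 1)
  structure(list(algorithms = algorithms, split = split, features = features,
                 n_trees = as.integer(n_trees), k_grid = k_grid,
                 ridge_grid = ridge_grid, depth_grid = depth_grid),
            class = "benchmark_spec")
}

# Design matrix: log10 the Cd pool columns, keep the rest raw.
.bench_design <- function(data, features) {
  X <- as.data.frame(data)[features]
  for (f in intersect(features, .cd_pool_cols)) {
    if (any(X[[f]] <= 0, na.rm = TRUE))
      stop("non-positive value for log10 feature '", f, "'", call. = FALSE)
    X[[f]] <- log10(X[[f]])
    names(X)[names(X) == f] <- paste0("log10_", f)
  }
  X
}

# Fit one learner; returns list(predict = function(X), model = fitted object).
.bench_fit <- function(alg, X, y, hp, spec) {
  df <- cbind(X, .y = y)
  p <- ncol(X)
  switch(alg,
    ridge = {
      m <- MASS::lm.ridge(.y ~ ., data = df, lambda = hp$lambda)
      cf <- stats::coef(m)
      list(model = m,
           predict = function(Z) drop(as.matrix(cbind(1, Z)) %*% cf))
    },
    dt = {
      m <- rpart::rpart(.y ~ ., data = df,
                        control = rpart::rpart.control(maxdepth = hp$depth,
                                                       cp = 0.001, xval = 0))
      list(model = m, predict = function(Z) unname(stats::predict(m, Z)))
    },
    svr = {
      m <- e1071::svm(.y ~ ., data = df)
      list(model = m, predict = function(Z) unname(stats::predict(m, Z)))
    },
    knn = {
      ctr <- colMeans(X)
      scl <- pmax(apply(X, 2, stats::sd), .Machine$double.eps)
      Xs <- scale(X, ctr, scl)
      m <- caret::knnreg(as.data.frame(Xs), y, k = hp$k)
      list(model = m,
           predict = function(Z)
             unname(stats::predict(m, as.data.frame(scale(Z, ctr, scl)))))
    },
    rf = {
      m <- randomForest::randomForest(X, y, ntree = spec$n_trees)
      list(model = m, predict = function(Z) unname(stats::predict(m, Z)))
    },
    ert = {
      m <- ranger::ranger(.y ~ ., data = df, num.trees = spec$n_trees,
                          splitrule = "extratrees", num.random.splits = 1,
                          mtry = p, replace = FALSE, sample.fraction = 1,
                          importance = "impurity", num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1))
      list(model = m,
           predict = function(Z)
             stats::predict(m, Z, num.threads = 1)$predictions)
    },
    gbdt = {
      m <- xgboost::xgboost(x = as.matrix(X), y = y, nrounds = spec$n_trees,
                            nthreads = 1, verbosity = 0, learning_rate = 0.1,
                            max_depth = 3, reg_lambda = 0, reg_alpha = 0,
                            min_child_weight = 1, subsample = 1)
      list(model = m,
           predict = function(Z) stats::predict(m, as.matrix(Z)))
    },
    xgb = {
      m <- xgboost::xgboost(x = as.matrix(X), y = y, nrounds = spec$n_trees,
                            nthreads = 1, verbosity = 0, learning_rate = 0.3,
                            max_depth = 6)
      list(model = m,
           predict = function(Z) stats::predict(m, as.matrix(Z)))
    },
    stop("unknown algorithm '", alg, "'", call. = FALSE))
}

.bench_grid <- function(alg, spec) {
  switch(alg,
    ridge = lapply(spec$ridge_grid, function(l) list(lambda = l)),
    dt = lapply(spec$depth_grid, function(d) list(depth = d)),
    knn = lapply(spec$k_grid, function(k) list(k = k)),
    list(list()))
}

.r2 <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

# Mean CV R^2 of one hyperparameter setting on the training set.
.cv_score <- function(alg, hp, X, y, folds, spec) {
  fold_id <- sample(rep(seq_len(folds), length.out = length(y)))
  pred <- numeric(length(y))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- .bench_fit(alg, X[!hold, , drop = FALSE], y[!hold], hp, spec)
    pred[hold] <- fit$predict(X[hold, , drop = FALSE])
  }
  .r2(y, pred)
}

#' Impurity-based feature importance shares of a fitted tree ensemble
#'
#' Normalises the ensemble's impurity-reduction importances to shares summing
#' to one and orders them descending. Supported fitted objects:
#' `randomForest`, `ranger`, and `xgb.Booster`.
#'
#' @param fitted a fitted ensemble object.
#' @param feature_names optional feature names (required for `xgb.Booster` to
#'   include zero-importance features).
#' @return data.frame with columns `feature` and `share` (descending,
#'   summing to 1).
#' @export
rank_feature_importance <- function(fitted, feature_names = NULL) {
  if (inherits(fitted, "randomForest")) {
    imp <- fitted$importance[, "IncNodePurity"]
  } else if (inherits(fitted, "ranger")) {
    imp <- fitted$variable.importance
  } else if (inherits(fitted, "xgb.Booster")) {
    tab <- xgboost::xgb.importance(model = fitted)
    imp <- stats::setNames(tab$Gain, tab$Feature)
    if (!is.null(feature_names)) {
      full <- stats::setNames(numeric(length(feature_names)), feature_names)
      full[names(imp)] <- imp
      imp <- full
    }
  } else {
    stop("unsupported model: impurity importance requires a tree ensemble",
         call. = FALSE)
  }
  imp <- pmax(imp, 0)
  share <- if (sum(imp) > 0) imp / sum(imp) else imp
  out <- data.frame(feature = names(share), share = unname(share))
  out[order(-out$share), , drop = FALSE]
}

#' Run the repeated-split benchmark
#'
#' For each of the spec's independent 4:1 splits: hyperparameter grids with
#' more than one point are resolved by `cv_folds`-fold cross-validation on
#' the training set; the chosen configuration is then refit on the 9:1
#' pre-train portion and scored on the held-in validation portion (recorded
#' as `val_r2`); the final model is fit on the full training set and scored
#' on the untouched test split. The label is `log10(cd_wheat)` throughout, so
#' all metrics are on the log10 scale. Fixed seeds make the whole run
#' reproducible.
#'
#' @param data a cleaned `cd_dataset` with at least 30 records.
#' @param spec a [benchmark_spec()].
#' @return A list of class `cd_benchmark`: `results` (one row per algorithm
#'   and repeat), `summary` (mean and sd of test metrics per algorithm),
#'   `importances` (mean impurity shares per ensemble algorithm), and
#'   `splits` (record identifiers per repeat, for leakage auditing).
#' @export
run_benchmark <- function(data, spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  data <- as.data.frame(data)
  keep <- stats::complete.cases(data[c(spec$features, "cd_wheat_mgkg")])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 30) stop("need at least 30 complete records", call. = FALSE)
  if (nrow(data) < spec$split$cv_folds)
    stop("dataset smaller than the fold count", call. = FALSE)
  ds <- data
  if (is.null(ds$.id)) ds$.id <- paste0("row:", seq_len(nrow(ds)))
  class(ds) <- c("cd_dataset", "data.frame")
  splits <- split_dataset(ds, spec$split)
  X_all <- .bench_design(data, spec$features)
  y_all <- log10(data$cd_wheat_mgkg)

  rows <- list(); imps <- list()
  with_seed(spec$split$seed + 1L, {
    for (r in seq_along(splits)) {
      tr <- splits[[r]]$train_idx; te <- splits[[r]]$test_idx
      Xtr <- X_all[tr, , drop = FALSE]; ytr <- y_all[tr]
      Xte <- X_all[te, , drop = FALSE]; yte <- y_all[te]
      n_pre <- floor(length(tr) * spec$split$pretrain_fraction)
      pre <- sample(seq_along(tr), n_pre)
      for (alg in spec$algorithms) {
        grid <- .bench_grid(alg, spec)
        hp <- grid[[1]]
        cv_r2 <- NA_real_
        if (length(grid) > 1) {
          scores <- vapply(grid, function(h)
            .cv_score(alg, h, Xtr, ytr, spec$split$cv_folds, spec), 0)
          hp <- grid[[which.max(scores)]]
          cv_r2 <- max(scores)
        }
        pre_fit <- .bench_fit(alg, Xtr[pre, , drop = FALSE], ytr[pre], hp, spec)
        val_r2 <- .r2(ytr[-pre], pre_fit$predict(Xtr[-pre, , drop = FALSE]))
        fit <- .bench_fit(alg, Xtr, ytr, hp, spec)
        pred_te <- fit$predict(Xte)
        res <- yte - pred_te
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, repeat_id = r,
          hyperparams = paste(names(hp), unlist(hp), sep = "=", collapse = ","),
          cv_r2 = cv_r2, val_r2 = val_r2,
          r2_train = .r2(ytr, fit$predict(Xtr)), r2_test = .r2(yte, pred_te),
          rmse_test = sqrt(mean(res^2)), mae_test = mean(abs(res)),
          stringsAsFactors = FALSE)
        if (alg %in% .bench_ensembles) {
          im <- rank_feature_importance(fit$model, names(X_all))
          im$algorithm <- alg; im$repeat_id <- r
          imps[[length(imps) + 1L]] <- im
        }
      }
    }
  })
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results$algorithm), function(d)
    data.frame(algorithm = d$algorithm[1],
               r2_test_mean = mean(d$r2_test), r2_test_sd = stats::sd(d$r2_test),
               rmse_test_mean = mean(d$rmse_test),
               mae_test_mean = mean(d$mae_test))))
  agg <- agg[order(-agg$r2_test_mean), , drop = FALSE]
  importances <- NULL
  if (length(imps)) {
    all_imp <- do.call(rbind, imps)
    importances <- do.call(rbind, lapply(
      split(all_imp, list(all_imp$algorithm, all_imp$feature)), function(d)
        data.frame(algorithm = d$algorithm[1], feature = d$feature[1],
                   share = mean(d$share))))
    importances <- importances[order(importances$algorithm,
                                     -importances$share), , drop = FALSE]
    rownames(importances) <- NULL
  }
  structure(list(results = results, summary = agg, importances = importances,
                 splits = lapply(splits, function(s)
                   list(train_ids = ds$.id[s$train_idx],
                        test_ids = ds$.id[s$test_idx])),
                 spec = spec),
            class = "cd_benchmark")
}

#' @export
print.cd_benchmark <- function(x, ...) {
  cat("Benchmark over", length(x$splits), "repeat(s),",
      length(x$spec$algorithms), "algorithm(s)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
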