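#' Pipeline configuration
#'
#' Parameters of the age-regression pipeline: per-fold Spearman selection
#' size, number of principal components, perceptron hyperparameters, fold
#' unit, and the top-level seed from which all fold seeds derive.
#'
#' @param k_select features kept by absolute Spearman ranking (15).
#' @param n_components principal components kept (3).
#' @param hidden hidden layer sizes of the perceptron.
#' @param epochs,lr,l2 perceptron training constants (see [mlp_fit()]).
#' @param group_folds if `TRUE`, folds leave one patient out rather than
#'   one image out.
#' @param seed top-level seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_select = 15L, n_components = 3L,
                            hidden = c(10L, 10L), epochs = 600L, lr = 0.02,
                            l2 = 0.03, group_folds = FALSE, seed = 1L) {
  structure(
    list(k_select = as.integer(k_select),
         n_components = as.integer(n_components), hidden = as.integer(hidden),
         epochs = as.integer(epochs), lr = lr, l2 = l2,
         group_folds = isTRUE(group_folds), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Rank features by absolute Spearman correlation with age
#'
#' Computed on training rows only; the `k` features with the largest
#' `|rho|` are returned, ties broken by schema order. Features that are
#' constant on the training rows get `|rho| = 0`.
#'
#' @param table a [feature_table()].
#' @param train_rows integer indices of the training rows.
#' @param k number of features to keep.
#' @return character vector of `k` feature names.
#' @export
spearman_select <- function(table, train_rows, k = 15L) {
  if (length(train_rows) < 3) stop("need at least 3 training rows")
  X <- table$features[train_rows, , drop = FALSE]
  y <- table$age_years[train_rows]
  if (stats::sd(y) == 0) stop("degenerate labels: age is constant on training rows")
  rho <- suppressWarnings(as.vector(stats::cor(X, y, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  ord <- order(-abs(rho), seq_along(rho))
  colnames(X)[ord[seq_len(k)]]
}

#' Fit a PCA basis on training rows
#'
#' Features are centred and scaled to unit variance by their training
#' statistics, then reduced to `n_components` principal components
#' (ordered by decreasing explained variance). Fails if the training data
#' span fewer non-degenerate directions than requested.
#'
#' @param table a [feature_table()].
#' @param train_rows training row indices.
#' @param features feature names to use (e.g. from [spearman_select()]).
#' @param n_components components to keep.
#' @return list of class `pca_basis` with `center`, `scale`, `rotation`
#'   (orthonormal columns), `sdev`, and the training `scores`.
#' @export
pca_reduce <- function(table, train_rows, features, n_components = 3L) {
  if (length(train_rows) < n_components + 1) {
    stop("need at least n_components + 1 training rows")
  }
  X <- table$features[train_rows, features, drop = FALSE]
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  sv <- svd(Xs)
  tol <- max(dim(Xs)) * .Machine$double.eps * max(sv$d)
  rank <- sum(sv$d > tol)
  if (rank < n_components) {
    stop("rank error: training data span ", rank,
         " directions, need ", n_components)
  }
  rotation <- sv$v[, seq_len(n_components), drop = FALSE]
  rownames(rotation) <- features
  scores <- Xs %*% rotation
  structure(
    list(center = center, scale = scale_, rotation = rotation,
         sdev = sv$d / sqrt(max(1, nrow(Xs) - 1)),
         scores = scores, features = features),
    class = "pca_basis"
  )
}

#' Project rows of a feature table onto a fitted PCA basis
#'
#' @param basis a [pca_reduce()] result.
#' @param table a [feature_table()].
#' @param rows row indices to project.
#' @return matrix of component scores.
#' @export
pca_transform <- function(basis, table, rows) {
  X <- table$features[rows, basis$features, drop = FALSE]
  Xs <- sweep(sweep(X, 2, basis$center), 2, basis$scale, "/")
  Xs %*% basis$rotation
}

#' Fit the regressor for one cross-validation fold
#'
#' Selection, PCA and the perceptron are all fitted on the training rows
#' only; nothing about any held-out row enters the fold model.
#'
#' @param table a [feature_table()].
#' @param train_rows training row indices.
#' @param config a [pipeline_config()].
#' @param seed seed for this fold's weight initialization.
#' @return list of class `fold_model` with `selected`, `pca`, `mlp`,
#'   `seed`.
#' @export
fit_fold <- function(table, train_rows, config = pipeline_config(),
                     seed = config$seed) {
  selected <- spearman_select(table, train_rows, k = config$k_select)
  basis <- pca_reduce(table, train_rows, selected,
                      n_components = config$n_components)
  fit <- mlp_fit(basis$scores, table$age_years[train_rows], seed = seed,
                 hidden = config$hidden, epochs = config$epochs,
                 lr = config$lr, l2 = config$l2)
  structure(list(selected = selected, pca = basis, mlp = fit, seed = seed),
            class = "fold_model")
}

#' Predict ages for rows of a table from a fold model
#'
#' @param model a [fit_fold()] result.
#' @param table a [feature_table()].
#' @param rows row indices to predict.
#' @return numeric predicted ages.
#' @export
predict_fold <- function(model, table, rows) {
  predict(model$mlp, pca_transform(model$pca, table, rows))
}

#' Regression error metrics
#'
#' MSE, RMSE, MAE and the coefficient of determination
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed on the
#' pooled predictions.
#'
#' @param y true values.
#' @param yhat predictions.
#' @return named list `r2`, `rmse`, `mse`, `mae`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mse <- mean((y - yhat)^2)
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       rmse = sqrt(mse), mse = mse, mae = mean(abs(y - yhat)))
}

#' Leave-one-out evaluation of the full pipeline
#'
#' For every fold (one image, or one patient with `group_folds`), the
#' Spearman selection, PCA basis and perceptron are re-fitted on the
#' remaining rows and the held-out rows are predicted; the four error
#' metrics are computed on the pooled predictions. Fold `i` uses seed
#' `config$seed + i` so the whole report is reproducible from the one
#' top-level seed.
#'
#' @param table a [feature_table()] (needs >= 4 rows).
#' @param config a [pipeline_config()].
#' @return list of class `loo_report`: `predictions` data.frame (row,
#'   patient_id, age_years, predicted), `metrics`, `config_digest`,
#'   `seed`.
#' @export
loo_evaluate <- function(table, config = pipeline_config()) {
  n <- nrow(table$features)
  if (n < 4) stop("need at least 4 samples for leave-one-out evaluation")
  units <- if (config$group_folds) {
    split(seq_len(n), table$patient_id)
  } else {
    as.list(seq_len(n))
  }
  pred <- rep(NA_real_, n)
  for (f in seq_along(units)) {
    holdout <- units[[f]]
    train <- setdiff(seq_len(n), holdout)
    model <- tryCatch(
      fit_fold(table, train, config, seed = config$seed + f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    pred[holdout] <- predict_fold(model, table, holdout)
  }
  metrics <- regression_metrics(table$age_years, pred)
  structure(
    list(predictions = data.frame(
           row = seq_len(n), patient_id = table$patient_id,
           age_years = table$age_years, predicted = pred),
         metrics = metrics, config_digest = config_digest(config),
         seed = config$seed),
    class = "loo_report"
  )
}

config_digest <- function(config) {
  paste0("k", config$k_select, "-pc", config$n_components,
         "-h", paste(config$hidden, collapse = "x"),
         "-e", config$epochs, "-lr", format(config$lr),
         "-l2", format(config$l2),
         "-", if (config$group_folds) "patientfold" else "imagefold")
}

#' Write a leave-one-out report to disk
#'
#' Per-sample predictions as CSV plus the metrics, configuration digest
#' and seed as JSON.
#'
#' @param report a [loo_evaluate()] result.
#' @param csv_path,json_path output paths.
#' @return invisible list of the two paths.
#' @export
write_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$predictions, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics, config_digest = report$config_digest,
         seed = report$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}

#' @export
print.loo_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<loo_report> n=%d  R2=%.4f  RMSE=%.4f  MSE=%.4f  MAE=%.4f  (%s, seed %d)\n",
    nrow(x$predictions), m$r2, m$rmse, m$mse, m$mae, x$config_digest, x$seed))
  invisible(x)
}
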