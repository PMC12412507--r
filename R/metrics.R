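#' Lin's concordance correlation coefficient
#'
#' Agreement between predicted and true values, penalizing both location
#' and scale shifts: `2*cov(y, yhat) / (var(y) + var(yhat) + (mean(y) -
#' mean(yhat))^2)`. Population (divide-by-N) moments by default, matching
#' the usual CCC convention.
#'
#' @param y True values.
#' @param y_hat Predicted values.
#' @param population Use population variances (default) or sample (N-1).
#' @return Scalar in \[-1, 1\].
#' @export
ccc <- function(y, y_hat, population = TRUE) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2) stop("ccc requires at least 2 observations")
  n <- length(y)
  denom_n <- if (population) n else n - 1
  my <- mean(y); mh <- mean(y_hat)
  vy <- sum((y - my)^2) / denom_n
  vh <- sum((y_hat - mh)^2) / denom_n
  cv <- sum((y - my) * (y_hat - mh)) / denom_n
  if (vy == 0 && vh == 0)
    stop("ccc undefined: both vectors are constant")
  2 * cv / (vy + vh + (my - mh)^2)
}

#' Root mean square error
#'
#' @param y True values.
#' @param y_hat Predicted values.
#' @return Non-negative scalar.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sqrt(mean((y - y_hat)^2))
}

#' Pearson correlation coefficient
#'
#' @param y True values.
#' @param y_hat Predicted values.
#' @return Scalar in \[-1, 1\].
#' @export
pcc <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0)
    stop("pcc undefined: constant vector")
  stats::cor(y, y_hat)
}

#' Evaluate predicted against true cell-type proportions
#'
#' Produces both views used in deconvolution benchmarking: per-sample
#' metrics computed across the cell-type entries of each row, and
#' per-cell-type metrics computed across samples for each column.
#' Aggregates are unweighted means (rows with undefined metrics are
#' dropped from the mean with a warning).
#'
#' @param pred,truth [proportion_matrix()] objects with matching
#'   `sample_ids` and `type_universe`.
#' @return A `metric_report`: list with data.frames `per_sample`,
#'   `per_celltype` (NULL with a warning when fewer than 2 samples), and
#'   `aggregate` (named lists of means).
#' @export
evaluate_deconv <- function(pred, truth) {
  validate_proportion_matrix(pred)
  validate_proportion_matrix(truth)
  if (!identical(pred$sample_ids, truth$sample_ids))
    stop("pred and truth must have identical sample_ids")
  if (!identical(pred$type_universe, truth$type_universe))
    stop("pred and truth must have identical type_universe")
  P <- pred$values; Y <- truth$values
  safe <- function(f, a, b) tryCatch(f(a, b), error = function(e) NA_real_)
  per_sample <- data.frame(
    sample_id = pred$sample_ids,
    ccc  = vapply(seq_len(nrow(Y)), function(i) safe(ccc,  Y[i, ], P[i, ]), 0),
    rmse = vapply(seq_len(nrow(Y)), function(i) rmse(Y[i, ], P[i, ]), 0),
    pcc  = vapply(seq_len(nrow(Y)), function(i) safe(pcc,  Y[i, ], P[i, ]), 0),
    stringsAsFactors = FALSE)
  if (anyNA(per_sample$ccc) || anyNA(per_sample$pcc))
    warning("some per-sample metrics undefined (constant rows); dropped from aggregates")
  if (nrow(Y) < 2) {
    warning("per-cell-type metrics undefined: need at least 2 samples")
    per_celltype <- NULL
  } else {
    per_celltype <- data.frame(
      cell_type = pred$type_universe,
      ccc  = vapply(seq_len(ncol(Y)), function(j) safe(ccc,  Y[, j], P[, j]), 0),
      rmse = vapply(seq_len(ncol(Y)), function(j) rmse(Y[, j], P[, j]), 0),
      pcc  = vapply(seq_len(ncol(Y)), function(j) safe(pcc,  Y[, j], P[, j]), 0),
      stringsAsFactors = FALSE)
  }
  agg <- function(df) if (is.null(df)) NULL else
    list(ccc = mean(df$ccc, na.rm = TRUE),
         rmse = mean(df$rmse, na.rm = TRUE),
         pcc = mean(df$pcc, na.rm = TRUE))
  structure(list(per_sample = per_sample, per_celltype = per_celltype,
                 aggregate = list(per_sample = agg(per_sample),
                                  per_celltype = agg(per_celltype))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregate$per_sample
  cat(sprintf("metric_report: sample-wise mean CCC %.4f, RMSE %.4f, PCC %.4f (%d samples)\n",
              a$ccc, a$rmse, a$pcc, nrow(x$per_sample)))
  if (!is.null(x$per_celltype)) {
    b <- x$aggregate$per_celltype
    cat(sprintf("  cell-type-wise mean CCC %.4f, RMSE %.4f, PCC %.4f (%d types)\n",
                b$ccc, b$rmse, b$pcc, nrow(x$per_celltype)))
  }
  invisible(x)
}
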