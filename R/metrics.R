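#' Coefficient of determination (squared Pearson correlation)
#'
#' `r_squared` is the squared Pearson correlation between observed and
#' predicted series; it equals 1 for any exact positive or negative affine
#' relationship and is undefined (an error) when either series is constant.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return Dimensionless value in \[0, 1\].
#' @export
r_squared <- function(observed, predicted) {
  .check_series(observed, predicted, min_n = 2)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    stop("r_squared undefined for a constant series")
  }
  stats::cor(observed, predicted)^2
}

#' Mean absolute error
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return MAE in the natural units of the response.
#' @export
mae <- function(observed, predicted) {
  .check_series(observed, predicted, min_n = 1)
  mean(abs(observed - predicted))
}

#' Root mean squared error
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return RMSE in the natural units of the response; always >= [mae()].
#' @export
rmse <- function(observed, predicted) {
  .check_series(observed, predicted, min_n = 1)
  sqrt(mean((observed - predicted)^2))
}

.check_series <- function(observed, predicted, min_n) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ")
  }
  if (length(observed) < min_n) stop("need at least ", min_n, " observations")
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite values in series")
  }
  invisible(TRUE)
}

#' Evaluate a fitted model on a replicate-level table
#'
#' Predictions are made in natural response units (no clipping) and compared
#' with the observed response by R-squared, RMSE and MAE.
#'
#' @param model An `svr_model` or `mlp_model`.
#' @param data Replicate-level data.frame.
#' @param inputs Input column names.
#' @return One-row data.frame with `r2`, `rmse`, `mae`, `n`.
#' @export
evaluate_model <- function(model, data, inputs = .input_cols) {
  ycol <- .response_map$column[.response_map$response == model$target_name]
  obs <- data[[ycol]]
  pred <- predict(model, data[inputs])
  data.frame(r2 = r_squared(obs, pred), rmse = rmse(obs, pred),
             mae = mae(obs, pred), n = length(obs))
}

#' Performance table for a set of fitted models
#'
#' Builds the model-comparison table: one row per (model family, response,
#' partition) with R-squared, RMSE and MAE in natural units.
#'
#' @param models Named list of fitted models; names are used as the family
#'   label (e.g. `svr`, `mlp`), each element itself a named list by response.
#' @param partitions Named list of replicate-level data.frames
#'   (e.g. `list(train = ..., test = ...)`).
#' @param inputs Input column names.
#' @return data.frame of class `metrics_report`.
#' @export
metrics_report <- function(models, partitions, inputs = .input_cols) {
  rows <- list()
  for (fam in names(models)) {
    for (resp in names(models[[fam]])) {
      for (part in names(partitions)) {
        m <- evaluate_model(models[[fam]][[resp]], partitions[[part]], inputs)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(model = fam, response = resp, partition = part), m)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}
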