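#' Fit a min-max scaler
#'
#' Records the observed minimum and maximum of each named variable so that it
#' can be mapped linearly onto \[0, 1\]. Fit on the training partition only;
#' out-of-range values at prediction time map linearly outside \[0, 1\]
#' (no clipping).
#'
#' @param table A data.frame containing `variables`.
#' @param variables Character vector of column names to scale.
#' @return An object of class `scaler`.
#' @examples
#' sc <- fit_scaler(load_fixture(), c("d24_uM", "kin_uM", "snp_uM"))
#' @export
fit_scaler <- function(table, variables) {
  stopifnot(is.data.frame(table), length(variables) >= 1)
  missing <- setdiff(variables, names(table))
  if (length(missing)) stop("unknown variable(s): ", paste(missing, collapse = ", "))
  mins <- vapply(variables, function(v) min(table[[v]]), numeric(1))
  maxs <- vapply(variables, function(v) max(table[[v]]), numeric(1))
  degenerate <- variables[maxs <= mins]
  if (length(degenerate)) {
    stop("constant variable(s) cannot be min-max scaled: ",
         paste(degenerate, collapse = ", "))
  }
  structure(list(variables = variables, min = mins, max = maxs),
            class = "scaler")
}

#' Apply or invert a min-max scaler
#'
#' `apply_scaler` maps each fitted variable x to (x - min) / (max - min);
#' `invert_scaler` is its exact inverse. Round-tripping reproduces the input
#' to within 1e-12. Non-fitted columns pass through untouched.
#'
#' @param params A [fit_scaler()] object.
#' @param table data.frame (or matrix with fitted column names).
#' @return The table with fitted variables transformed.
#' @export
apply_scaler <- function(params, table) {
  .scale_table(params, table, invert = FALSE)
}

#' @rdname apply_scaler
#' @param scaled A table in scaled units.
#' @export
invert_scaler <- function(params, scaled) {
  .scale_table(params, scaled, invert = TRUE)
}

.scale_table <- function(params, table, invert) {
  stopifnot(inherits(params, "scaler"))
  is_vec <- is.null(dim(table)) && length(params$variables) == 1L
  if (is_vec) {
    table <- stats::setNames(data.frame(table), params$variables)
  }
  missing <- setdiff(params$variables, colnames(table))
  if (length(missing)) stop("unknown variable(s): ", paste(missing, collapse = ", "))
  for (v in params$variables) {
    rng <- params$max[[v]] - params$min[[v]]
    table[, v] <- if (invert) table[, v] * rng + params$min[[v]]
                  else (table[, v] - params$min[[v]]) / rng
  }
  if (is_vec) table[[1]] else table
}

#' @export
print.scaler <- function(x, ...) {
  cat("min-max scaler:\n")
  print(data.frame(min = x$min, max = x$max))
  invisible(x)
}

#' Serialize a scaler to/from JSON
#'
#' @param params A [fit_scaler()] object.
#' @param json A JSON string produced by `scaler_to_json`.
#' @return `scaler_to_json`: a JSON string mapping variable -> \{min, max\};
#'   `scaler_from_json`: the reconstructed `scaler`.
#' @export
scaler_to_json <- function(params) {
  stopifnot(inherits(params, "scaler"))
  obj <- lapply(params$variables, function(v) {
    list(min = params$min[[v]], max = params$max[[v]])
  })
  names(obj) <- params$variables
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @rdname scaler_to_json
#' @export
scaler_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  vars <- names(obj)
  structure(list(
    variables = vars,
    min = vapply(obj, function(e) e$min, numeric(1)),
    max = vapply(obj, function(e) e$max, numeric(1))
  ), class = "scaler")
}

#' Random train/test split at replicate-row level
#'
#' Rows are sampled without stratification; the training partition has
#' `round(train_fraction * nrow(table))` rows. With the default fraction 0.75
#' the 576-row expanded dataset splits 432 / 144.
#'
#' @param table data.frame to split.
#' @param train_fraction Proportion in (0, 1); default 0.75.
#' @param seed Optional integer seed (deterministic per seed).
#' @return List with elements `train`, `test` (data.frames) and
#'   `train_indices`, `test_indices` (integer vectors).
#' @export
split_data <- function(table, train_fraction = 0.75, seed = NULL) {
  n <- nrow(table)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("train_fraction ", train_fraction, " yields an empty partition for n = ", n)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(
    train = table[train_idx, , drop = FALSE],
    test = table[test_idx, , drop = FALSE],
    train_indices = train_idx,
    test_indices = test_idx
  )
}
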