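#' Variable importance by remove-and-retrain sensitivity analysis
#'
#' Ranks the regulator inputs for one response. A baseline model is tuned and
#' fitted on `full_table` using all inputs and scored by RMSE on all its rows;
#' then, for each input in turn, the model is re-tuned and refitted from
#' scratch without that input (same grid / seed policy) and scored on the same
#' rows. The variable sensitivity error (VSE) is the reduced model's RMSE and
#' the variable sensitivity ratio (VSR) is VSE divided by the baseline RMSE:
#' the larger the ratio, the more the model depends on that input. Ranks are
#' assigned by descending VSR, ties broken by input order (2,4-D, KIN, SNP).
#'
#' A `mode = "zero"` variant is available for comparison: instead of
#' retraining, the full model is evaluated with the input's column set to
#' zero.
#'
#' @param full_table Replicate-level data.frame (typically all 576 rows).
#' @param target_name One of `"cal"`, `"emb"`, `"num"`.
#' @param model_family `"svr"` or `"mlp"`.
#' @param tuning An [svr_grid()] (for `"svr"`) or [lm_config()] (for `"mlp"`).
#' @param seed Integer seed applied to every tuning/fitting stage.
#' @param mode `"retrain"` (remove the variable and refit) or `"zero"`
#'   (zero-substitute the variable in the full model).
#' @param inputs Input column names (>= 2 required).
#' @return data.frame of class `sensitivity_report`: per input, `vse`,
#'   `baseline_rmse`, `vsr` and `rank`.
#' @export
compute_sensitivity <- function(full_table,
                                target_name = c("cal", "emb", "num"),
                                model_family = c("svr", "mlp"),
                                tuning = NULL, seed = NULL,
                                mode = c("retrain", "zero"),
                                inputs = .input_cols) {
  target_name <- match.arg(target_name)
  model_family <- match.arg(model_family)
  mode <- match.arg(mode)
  if (length(inputs) < 2) stop("sensitivity needs at least 2 inputs")
  ycol <- .response_map$column[.response_map$response == target_name]
  obs <- full_table[[ycol]]

  fit_with <- function(vars) {
    if (model_family == "svr") {
      grid <- if (is.null(tuning)) svr_grid(seed = seed) else tuning
      if (!is.null(seed)) grid$seed <- seed
      tuned <- tune_svr(full_table, target_name, grid = grid, inputs = vars)
      train_svr(full_table, target_name, C = tuned$C, epsilon = tuned$epsilon,
                gamma = tuned$gamma, inputs = vars)
    } else {
      cfg <- if (is.null(tuning)) lm_config() else tuning
      tune_mlp(full_table, target_name, config = cfg, seed = seed,
               inputs = vars)
    }
  }

  baseline <- fit_with(inputs)
  baseline_rmse <- rmse(obs, predict(baseline, full_table[inputs]))
  if (baseline_rmse == 0) {
    stop("baseline RMSE is zero; sensitivity ratio undefined")
  }

  vse <- vapply(inputs, function(v) {
    if (mode == "retrain") {
      kept <- setdiff(inputs, v)
      reduced <- fit_with(kept)
      rmse(obs, predict(reduced, full_table[kept]))
    } else {
      zeroed <- full_table
      zeroed[[v]] <- 0
      rmse(obs, predict(baseline, zeroed[inputs]))
    }
  }, numeric(1))

  vsr <- vse / baseline_rmse
  rank <- integer(length(inputs))
  rank[order(-vsr, seq_along(inputs))] <- seq_along(inputs)
  out <- data.frame(
    input = inputs, vse = vse, baseline_rmse = baseline_rmse,
    vsr = vsr, rank = rank, row.names = NULL
  )
  attr(out, "target") <- target_name
  attr(out, "model_family") <- model_family
  attr(out, "mode") <- mode
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity (%s model, %s mode) for response '%s':\n",
              attr(x, "model_family"), attr(x, "mode"), attr(x, "target")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
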