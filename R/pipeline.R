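#' Configuration of a full study run
#'
#' Collects every knob of the end-to-end workflow: data source, split,
#' model tuning, optimizer settings and the single integer seed from which
#' every stochastic stage derives its own stream.
#'
#' @param data_source `"fixture"` (the bundled treatment table), a path to a
#'   replicate-level CSV, or a [surface_config()] for synthetic data.
#' @param n_reps Replicates per treatment when expanding the fixture.
#' @param train_fraction Train proportion (default 0.75: 432 / 144 rows).
#' @param svr Hyperparameter grid ([svr_grid()]) for the SVR models.
#' @param mlp Training configuration ([lm_config()]) for the MLP models.
#' @param nsga Optimizer configuration ([nsga_config()]).
#' @param refit_full Refit the optimization surrogates on the full table
#'   (train + test recombined) with the tuned hyperparameters before the
#'   NSGA-II stage? If `FALSE` the train-partition models are used.
#' @param sensitivity Run the remove-and-retrain sensitivity stage?
#' @param out_dir Optional directory; when given, the replicate table, the
#'   metrics and sensitivity tables, the Pareto front (all CSV), the JSON
#'   report and a run log are written there.
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data_source = "fixture", n_reps = 9,
                       train_fraction = 0.75,
                       svr = svr_grid(), mlp = lm_config(),
                       nsga = nsga_config(), refit_full = TRUE,
                       sensitivity = TRUE, out_dir = NULL, seed = 1) {
  structure(list(data_source = data_source, n_reps = n_reps,
                 train_fraction = train_fraction, svr = svr, mlp = mlp,
                 nsga = nsga, refit_full = refit_full,
                 sensitivity = sensitivity, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Stage seeds derived from the master seed (kept below 2^31).
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 97 + stage * 1009) %% 2147483647
}

.load_study_data <- function(config) {
  if (inherits(config$data_source, "surface_config")) {
    generate_surface(config$data_source, seed = .stage_seed(config$seed, 1))
  } else if (identical(config$data_source, "fixture")) {
    expand_replicates(load_fixture(), n_reps = config$n_reps,
                      seed = .stage_seed(config$seed, 1))
  } else {
    read_replicate_csv(config$data_source)
  }
}

#' Run the complete modeling and optimization study
#'
#' Executes the full workflow: build the replicate-level table, split it,
#' tune and fit one SVR and one MLP per response, tabulate R-squared / RMSE /
#' MAE on both partitions, rank input importance for each response
#' (remove-and-retrain, SVR family), refit embryogenesis-rate and embryo-count
#' SVR surrogates (by default on the full table) and search the concentration
#' space with NSGA-II, finally reducing the Pareto front to one recommended
#' medium by the ideal-point rule against the best observed responses. Every
#' stage derives its randomness from the single master seed, so a repeated
#' run reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return List of class `study_report`: `data` (the replicate table), `split`,
#'   `models`, `metrics` (a [metrics_report()]), `sensitivity` (list per
#'   response), `optimization` (an `optimization_result`), `tuned` (selected
#'   hyperparameters), and `provenance`.
#' @export
run_study <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say("[%s] seed=%d elapsed=%.1fs", name, config$seed,
        proc.time()[["elapsed"]] - t0)
    out
  }

  data <- stage("data", .load_study_data(config))
  split <- stage("split", split_data(data, config$train_fraction,
                                     seed = .stage_seed(config$seed, 2)))

  responses <- .response_map$response
  tuned <- list()
  svr_models <- list()
  mlp_models <- list()
  for (i in seq_along(responses)) {
    resp <- responses[i]
    tuned[[resp]] <- stage(paste0("tune_svr_", resp), {
      grid <- config$svr
      grid$seed <- .stage_seed(config$seed, 10 + i)
      tune_svr(split$train, resp, grid = grid)
    })
    svr_models[[resp]] <- stage(paste0("fit_svr_", resp), {
      train_svr(split$train, resp, C = tuned[[resp]]$C,
                epsilon = tuned[[resp]]$epsilon, gamma = tuned[[resp]]$gamma)
    })
    mlp_models[[resp]] <- stage(paste0("fit_mlp_", resp), {
      tune_mlp(split$train, resp, config = config$mlp,
               seed = .stage_seed(config$seed, 20 + i))
    })
  }

  metrics <- stage("metrics", metrics_report(
    list(svr = svr_models, mlp = mlp_models),
    list(train = split$train, test = split$test)))

  sens <- NULL
  if (isTRUE(config$sensitivity)) {
    sens <- list()
    for (i in seq_along(responses)) {
      resp <- responses[i]
      sens[[resp]] <- stage(paste0("sensitivity_", resp), {
        compute_sensitivity(data, resp, model_family = "svr",
                            tuning = config$svr,
                            seed = .stage_seed(config$seed, 30 + i))
      })
    }
  }

  surrogate_data <- if (isTRUE(config$refit_full)) data else split$train
  surrogates <- stage("surrogates", {
    lapply(c(emb = "emb", num = "num"), function(resp) {
      train_svr(surrogate_data, resp, C = tuned[[resp]]$C,
                epsilon = tuned[[resp]]$epsilon, gamma = tuned[[resp]]$gamma)
    })
  })

  optimization <- stage("optimize", {
    nsga <- config$nsga
    nsga$seed <- .stage_seed(config$seed, 40)
    front <- nsga2_optimize(
      objectives = list(
        emb = function(X) predict_svr(surrogates$emb, X),
        num = function(X) predict_svr(surrogates$num, X)
      ),
      bounds = pgr_bounds(), config = nsga
    )
    ideal <- observed_ideal(summarize_replicates(data))
    select_ideal_point(front, ideal)
  })

  report <- structure(list(
    data = data, split = split,
    models = list(svr = svr_models, mlp = mlp_models),
    tuned = tuned, metrics = metrics, sensitivity = sens,
    optimization = optimization,
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("seoptim")),
                      config = config)
  ), class = "study_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    write_replicate_csv(data, out("replicates.csv"))
    write.csv(metrics, out("metrics.csv"), row.names = FALSE)
    if (!is.null(sens)) {
      for (resp in names(sens)) {
        write.csv(as.data.frame(sens[[resp]]),
                  out(paste0("sensitivity_", resp, ".csv")), row.names = FALSE)
      }
    }
    write.csv(as.data.frame(optimization$front), out("pareto_front.csv"),
              row.names = FALSE)
    writeLines(report_to_json(report), out("report.json"))
    writeLines(log_lines, out("run_log.txt"))
    say("[artifacts] written to %s", config$out_dir)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report (seed", x$provenance$seed, ")\n\n")
  cat("model performance (natural units):\n")
  print.data.frame(x$metrics, row.names = FALSE, digits = 4)
  if (!is.null(x$sensitivity)) {
    cat("\nsensitivity (VSR, rank):\n")
    for (resp in names(x$sensitivity)) print(x$sensitivity[[resp]])
  }
  cat("\nrecommended medium (ideal-point selection):\n")
  print(x$optimization)
  invisible(x)
}

#' Side-by-side model comparison
#'
#' Reshapes a study's metrics into one row per (response, partition, metric)
#' with the SVR and MLP values side by side and the winner flagged by the
#' greater-R-squared / smaller-error rule (`"tie"` when equal). Partitions
#' evaluated for only one family raise an error.
#'
#' @param report A `study_report` or a [metrics_report()] data.frame.
#' @return data.frame with columns `response`, `partition`, `metric`,
#'   `svr`, `mlp`, `winner`.
#' @export
compare_models <- function(report) {
  metrics <- if (inherits(report, "study_report")) report$metrics else report
  if (!all(c("svr", "mlp") %in% metrics$model)) {
    stop("comparison needs both the svr and mlp families")
  }
  rows <- list()
  for (resp in unique(metrics$response)) {
    for (part in unique(metrics$partition)) {
      s <- metrics[metrics$model == "svr" & metrics$response == resp &
                     metrics$partition == part, ]
      m <- metrics[metrics$model == "mlp" & metrics$response == resp &
                     metrics$partition == part, ]
      for (metric in c("r2", "rmse", "mae")) {
        if (nrow(s) == 0 || nrow(m) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            response = resp, partition = part, metric = metric,
            svr = if (nrow(s)) s[[metric]] else NA_real_,
            mlp = if (nrow(m)) m[[metric]] else NA_real_,
            winner = "absent")
          next
        }
        sv <- s[[metric]]; mv <- m[[metric]]
        winner <- if (sv == mv) "tie"
          else if (metric == "r2") if (sv > mv) "svr" else "mlp"
          else if (sv < mv) "svr" else "mlp"
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, partition = part, metric = metric,
          svr = sv, mlp = mv, winner = winner)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a study report to JSON
#'
#' A compact, timestamp-free JSON rendering (metrics, tuned hyperparameters,
#' sensitivity ratios, the selected optimum and the Pareto front): two runs
#' with the same configuration produce byte-identical documents.
#'
#' @param report A `study_report`.
#' @return JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "study_report"))
  sel <- report$optimization$selected
  obj <- list(
    seed = report$provenance$seed,
    package_version = report$provenance$package_version,
    metrics = report$metrics,
    tuned = lapply(report$tuned, function(t)
      list(C = t$C, epsilon = t$epsilon, gamma = t$gamma,
           cv_rmse = t$cv_rmse)),
    sensitivity = lapply(report$sensitivity, function(s)
      as.data.frame(s)),
    optimum = list(
      decision = as.list(sel[seq_len(3)]),
      objectives = as.list(sel[4:5]),
      ideal = report$optimization$ideal,
      distance = report$optimization$distance
    ),
    pareto_front = as.data.frame(report$optimization$front)
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"))
}
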