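#' @useDynLib seoptim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median predict quantile
#' @importFrom utils read.csv write.csv
NULL

# Column layout shared by every replicate-level table in the package.
.replicate_cols <- c("d24_uM", "kin_uM", "snp_uM", "cal_pct", "emb_pct", "num")
.input_cols <- c("d24_uM", "kin_uM", "snp_uM")
.response_map <- data.frame(
  response = c("cal", "emb", "num"),
  column = c("cal_pct", "emb_pct", "num"),
  mean_col = c("cal_mean", "emb_mean", "num_mean"),
  se_col = c("cal_se", "emb_se", "num_se"),
  lower = c(0, 0, 0),
  upper = c(100, 100, Inf),
  stringsAsFactors = FALSE
)

#' Experimental factor levels of the chrysanthemum media design
#'
#' The 4 x 4 x 4 factorial levels (in micromolar) at which 2,4-D, kinetin and
#' sodium nitroprusside were applied in the bundled dataset.
#'
#' @return Named list of three numeric vectors (`d24_uM`, `kin_uM`, `snp_uM`).
#' @export
factor_levels <- function() {
  list(
    d24_uM = c(0, 4.54, 9.09, 13.63),
    kin_uM = c(0, 4.65, 9.29, 13.94),
    snp_uM = c(0, 10, 20, 40)
  )
}

#' Load the bundled treatment-level dataset
#'
#' Reads the packaged 64-treatment summary of the chrysanthemum somatic
#' embryogenesis experiment: per treatment, the concentrations of the three
#' plant growth regulators and the mean and standard error (n = 9 replicates)
#' of callogenesis rate (%), embryogenesis rate (%) and somatic embryo count
#' per explant.
#'
#' @param path Optional path to a treatment CSV with the same schema;
#'   defaults to the packaged fixture.
#' @return A data.frame with 64 rows and columns `d24_uM`, `kin_uM`, `snp_uM`,
#'   `cal_mean`, `cal_se`, `emb_mean`, `emb_se`, `num_mean`, `num_se`.
#' @examples
#' tr <- load_fixture()
#' nrow(tr)  # 64
#' @export
load_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chrysanthemum_se_treatments.csv",
                        package = "seoptim")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("treatment fixture not found: ", path)
  }
  tr <- read.csv(path, stringsAsFactors = FALSE)
  expected <- c(.input_cols, "cal_mean", "cal_se", "emb_mean", "emb_se",
                "num_mean", "num_se")
  if (!identical(names(tr), expected)) {
    stop("corrupted treatment fixture: unexpected columns ",
         paste(names(tr), collapse = ","))
  }
  .validate_treatments(tr)
  tr
}

.validate_treatments <- function(tr) {
  if (nrow(tr) != 64L) {
    stop("corrupted treatment fixture: expected 64 treatments, found ", nrow(tr))
  }
  lv <- factor_levels()
  for (v in .input_cols) {
    if (!all(tr[[v]] %in% lv[[v]])) {
      stop("corrupted treatment fixture: ", v, " off the designed levels")
    }
  }
  if (anyDuplicated(tr[.input_cols])) {
    stop("corrupted treatment fixture: duplicated treatment combination")
  }
  stat_cols <- setdiff(names(tr), .input_cols)
  vals <- as.matrix(tr[stat_cols])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("corrupted treatment fixture: negative or non-finite statistics")
  }
  if (any(tr$cal_mean > 100) || any(tr$emb_mean > 100)) {
    stop("corrupted treatment fixture: rate mean above 100%")
  }
  invisible(tr)
}

#' Reconstruct replicate-level records from treatment means and SEs
#'
#' For each treatment and response, draws `n_reps` pseudo-random values and
#' affinely standardizes them so that their sample mean equals the printed
#' mean and their sample standard error (sd / sqrt(n)) equals the printed SE,
#' then clips rates to \[0, 100\] and counts to be non-negative. Where
#' clipping binds, exact moment matching is impossible; the achieved
#' deviations are recorded in the `clip_deviations` attribute and summarized
#' in a warning.
#'
#' @param records Treatment-level data.frame as returned by [load_fixture()].
#' @param n_reps Replicates per treatment (>= 2; the experiment used 9).
#' @param seed Optional integer seed; the expansion is deterministic per seed.
#' @return A data.frame with `nrow(records) * n_reps` rows and columns
#'   `d24_uM`, `kin_uM`, `snp_uM`, `rep_index`, `cal_pct`, `emb_pct`, `num`.
#' @examples
#' reps <- expand_replicates(load_fixture(), n_reps = 9, seed = 1)
#' nrow(reps)  # 576
#' @export
expand_replicates <- function(records, n_reps = 9, seed = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2 (standard error undefined below)")
  stat_cols <- unlist(.response_map[c("mean_col", "se_col")])
  if (!all(stat_cols %in% names(records))) {
    stop("records must carry mean and SE columns for all three responses")
  }
  if (any(!is.finite(as.matrix(records[stat_cols])))) {
    stop("non-finite mean/SE in records")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n_tr <- nrow(records)
  out <- data.frame(
    d24_uM = rep(records$d24_uM, each = n_reps),
    kin_uM = rep(records$kin_uM, each = n_reps),
    snp_uM = rep(records$snp_uM, each = n_reps),
    rep_index = rep.int(seq_len(n_reps), n_tr)
  )
  dev <- list()
  for (r in seq_len(nrow(.response_map))) {
    rm <- .response_map[r, ]
    vals <- numeric(n_tr * n_reps)
    for (i in seq_len(n_tr)) {
      mu <- records[[rm$mean_col]][i]
      se <- records[[rm$se_col]][i]
      x <- .moment_matched_draws(n_reps, mu, se)
      xc <- pmin(pmax(x, rm$lower), rm$upper)
      vals[(i - 1L) * n_reps + seq_len(n_reps)] <- xc
      d_mean <- abs(mean(xc) - mu)
      d_se <- abs(sd(xc) / sqrt(n_reps) - se)
      if (d_mean > 1e-9 || d_se > 1e-9) {
        dev[[length(dev) + 1L]] <- data.frame(
          treatment = i, response = rm$response,
          mean_dev = d_mean, se_dev = d_se
        )
      }
    }
    out[[rm$column]] <- vals
  }
  dev <- if (length(dev)) do.call(rbind, dev) else
    data.frame(treatment = integer(), response = character(),
               mean_dev = numeric(), se_dev = numeric())
  attr(out, "clip_deviations") <- dev
  if (nrow(dev)) {
    warning(sprintf(
      "clipping prevented exact moment matching in %d treatment/response cells (max mean deviation %.3g, max SE deviation %.3g)",
      nrow(dev), max(dev$mean_dev), max(dev$se_dev)))
  }
  out
}

# n pseudo-random draws with sample mean mu and sample SE se (sd denominator
# n - 1), before any clipping.
.moment_matched_draws <- function(n, mu, se) {
  if (se == 0) return(rep.int(mu, n))
  z <- rnorm(n)
  # guard against a degenerate draw (sd ~ 0); resample
  while (sd(z) < 1e-12) z <- rnorm(n)
  (z - mean(z)) / sd(z) * (se * sqrt(n)) + mu
}

#' Configuration of the synthetic Gaussian-peak response surface
#'
#' Describes smooth unimodal response surfaces over the three-regulator
#' concentration space, used for parameter-recovery tests: each response is
#' `height * exp(-sum(((x - peak) / width)^2))` plus Gaussian noise, sampled
#' over a full factorial of `factor_levels` with `n_reps` replicates.
#'
#' Defaults mirror the bundled experiment: the design's 4 x 4 x 4 levels with
#' 9 replicates, a peak at the observed optimum region (9.09, 4.65, 20) uM,
#' and peak heights equal to the best observed responses.
#'
#' @param peak_location Numeric 3-vector, peak concentrations (uM).
#' @param widths Numeric 3-vector of strictly positive Gaussian widths (uM).
#' @param peak_heights Named numeric vector of per-response maxima
#'   (`cal`, `emb` in percent, `num` in embryos/explant).
#' @param noise_sd Named non-negative numeric vector of per-response Gaussian
#'   noise standard deviations, in natural response units.
#' @param n_reps Replicates per factorial cell (>= 1).
#' @param levels Named list of three concentration-level vectors.
#' @return An object of class `surface_config`.
#' @export
surface_config <- function(peak_location = c(9.09, 4.65, 20),
                           widths = c(5, 7, 25),
                           peak_heights = c(cal = 100, emb = 100, num = 57.8),
                           noise_sd = c(cal = 5, emb = 5, num = 1),
                           n_reps = 9,
                           levels = factor_levels()) {
  stopifnot(length(peak_location) == 3, length(widths) == 3)
  if (any(widths <= 0)) stop("widths must be strictly positive")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (length(levels) != 3 || any(lengths(levels) == 0)) {
    stop("levels must be three non-empty concentration vectors")
  }
  resp <- .response_map$response
  peak_heights <- peak_heights[resp]
  noise_sd <- noise_sd[resp]
  if (any(is.na(peak_heights)) || any(is.na(noise_sd))) {
    stop("peak_heights and noise_sd must be named for cal, emb and num")
  }
  structure(
    list(peak_location = peak_location, widths = widths,
         peak_heights = peak_heights, noise_sd = noise_sd,
         n_reps = as.integer(n_reps), levels = levels),
    class = "surface_config"
  )
}

#' Noiseless value of the synthetic response surface
#'
#' @param config A [surface_config()].
#' @param x Numeric 3-vector or matrix of concentrations (rows = points).
#' @param response One of `"cal"`, `"emb"`, `"num"`.
#' @return Numeric vector of noiseless (unclipped) response values.
#' @export
surface_truth <- function(config, x, response = c("emb", "num", "cal")) {
  response <- match.arg(response)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- sweep(sweep(x, 2, config$peak_location), 2, config$widths, "/")
  config$peak_heights[[response]] * exp(-rowSums(z^2))
}

#' Generate a synthetic replicate-level dataset
#'
#' Full factorial over the configured levels, `n_reps` replicates per cell;
#' each response is its Gaussian-peak surface value plus iid Gaussian noise,
#' clipped to the valid range (rates to \[0, 100\], counts to >= 0).
#'
#' @param config A [surface_config()].
#' @param seed Optional integer seed (deterministic per seed).
#' @return Replicate-level data.frame with the same schema as
#'   [expand_replicates()].
#' @export
generate_surface <- function(config, seed = NULL) {
  stopifnot(inherits(config, "surface_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- expand.grid(
    d24_uM = config$levels[[1]], kin_uM = config$levels[[2]],
    snp_uM = config$levels[[3]], KEEP.OUT.ATTRS = FALSE
  )
  n_reps <- config$n_reps
  out <- data.frame(
    d24_uM = rep(grid$d24_uM, each = n_reps),
    kin_uM = rep(grid$kin_uM, each = n_reps),
    snp_uM = rep(grid$snp_uM, each = n_reps),
    rep_index = rep.int(seq_len(n_reps), nrow(grid))
  )
  X <- as.matrix(out[.input_cols])
  for (r in seq_len(nrow(.response_map))) {
    rm <- .response_map[r, ]
    mu <- surface_truth(config, X, rm$response)
    y <- mu + rnorm(nrow(X), sd = config$noise_sd[[rm$response]])
    out[[rm$column]] <- pmin(pmax(y, rm$lower), rm$upper)
  }
  out
}

#' Summarize a replicate-level table back to treatment means and SEs
#'
#' Inverse of [expand_replicates()]: per treatment cell, the sample mean and
#' standard error of each response, in the treatment-table schema.
#'
#' @param replicates Replicate-level data.frame.
#' @return Treatment-level data.frame (one row per factor combination).
#' @export
summarize_replicates <- function(replicates) {
  key <- interaction(replicates$d24_uM, replicates$kin_uM, replicates$snp_uM,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(replicates)), key)
  rows <- lapply(idx, function(i) {
    sub <- replicates[i, , drop = FALSE]
    n <- nrow(sub)
    row <- sub[1, .input_cols, drop = FALSE]
    for (r in seq_len(nrow(.response_map))) {
      rm <- .response_map[r, ]
      v <- sub[[rm$column]]
      row[[rm$mean_col]] <- mean(v)
      row[[rm$se_col]] <- sd(v) / sqrt(n)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$snp_uM, out$kin_uM, out$d24_uM), ]
}

#' Read/write replicate-level CSV tables
#'
#' The on-disk dialect is comma-separated, UTF-8, decimal point, with header
#' `d24_uM,kin_uM,snp_uM,cal_pct,emb_pct,num` (the replicate index is not
#' persisted).
#'
#' @param replicates Replicate-level data.frame.
#' @param path File path.
#' @return `read_replicate_csv` returns the table (with a regenerated
#'   `rep_index` column); `write_replicate_csv` returns `path` invisibly.
#' @export
write_replicate_csv <- function(replicates, path) {
  write.csv(replicates[.replicate_cols], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_replicate_csv
#' @export
read_replicate_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(tab), .replicate_cols)) {
    stop("unexpected replicate CSV header: ", paste(names(tab), collapse = ","))
  }
  key <- interaction(tab$d24_uM, tab$kin_uM, tab$snp_uM, drop = TRUE)
  tab$rep_index <- stats::ave(seq_len(nrow(tab)), key, FUN = seq_along)
  tab[c(.input_cols, "rep_index", "cal_pct", "emb_pct", "num")]
}

#' Best observed objective values for ideal-point selection
#'
#' The component-wise maxima, over the treatment table, of mean embryogenesis
#' rate and mean embryo count: the (usually infeasible) ideal point the
#' Pareto-front selection rule measures distances to.
#'
#' @param records Treatment-level data.frame (defaults to the fixture).
#' @return Named numeric vector `c(emb = ..., num = ...)`.
#' @examples
#' observed_ideal()  # c(emb = 100, num = 57.8)
#' @export
observed_ideal <- function(records = load_fixture()) {
  c(emb = max(records$emb_mean), num = max(records$num_mean))
}
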