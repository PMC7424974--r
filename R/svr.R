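#' Gaussian (RBF) kernel
#'
#' `k(x, z) = exp(-gamma * ||x - z||^2)`: 1 at zero distance, symmetric,
#' strictly positive.
#'
#' @param x,z Numeric vectors of equal length (scaled inputs).
#' @param gamma Kernel width parameter, > 0.
#' @return Similarity in (0, 1].
#' @examples
#' rbf_kernel(c(0, 0, 0), c(1, 0, 0), gamma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, z, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (length(x) != length(z)) stop("x and z must have equal length")
  exp(-gamma * sum((x - z)^2))
}

# Squared Euclidean cross-distances, rows of X vs rows of Z.
.sqdist <- function(X, Z) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  pmax(d2, 0)
}

.rbf_matrix <- function(X, Z, gamma) exp(-gamma * .sqdist(X, Z))

#' Fit an epsilon-insensitive support vector regression by its dual
#'
#' Solves the dual quadratic program of epsilon-SVR (box constraints
#' `0 <= alpha_i, alpha*_i <= C`, equality `sum(alpha_i - alpha*_i) = 0`) with
#' a maximal-violating-pair SMO, using the conventional parameterization in
#' which `C` multiplies the summed (not averaged) epsilon-insensitive loss.
#' The bias is recovered from the KKT equalities of free support vectors,
#' averaged; if no free vector exists it is the midpoint of the feasible bias
#' interval (with a warning).
#'
#' `X` and `y` are taken as already scaled; pass `scaler` / `target_scaler`
#' (as from [fit_scaler()]) so that [predict_svr()] can accept and return
#' natural units. [train_svr()] wraps the scaling for data.frame workflows.
#'
#' @param X Numeric matrix of scaled inputs (rows = observations).
#' @param y Numeric vector of scaled targets.
#' @param C Box/penalty parameter, > 0.
#' @param epsilon Insensitivity tube half-width, >= 0 (scaled target units).
#' @param gamma RBF width, > 0.
#' @param scaler,target_scaler Optional [fit_scaler()] objects mapping natural
#'   to scaled units for the inputs / target (identity if `NULL`).
#' @param target_name Optional response identifier (`"cal"`, `"emb"`, `"num"`)
#'   used for range clipping of predictions.
#' @param tol SMO duality-violation tolerance (default 1e-3, the customary
#'   termination criterion for SMO solvers; pass a tighter value when dual
#'   coefficients are needed to high accuracy).
#' @param max_iter Iteration cap for the SMO loop.
#' @return An object of class `svr_model`: support vectors, dual coefficients
#'   `alpha_i - alpha*_i`, bias, hyperparameters, scalers and solver
#'   diagnostics (`n_iter`, `kkt_gap`), plus the full dual solution for
#'   verification.
#' @export
fit_svr <- function(X, y, C, epsilon, gamma,
                    scaler = NULL, target_scaler = NULL, target_name = NULL,
                    tol = 1e-3, max_iter = 5000000L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) < 2) stop("need at least 2 training points")
  if (C <= 0) stop("C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")

  K <- .rbf_matrix(X, X, gamma)
  sol <- smo_solve(K, y, C, epsilon, tol, as.integer(max_iter))
  if (!sol$converged) {
    stop(sprintf("SVR dual solver did not converge: KKT violation %.3g after %d iterations",
                 sol$gap, sol$iterations))
  }
  if (sol$n_free == 0 && any(abs(sol$beta) > 0)) {
    warning("no free support vector; bias set to the midpoint of the feasible interval")
  }
  sv <- which(abs(sol$beta) > 1e-12)
  structure(list(
    sv_x = X[sv, , drop = FALSE],
    dual_coefs = sol$beta[sv],
    bias = sol$b,
    gamma = gamma, C = C, epsilon = epsilon,
    scaler = scaler, target_scaler = target_scaler,
    target_name = target_name,
    n_iter = sol$iterations, kkt_gap = sol$gap,
    dual = list(alpha = sol$alpha, alphastar = sol$alphastar,
                beta = sol$beta, u = sol$u),
    X_train = X, y_train = y
  ), class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("epsilon-SVR (RBF): C = %g, epsilon = %g, gamma = %g\n",
              x$C, x$epsilon, x$gamma))
  cat(sprintf("  %d support vectors of %d training points; bias %.4g\n",
              length(x$dual_coefs), nrow(x$X_train), x$bias))
  if (!is.null(x$target_name)) cat("  target:", x$target_name, "\n")
  invisible(x)
}

#' Predict from a fitted SVR model
#'
#' Evaluates the kernel expansion `sum_i (alpha_i - alpha*_i) k(x, x_i) + b`.
#' Inputs are given in natural units (the model's input scaler is applied
#' internally) and predictions are returned in natural target units. Rates
#' can additionally be clipped to \[0, 100\] and counts to >= 0 via `clip`;
#' the raw (unclipped) values are then attached as attribute `"raw"`.
#'
#' @param model An `svr_model`.
#' @param X data.frame or matrix of inputs in natural units.
#' @param clip Clip predictions to the response's valid range?
#' @return Numeric vector of predictions in natural units.
#' @export
predict_svr <- function(model, X, clip = FALSE) {
  stopifnot(inherits(model, "svr_model"))
  Xs <- .prepare_inputs(X, model$scaler, ncol(model$sv_x))
  yh <- if (length(model$dual_coefs)) {
    drop(.rbf_matrix(Xs, model$sv_x, model$gamma) %*% model$dual_coefs) + model$bias
  } else {
    rep.int(model$bias, nrow(Xs))
  }
  if (!is.null(model$target_scaler)) {
    yh <- invert_scaler(model$target_scaler, yh)
  }
  if (clip) {
    raw <- yh
    yh <- .clip_response(yh, model$target_name)
    attr(yh, "raw") <- raw
  }
  yh
}

#' @export
predict.svr_model <- function(object, newdata, clip = FALSE, ...) {
  predict_svr(object, newdata, clip = clip)
}

.prepare_inputs <- function(X, scaler, p) {
  if (is.data.frame(X)) {
    if (!is.null(scaler)) {
      X <- as.matrix(apply_scaler(scaler, X)[, scaler$variables, drop = FALSE])
    } else {
      X <- as.matrix(X)
    }
  } else {
    X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
    if (!is.null(scaler)) {
      colnames(X) <- scaler$variables
      X <- apply_scaler(scaler, X)
    }
  }
  if (ncol(X) != p) stop("input dimension mismatch: expected ", p, " columns")
  X
}

.clip_response <- function(y, target_name) {
  if (is.null(target_name)) return(y)
  rm <- .response_map[.response_map$response == target_name, ]
  if (nrow(rm) == 0) return(y)
  pmin(pmax(y, rm$lower), rm$upper)
}

#' Per-point KKT residuals of a fitted SVR dual solution
#'
#' For every training point, the violation of the Karush-Kuhn-Tucker
#' optimality conditions of the epsilon-SVR dual at the returned `(alpha,
#' alpha*, b)`: bound points must lie inside the tube, free support vectors
#' exactly on it, and bound-C points on or outside it.
#'
#' @param model An `svr_model`.
#' @return Numeric vector of non-negative residuals (scaled target units).
#' @export
svr_kkt_residuals <- function(model) {
  a <- model$dual$alpha
  as_ <- model$dual$alphastar
  C <- model$C
  eps <- model$epsilon
  f <- drop(.rbf_matrix(model$X_train, model$X_train, model$gamma) %*%
              model$dual$beta) + model$bias
  phi <- model$y_train - f
  tolb <- 1e-8 * C
  res <- numeric(length(phi))
  for (i in seq_along(phi)) {
    r <- 0
    if (a[i] <= tolb && as_[i] <= tolb) {
      r <- max(0, abs(phi[i]) - eps)
    }
    if (a[i] > tolb && a[i] < C - tolb) r <- max(r, abs(phi[i] - eps))
    if (as_[i] > tolb && as_[i] < C - tolb) r <- max(r, abs(phi[i] + eps))
    if (a[i] >= C - tolb) r <- max(r, eps - phi[i], 0)
    if (as_[i] >= C - tolb) r <- max(r, phi[i] + eps, 0)
    r <- max(r, min(a[i], as_[i]))  # complementarity of the pair
    res[i] <- r
  }
  res
}

#' Dual objective of an epsilon-SVR solution
#'
#' `sum(y * beta) - epsilon * sum(|beta|) - 1/2 beta' K beta`, the quantity
#' the SMO solver maximizes.
#'
#' @param model An `svr_model`.
#' @param beta Optional alternative dual vector to evaluate (defaults to the
#'   fitted one).
#' @return Scalar objective value.
#' @export
svr_dual_objective <- function(model, beta = NULL) {
  if (is.null(beta)) beta <- model$dual$beta
  K <- .rbf_matrix(model$X_train, model$X_train, model$gamma)
  sum(model$y_train * beta) - model$epsilon * sum(abs(beta)) -
    0.5 * drop(beta %*% K %*% beta)
}

#' Train an SVR on a replicate-level table
#'
#' Convenience wrapper: fits min-max scalers for the three regulator inputs
#' and the chosen response on `data`, scales, and calls [fit_svr()].
#'
#' @param data Replicate-level data.frame (see [expand_replicates()]).
#' @param target_name One of `"cal"`, `"emb"`, `"num"`.
#' @param C,epsilon,gamma SVR hyperparameters (scaled units for `epsilon`).
#' @param inputs Input column names.
#' @param ... Passed to [fit_svr()].
#' @return An `svr_model` carrying the fitted scalers.
#' @export
train_svr <- function(data, target_name = c("cal", "emb", "num"),
                      C, epsilon, gamma, inputs = .input_cols, ...) {
  target_name <- match.arg(target_name)
  ycol <- .response_map$column[.response_map$response == target_name]
  scaler <- fit_scaler(data, inputs)
  target_scaler <- fit_scaler(data, ycol)
  Xs <- as.matrix(apply_scaler(scaler, data)[, inputs, drop = FALSE])
  ys <- apply_scaler(target_scaler, data)[[ycol]]
  fit_svr(Xs, ys, C = C, epsilon = epsilon, gamma = gamma,
          scaler = scaler, target_scaler = target_scaler,
          target_name = target_name, ...)
}

#' Hyperparameter grid for SVR tuning
#'
#' Default coarse log-grid over the box parameter, tube width (in scaled
#' target units) and RBF width, searched exhaustively by k-fold
#' cross-validation.
#'
#' @param C,epsilon,gamma Candidate values (positive; `epsilon` may be 0).
#' @param k Number of cross-validation folds.
#' @param seed Optional integer seed for the fold assignment.
#' @return An object of class `svr_grid`.
#' @export
svr_grid <- function(C = c(1, 10, 100, 1000),
                     epsilon = c(0.001, 0.01, 0.05, 0.1),
                     gamma = c(0.1, 0.5, 1, 2, 5),
                     k = 5, seed = NULL) {
  if (!length(C) || !length(epsilon) || !length(gamma)) {
    stop("empty hyperparameter grid")
  }
  if (any(C <= 0) || any(gamma <= 0) || any(epsilon < 0)) {
    stop("C and gamma must be positive; epsilon non-negative")
  }
  structure(list(C = C, epsilon = epsilon, gamma = gamma,
                 k = as.integer(k), seed = seed),
            class = "svr_grid")
}

#' Grid-search SVR hyperparameters by cross-validated RMSE
#'
#' Exhaustive search over an [svr_grid()], scoring each candidate triple by
#' mean k-fold cross-validated RMSE in natural target units on the training
#' partition only. Ties are broken toward smaller `C`, then larger `epsilon`,
#' then smaller `gamma` (simpler, smoother models). Deterministic for a fixed
#' grid seed; candidate order does not affect the selection.
#'
#' @param train_table Replicate-level training data.frame.
#' @param target_name One of `"cal"`, `"emb"`, `"num"`.
#' @param grid An [svr_grid()].
#' @param inputs Input column names.
#' @param cv_tol,cv_max_iter Solver tolerance and iteration cap used for the
#'   cross-validation fits only (the final model is refitted at full
#'   tolerance); candidates in degenerate corners of the grid may be scored
#'   from a truncated solve, which does not affect well-fitting candidates.
#' @return List with the selected `C`, `epsilon`, `gamma`, its `cv_rmse`, and
#'   a data.frame `results` of all candidates.
#' @export
tune_svr <- function(train_table, target_name = c("cal", "emb", "num"),
                     grid = svr_grid(), inputs = .input_cols,
                     cv_tol = 1e-3, cv_max_iter = 15000L) {
  target_name <- match.arg(target_name)
  stopifnot(inherits(grid, "svr_grid"))
  ycol <- .response_map$column[.response_map$response == target_name]
  scaler <- fit_scaler(train_table, inputs)
  target_scaler <- fit_scaler(train_table, ycol)
  Xs <- as.matrix(apply_scaler(scaler, train_table)[, inputs, drop = FALSE])
  ys <- apply_scaler(target_scaler, train_table)[[ycol]]
  y_nat <- train_table[[ycol]]
  n <- nrow(Xs)
  if (!is.null(grid$seed)) withr::local_seed(grid$seed)
  fold <- sample(rep_len(seq_len(grid$k), n))

  combos <- expand.grid(C = grid$C, epsilon = grid$epsilon, gamma = grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  sq_err <- matrix(0, nrow(combos), grid$k)
  n_val <- integer(grid$k)
  for (f in seq_len(grid$k)) {
    tr <- fold != f
    D_tr <- .sqdist(Xs[tr, , drop = FALSE], Xs[tr, , drop = FALSE])
    D_cv <- .sqdist(Xs[!tr, , drop = FALSE], Xs[tr, , drop = FALSE])
    n_val[f] <- sum(!tr)
    for (g in grid$gamma) {
      K_tr <- exp(-g * D_tr)
      K_cv <- exp(-g * D_cv)
      for (e in grid$epsilon) {
        a0 <- NULL; as0 <- NULL  # warm start along the ascending C path
        for (Cv in sort(grid$C)) {
          sol <- smo_solve(K_tr, ys[tr], Cv, e, cv_tol, cv_max_iter, a0, as0)
          a0 <- sol$alpha; as0 <- sol$alphastar
          r <- which(combos$C == Cv & combos$epsilon == e & combos$gamma == g)
          pred_s <- drop(K_cv %*% sol$beta) + sol$b
          pred <- invert_scaler(target_scaler, pred_s)
          sq_err[r, f] <- sum((y_nat[!tr] - pred)^2)
        }
      }
    }
  }
  fold_rmse <- sweep(sq_err, 2, n_val, "/")
  combos$cv_rmse <- rowMeans(sqrt(fold_rmse))
  ord <- order(combos$cv_rmse, combos$C, -combos$epsilon, combos$gamma)
  best <- combos[ord[1], ]
  list(C = best$C, epsilon = best$epsilon, gamma = best$gamma,
       cv_rmse = best$cv_rmse, results = combos)
}

#' Serialize an SVR model to JSON
#'
#' @param model An `svr_model`.
#' @return JSON string with hyperparameters, scalers, support-vector
#'   coordinates, dual coefficients and bias.
#' @export
svr_to_json <- function(model) {
  stopifnot(inherits(model, "svr_model"))
  obj <- list(
    C = model$C, epsilon = model$epsilon, gamma = model$gamma,
    bias = model$bias, target = model$target_name,
    support_vectors = model$sv_x, dual_coefs = model$dual_coefs,
    input_scaler = if (!is.null(model$scaler))
      jsonlite::fromJSON(scaler_to_json(model$scaler)),
    target_scaler = if (!is.null(model$target_scaler))
      jsonlite::fromJSON(scaler_to_json(model$target_scaler))
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
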