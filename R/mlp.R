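#' Levenberg-Marquardt training configuration
#'
#' Settings for the three-layer perceptron trained on the sum-of-squared-error
#' objective: damping schedule, stopping rules, validation hold-out for early
#' stopping, and candidate hidden-layer sizes for [tune_mlp()].
#'
#' @param max_epochs Maximum accepted LM steps.
#' @param mu0 Initial damping parameter.
#' @param mu_inc Damping multiplier on a rejected step (> 1).
#' @param mu_dec Damping multiplier on an accepted step (< 1).
#' @param mu_max Damping bound; training stops if exceeded.
#' @param grad_tol Stop when the max absolute gradient falls below this.
#' @param val_fraction Fraction of training rows held out for early stopping.
#' @param patience Accepted steps without validation improvement tolerated.
#' @param hidden_candidates Hidden-layer sizes tried by [tune_mlp()].
#' @return An object of class `lm_config`.
#' @export
lm_config <- function(max_epochs = 1000, mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1,
                      mu_max = 1e10, grad_tol = 1e-7, val_fraction = 0.15,
                      patience = 12, hidden_candidates = c(3, 5, 8, 12, 15)) {
  if (mu_inc <= 1 || mu_dec >= 1 || mu_dec <= 0) {
    stop("damping factors must satisfy mu_inc > 1 and 0 < mu_dec < 1")
  }
  if (grad_tol <= 0 || mu0 <= 0) stop("tolerances and mu0 must be > 0")
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must be in [0, 1)")
  structure(list(max_epochs = as.integer(max_epochs), mu0 = mu0,
                 mu_inc = mu_inc, mu_dec = mu_dec, mu_max = mu_max,
                 grad_tol = grad_tol, val_fraction = val_fraction,
                 patience = as.integer(patience),
                 hidden_candidates = as.integer(hidden_candidates)),
            class = "lm_config")
}

# Pack/unpack weights <-> flat parameter vector.
.mlp_unpack <- function(theta, p, h) {
  list(
    W1 = matrix(theta[seq_len(p * h)], nrow = p, ncol = h),
    b1 = theta[p * h + seq_len(h)],
    w2 = theta[p * h + h + seq_len(h)],
    b2 = theta[p * h + 2 * h + 1]
  )
}

.mlp_pack <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)

# Forward pass in scaled units. X: n x p matrix.
.mlp_eval <- function(w, X) {
  Z <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  drop(Z %*% w$w2) + w$b2
}

# Jacobian of predictions wrt the flat parameter vector (n x n_par),
# by backpropagation through the tanh hidden layer.
.mlp_jacobian <- function(w, X) {
  n <- nrow(X); p <- ncol(X); h <- length(w$b1)
  Z <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  D <- (1 - Z^2) * matrix(w$w2, n, h, byrow = TRUE)  # d yhat / d a_k
  J <- matrix(0, n, p * h + 2 * h + 1)
  for (k in seq_len(h)) {
    J[, (k - 1) * p + seq_len(p)] <- D[, k] * X  # W1[, k]
  }
  J[, p * h + seq_len(h)] <- D          # b1
  J[, p * h + h + seq_len(h)] <- Z      # w2
  J[, p * h + 2 * h + 1] <- 1           # b2
  J
}

#' Forward pass of a fitted perceptron
#'
#' `output = w2' tanh(W1' x + b1) + b2` on scaled inputs, mapped back to
#' natural target units via the model's scalers.
#'
#' @param model An `mlp_model`.
#' @param X data.frame or matrix of inputs in natural units.
#' @param clip Clip predictions to the response's valid range?
#' @return Numeric vector of predictions in natural units.
#' @export
mlp_forward <- function(model, X, clip = FALSE) {
  stopifnot(inherits(model, "mlp_model"))
  Xs <- .prepare_inputs(X, model$scaler, nrow(model$weights$W1))
  yh <- .mlp_eval(model$weights, Xs)
  if (!is.null(model$target_scaler)) yh <- invert_scaler(model$target_scaler, yh)
  if (clip) yh <- .clip_response(yh, model$target_name)
  yh
}

#' @export
predict.mlp_model <- function(object, newdata, clip = FALSE, ...) {
  mlp_forward(object, newdata, clip = clip)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("3-layer perceptron: %d-%d-1 (tanh / identity), LM-trained\n",
              nrow(x$weights$W1), length(x$weights$b1)))
  if (!is.null(x$target_name)) cat("  target:", x$target_name, "\n")
  cat(sprintf("  epochs accepted: %d; train RMSE (scaled): %.4g\n",
              x$epochs, x$train_rmse_scaled))
  invisible(x)
}

# Seeded fan-in-scaled uniform initialization.
.mlp_init <- function(p, h) {
  list(
    W1 = matrix(runif(p * h, -0.5, 0.5) / sqrt(p), p, h),
    b1 = runif(h, -0.5, 0.5) / sqrt(p),
    w2 = runif(h, -0.5, 0.5) / sqrt(h),
    b2 = runif(1, -0.5, 0.5) / sqrt(h)
  )
}

# Core LM loop on scaled data. Returns weights, accepted-epoch count and
# training trace. Xv/yv may be NULL (no early stopping).
.mlp_train_lm <- function(X, y, hidden, config, Xv = NULL, yv = NULL) {
  p <- ncol(X)
  w <- .mlp_init(p, hidden)
  theta <- .mlp_pack(w)
  n_par <- length(theta)
  sse <- function(th) {
    r <- y - .mlp_eval(.mlp_unpack(th, p, hidden), X)
    sum(r^2)
  }
  cur_sse <- sse(theta)
  if (!is.finite(cur_sse)) stop("non-finite loss at initialization")
  sse_trace <- cur_sse
  mu <- config$mu0
  best_val <- Inf
  best_theta <- theta
  stall <- 0L
  epochs <- 0L
  val_rmse <- function(th) {
    if (is.null(Xv) || nrow(Xv) == 0) return(NA_real_)
    sqrt(mean((yv - .mlp_eval(.mlp_unpack(th, p, hidden), Xv))^2))
  }
  if (!is.null(Xv)) best_val <- val_rmse(theta)

  for (epoch in seq_len(config$max_epochs)) {
    w <- .mlp_unpack(theta, p, hidden)
    r <- y - .mlp_eval(w, X)
    J <- .mlp_jacobian(w, X)
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < config$grad_tol) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      A <- JtJ + diag(mu, n_par)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + delta
        cand_sse <- sse(cand)
        if (is.finite(cand_sse) && cand_sse <= cur_sse) {
          theta <- cand
          cur_sse <- cand_sse
          mu <- max(mu * config$mu_dec, 1e-12)
          accepted <- TRUE
          epochs <- epoch
          sse_trace <- c(sse_trace, cur_sse)
        }
      }
      if (!accepted) {
        mu <- mu * config$mu_inc
        if (mu > config$mu_max) break
      }
    }
    if (!accepted) break  # damping exhausted: stationary within tolerance
    if (!is.null(Xv)) {
      v <- val_rmse(theta)
      if (v < best_val - 1e-12) {
        best_val <- v
        best_theta <- theta
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    } else {
      best_theta <- theta
    }
  }
  if (is.null(Xv)) best_theta <- theta
  list(theta = best_theta, epochs = epochs,
       train_rmse_scaled = sqrt(sse(best_theta) / length(y)),
       val_rmse_scaled = if (is.null(Xv)) NA_real_ else best_val,
       sse_trace = sse_trace)
}

#' Fit a three-layer perceptron with Levenberg-Marquardt
#'
#' One tanh hidden layer, identity output, trained by damped Gauss-Newton
#' steps `delta = (J'J + mu I)^{-1} J' e` on the sum-of-squared-error
#' objective with an analytic backpropagation Jacobian. The damping `mu`
#' shrinks on accepted steps and grows on rejected ones; training stops on the
#' epoch budget, a vanishing gradient, exhausted damping, or a run of
#' non-improving validation errors (the best-validation weights are kept).
#'
#' @param data Replicate-level data.frame.
#' @param target_name One of `"cal"`, `"emb"`, `"num"`.
#' @param hidden Hidden-layer size (>= 1).
#' @param config An [lm_config()].
#' @param seed Optional integer seed (weight init and validation split).
#' @param inputs Input column names.
#' @return An object of class `mlp_model`.
#' @export
fit_mlp <- function(data, target_name = c("cal", "emb", "num"), hidden = 8,
                    config = lm_config(), seed = NULL, inputs = .input_cols) {
  target_name <- match.arg(target_name)
  stopifnot(inherits(config, "lm_config"))
  if (nrow(data) < 10) stop("need at least 10 training rows")
  if (hidden < 1) stop("hidden size must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)

  ycol <- .response_map$column[.response_map$response == target_name]
  scaler <- fit_scaler(data, inputs)
  target_scaler <- fit_scaler(data, ycol)
  Xs <- as.matrix(apply_scaler(scaler, data)[, inputs, drop = FALSE])
  ys <- apply_scaler(target_scaler, data)[[ycol]]

  n <- nrow(Xs)
  n_val <- floor(config$val_fraction * n)
  if (n_val > 0) {
    vi <- sample.int(n, n_val)
    Xv <- Xs[vi, , drop = FALSE]; yv <- ys[vi]
    Xt <- Xs[-vi, , drop = FALSE]; yt <- ys[-vi]
  } else {
    Xv <- NULL; yv <- NULL; Xt <- Xs; yt <- ys
  }
  fit <- .mlp_train_lm(Xt, yt, hidden, config, Xv, yv)
  out <- structure(list(
    weights = .mlp_unpack(fit$theta, ncol(Xs), hidden),
    hidden = as.integer(hidden),
    scaler = scaler, target_scaler = target_scaler,
    target_name = target_name,
    epochs = fit$epochs,
    train_rmse_scaled = fit$train_rmse_scaled,
    val_rmse_scaled = fit$val_rmse_scaled
  ), class = "mlp_model")
  attr(out, "sse_trace") <- fit$sse_trace
  out
}

#' Select the hidden-layer size by validation error
#'
#' Fits one perceptron per candidate hidden size on `data` (each with its own
#' seeded validation carve-out), keeps the size with the smallest validation
#' RMSE (ties toward the smaller network), and refits on all rows of `data`.
#' Deterministic for a fixed seed.
#'
#' @inheritParams fit_mlp
#' @return The selected, refitted `mlp_model`.
#' @export
tune_mlp <- function(data, target_name = c("cal", "emb", "num"),
                     config = lm_config(), seed = NULL, inputs = .input_cols) {
  target_name <- match.arg(target_name)
  cands <- config$hidden_candidates
  if (!length(cands)) stop("no hidden-size candidates")
  if (!is.null(seed)) withr::local_seed(seed)
  scores <- vapply(cands, function(h) {
    m <- fit_mlp(data, target_name, hidden = h, config = config,
                 seed = NULL, inputs = inputs)
    if (is.na(m$val_rmse_scaled)) m$train_rmse_scaled else m$val_rmse_scaled
  }, numeric(1))
  best <- cands[order(scores, cands)][1]
  fit_mlp(data, target_name, hidden = best, config = config,
          seed = NULL, inputs = inputs)
}

#' Serialize an MLP model to JSON
#'
#' @param model An `mlp_model`.
#' @return JSON string with the architecture, flattened weights and scalers.
#' @export
mlp_to_json <- function(model) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    hidden = model$hidden,
    target = model$target_name,
    W1 = model$weights$W1, b1 = model$weights$b1,
    w2 = model$weights$w2, b2 = model$weights$b2,
    input_scaler = jsonlite::fromJSON(scaler_to_json(model$scaler)),
    target_scaler = jsonlite::fromJSON(scaler_to_json(model$target_scaler))
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
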