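test_that("RBF kernel has unit diagonal, symmetry and the closed form", {
  x <- c(0.2, 0.5, 0.9); z <- c(0.1, 0.4, 0.3)
  expect_equal(rbf_kernel(x, x, gamma = 2), 1)
  expect_equal(rbf_kernel(x, z, 3), rbf_kernel(z, x, 3))
  expect_equal(rbf_kernel(c(0, 0, 0), c(1, 0, 0), 1), exp(-1))
  expect_error(rbf_kernel(x, z, 0), "gamma")
  expect_error(rbf_kernel(x, z[1:2], 1), "length")
})

test_that("constant targets give a zero dual and a flat prediction", {
  X <- matrix(runif(15, 0, 1), 5, 3)
  m <- fit_svr(X, rep(0.4, 5), C = 10, epsilon = 0.1, gamma = 1)
  expect_equal(length(m$dual_coefs), 0L)
  expect_equal(m$bias, 0.4)
  expect_equal(predict_svr(m, matrix(runif(9), 3, 3)), rep(0.4, 3))
})

test_that("training points stay inside the epsilon tube at large C", {
  prob <- toy_svr_problem(n = 10, seed = 3)
  m <- fit_svr(prob$X, prob$y, C = 1e4, epsilon = 0.1, gamma = 1, tol = 1e-8)
  pred <- predict_svr(m, prob$X)
  expect_true(all(abs(pred - prob$y) <= 0.1 + 1e-6))
})

test_that("SMO dual coefficients match an interior-point QP oracle", {
  skip_if_not_installed("kernlab")
  # fixed 4-point problem
  X4 <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.5, 0.5, 0.5), 4, 3, byrow = TRUE)
  y4 <- c(0.1, 0.9, 0.4, 0.6)
  m4 <- fit_svr(X4, y4, C = 5, epsilon = 0.05, gamma = 1, tol = 1e-9)
  ref4 <- qp_reference_beta(X4, y4, C = 5, eps = 0.05, gamma = 1)
  expect_lt(max(abs(m4$dual$beta - ref4)), 1e-5)
  # random problems with <= 10 points
  for (seed in 1:5) {
    prob <- toy_svr_problem(n = 4 + seed, seed = seed)
    C <- c(1, 10, 50, 3, 20)[seed]
    eps <- c(0.01, 0.05, 0.1, 0.02, 0.05)[seed]
    g <- c(0.5, 1, 2, 1, 0.7)[seed]
    m <- fit_svr(prob$X, prob$y, C, eps, g, tol = 1e-9)
    ref <- qp_reference_beta(prob$X, prob$y, C, eps, g)
    expect_lt(max(abs(m$dual$beta - ref)), 1e-5)
  }
})

test_that("returned solutions satisfy the KKT conditions", {
  prob <- toy_svr_problem(n = 30, seed = 11)
  for (C in c(1, 100)) {
    m <- fit_svr(prob$X, prob$y, C = C, epsilon = 0.05, gamma = 1.5,
                 tol = 1e-7)
    expect_lt(max(svr_kkt_residuals(m)), 1e-5)
    expect_lt(abs(sum(m$dual$beta)), 1e-6)
    expect_true(all(m$dual$alpha >= 0 & m$dual$alpha <= C))
    expect_true(all(m$dual$alphastar >= 0 & m$dual$alphastar <= C))
  }
  # on a replicate-level subset of the real data
  tab <- expanded_fixture()[seq(1, 576, by = 5), ]
  m <- train_svr(tab, "emb", C = 100, epsilon = 0.01, gamma = 2, tol = 1e-7)
  expect_lt(max(svr_kkt_residuals(m)), 1e-5)
})

test_that("the fitted dual beats 1000 random feasible points", {
  prob <- toy_svr_problem(n = 12, seed = 5)
  C <- 10
  m <- fit_svr(prob$X, prob$y, C = C, epsilon = 0.05, gamma = 1)
  obj_fit <- svr_dual_objective(m)
  withr::with_seed(1, {
    worst <- -Inf
    for (i in 1:1000) {
      b <- project_feasible_beta(runif(12, -C, C), C)
      expect_lte(abs(sum(b)), 1e-9)
      worst <- max(worst, svr_dual_objective(m, b))
    }
    expect_gte(obj_fit, worst - 1e-8)
  })
})

test_that("widening the tube never adds support vectors", {
  prob <- toy_svr_problem(n = 40, seed = 13)
  n_sv <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.2), function(eps) {
    m <- fit_svr(prob$X, prob$y, C = 10, epsilon = eps, gamma = 1, tol = 1e-8)
    length(m$dual_coefs)
  }, numeric(1))
  expect_true(all(diff(n_sv) <= 0))
})

test_that("prediction equals the hand-evaluated kernel expansion", {
  prob <- toy_svr_problem(n = 4, seed = 2)
  m <- fit_svr(prob$X, prob$y, C = 5, epsilon = 0.02, gamma = 1.2)
  xnew <- c(0.3, 0.7, 0.1)
  by_hand <- sum(vapply(seq_len(nrow(m$sv_x)), function(i) {
    m$dual_coefs[i] * rbf_kernel(xnew, m$sv_x[i, ], 1.2)
  }, numeric(1))) + m$bias
  expect_equal(predict_svr(m, matrix(xnew, 1)), by_hand)
  expect_error(predict_svr(m, matrix(0.5, 1, 2)), "dimension mismatch")
})

test_that("predictions agree with an independent SVR implementation", {
  skip_if_not_installed("e1071")
  prob <- toy_svr_problem(n = 25, seed = 8)
  m <- fit_svr(prob$X, prob$y, C = 10, epsilon = 0.05, gamma = 1, tol = 1e-8)
  ref <- e1071::svm(prob$X, prob$y, type = "eps-regression", kernel = "radial",
                    gamma = 1, cost = 10, epsilon = 0.05, scale = FALSE,
                    tolerance = 1e-6)
  Xnew <- matrix(runif(30), 10, 3)
  expect_lt(max(abs(predict_svr(m, Xnew) - predict(ref, Xnew))), 1e-3)
})

test_that("train_svr predicts in natural units and clips on request", {
  tab <- expanded_fixture()
  m <- train_svr(tab, "emb", C = 100, epsilon = 0.01, gamma = 2)
  pred <- predict_svr(m, tab[c("d24_uM", "kin_uM", "snp_uM")])
  expect_gt(max(pred), 50)  # natural percent scale, not [0, 1]
  clipped <- predict_svr(m, tab[c("d24_uM", "kin_uM", "snp_uM")], clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 100))
  expect_equal(attr(clipped, "raw"), pred)
})

test_that("grid tuning is exhaustive, deterministic and order-invariant", {
  tab <- expanded_fixture()[seq(1, 576, by = 4), ]
  single <- svr_grid(C = 10, epsilon = 0.05, gamma = 1, k = 3, seed = 1)
  t1 <- tune_svr(tab, "num", grid = single)
  expect_equal(t1[c("C", "epsilon", "gamma")],
               list(C = 10, epsilon = 0.05, gamma = 1))
  g1 <- small_grid(seed = 7)
  g2 <- small_grid(seed = 7)
  g2$C <- rev(g2$C); g2$gamma <- rev(g2$gamma)
  t2 <- tune_svr(tab, "num", grid = g1)
  t3 <- tune_svr(tab, "num", grid = g2)
  expect_equal(t2[c("C", "epsilon", "gamma", "cv_rmse")],
               t3[c("C", "epsilon", "gamma", "cv_rmse")])
  expect_error(svr_grid(C = numeric(0)), "empty")
})

test_that("tuned SVR recovers a noiseless synthetic surface", {
  cfg <- surface_config(noise_sd = c(cal = 0, emb = 0, num = 0), n_reps = 2)
  tab <- generate_surface(cfg, seed = 21)
  sp <- split_data(tab, 0.75, seed = 22)
  tuned <- tune_svr(sp$train, "emb", grid = svr_grid(seed = 23))
  m <- train_svr(sp$train, "emb", C = tuned$C, epsilon = tuned$epsilon,
                 gamma = tuned$gamma)
  expect_gte(evaluate_model(m, sp$train)$r2, 0.99)
})
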