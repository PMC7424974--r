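# Brute-force dominance reference used by the sorting oracle test.
brute_fronts <- function(P) {
  n <- nrow(P)
  dominates <- function(i, j) all(P[i, ] >= P[j, ]) && any(P[i, ] > P[j, ])
  rank <- rep(NA_integer_, n)
  level <- 0L
  while (anyNA(rank)) {
    alive <- which(is.na(rank))
    for (i in alive) {
      if (!any(vapply(setdiff(alive, i), function(j) dominates(j, i),
                      logical(1)))) {
        rank[i] <- level
      }
    }
    level <- level + 1L
  }
  lapply(seq_len(max(rank) + 1L) - 1L, function(l) which(rank == l))
}

test_that("non-dominated sorting handles the textbook cases", {
  P <- rbind(c(2, 2), c(0, 3), c(1, 1))
  fr <- fast_nondominated_sort(P)
  expect_equal(fr, list(c(1L, 2L), 3L))
  expect_equal(fast_nondominated_sort(rbind(c(1, 5))), list(1L))
  same <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(fast_nondominated_sort(same), list(1:3))
  expect_equal(fast_nondominated_sort(matrix(numeric(0), 0, 2)), list())
  # minimization flips dominance: (1,1) beats (2,2), (0,3) stays incomparable
  expect_equal(fast_nondominated_sort(P, sense = "min")[[1]], c(2L, 3L))
})

test_that("sorting agrees with the brute-force dominance oracle", {
  withr::with_seed(314, {
    for (i in 1:200) {
      n <- sample(2:50, 1)
      M <- sample(2:3, 1)
      P <- matrix(sample(0:8, n * M, replace = TRUE), n, M)
      expect_identical(fast_nondominated_sort(P), brute_fronts(P))
    }
  })
})

test_that("crowding distance follows the boundary and interior rules", {
  expect_equal(crowding_distance(rbind(c(1, 2))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  three <- rbind(c(0, 0), c(1, 1), c(2, 2))  # evenly spaced, collinear
  expect_equal(crowding_distance(three), c(Inf, 2, Inf))
  # permutations change only the order, not the multiset
  front <- rbind(c(0, 5), c(1, 4), c(2, 2.5), c(3, 0))
  d1 <- crowding_distance(front)
  perm <- c(3, 1, 4, 2)
  d2 <- crowding_distance(front[perm, ])
  expect_equal(sort(d2), sort(d1))
  expect_equal(d2, d1[perm])
  # a zero-range objective contributes nothing
  flat <- cbind(c(0, 1, 2), c(7, 7, 7))
  expect_equal(crowding_distance(flat), c(Inf, 1, Inf))
  expect_error(crowding_distance(flat[0, ]), "empty")
})

test_that("a no-trade-off problem collapses onto the shared maximum", {
  cfg <- nsga_config(pop_size = 20, generations = 40, seed = 1)
  front <- nsga2_optimize(
    list(f1 = function(X) X[, 1], f2 = function(X) X[, 1]),
    bounds = list(lower = 0, upper = 1), config = cfg)
  expect_true(all(front$f1 > 0.99))
})

test_that("a total trade-off yields a spread, mutually non-dominated front", {
  cfg <- nsga_config(pop_size = 40, generations = 40, seed = 2)
  front <- nsga2_optimize(
    list(f1 = function(X) X[, 1], f2 = function(X) 1 - X[, 1]),
    bounds = list(lower = 0, upper = 1), config = cfg)
  expect_gt(nrow(front), 5)
  expect_gt(max(front$f1), 0.9)
  expect_gt(max(front$f2), 0.9)
  F <- as.matrix(front[c("f1", "f2")])
  expect_equal(fast_nondominated_sort(F), list(seq_len(nrow(front))))
  expect_true(all(front$x1 >= 0 & front$x1 <= 1))
})

test_that("the returned front approximates a known circular front", {
  # decisions in [0,1]^2 projected onto the unit disk: the Pareto front of
  # (f1, f2) is the quarter circle a^2 + b^2 = 1
  proj <- function(X) pmax(1, sqrt(rowSums(X^2)))
  cfg <- nsga_config(pop_size = 100, generations = 200, seed = 3)
  front <- nsga2_optimize(
    list(f1 = function(X) X[, 1] / proj(X), f2 = function(X) X[, 2] / proj(X)),
    bounds = list(lower = c(0, 0), upper = c(1, 1)), config = cfg)
  radii <- sqrt(front$f1^2 + front$f2^2)
  expect_lt(mean(abs(radii - 1)), 0.02)
})

test_that("elitism keeps per-objective bests non-decreasing", {
  cfg <- nsga_config(pop_size = 30, generations = 60, seed = 4)
  front <- nsga2_optimize(
    list(f1 = function(X) -(X[, 1] - 3)^2, f2 = function(X) -(X[, 1] - 7)^2),
    bounds = list(lower = 0, upper = 10), config = cfg)
  trace <- attr(front, "elite_trace")
  expect_true(all(diff(trace[, 1]) >= -1e-12))
  expect_true(all(diff(trace[, 2]) >= -1e-12))
})

test_that("runs are deterministic per seed and reject bad objectives", {
  cfg <- nsga_config(pop_size = 12, generations = 8, seed = 5)
  objs <- list(f1 = function(X) X[, 1], f2 = function(X) -X[, 1]^2)
  f1 <- nsga2_optimize(objs, list(lower = 0, upper = 2), cfg)
  f2 <- nsga2_optimize(objs, list(lower = 0, upper = 2), cfg)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  expect_error(
    nsga2_optimize(list(function(X) rep(NaN, nrow(X)),
                        function(X) X[, 1]),
                   list(lower = 0, upper = 1), cfg),
    "non-finite")
  expect_error(nsga_config(pop_size = 7), "even")
  expect_error(nsga_config(crossover_rate = 1.2), "rates")
})

test_that("ideal-point selection minimizes the published distance form", {
  front <- data.frame(d24 = c(9.1, 5.0), kin = c(4.7, 2.0),
                      snp = c(18.7, 10.0),
                      emb = c(99.09, 90.0), num = c(56.23, 57.0),
                      rank = 0L, crowding = c(Inf, Inf))
  res <- select_ideal_point(front, c(100, 57.80),
                            objective_cols = c("emb", "num"))
  expect_equal(res$distance, sqrt(0.91^2 + 1.57^2))
  expect_equal(res$selected$emb, 99.09)
  # an exact ideal member is selected with zero distance
  front2 <- rbind(front, data.frame(d24 = 9.09, kin = 4.65, snp = 20,
                                    emb = 100, num = 57.80, rank = 0L,
                                    crowding = Inf))
  res2 <- select_ideal_point(front2, c(100, 57.80),
                             objective_cols = c("emb", "num"))
  expect_equal(res2$distance, 0)
  # ties break toward the lower first decision value
  front3 <- data.frame(d24 = c(12, 6), kin = c(1, 1), snp = c(5, 5),
                       emb = c(99, 101), num = c(57.8, 57.8),
                       rank = 0L, crowding = Inf)
  res3 <- select_ideal_point(front3, c(100, 57.8),
                             objective_cols = c("emb", "num"))
  expect_equal(res3$selected$d24, 6)
})

test_that("the optimizer recovers the peak of an analytic surface", {
  cfg_s <- surface_config(peak_location = c(8, 6, 22),
                          noise_sd = c(cal = 0, emb = 0, num = 0))
  objs <- list(
    emb = function(X) surface_truth(cfg_s, X, "emb"),
    num = function(X) surface_truth(cfg_s, X, "num")
  )
  cfg <- nsga_config(pop_size = 60, generations = 80, seed = 6)
  front <- nsga2_optimize(objs, pgr_bounds(), cfg)
  ideal <- c(cfg_s$peak_heights[["emb"]], cfg_s$peak_heights[["num"]])
  res <- select_ideal_point(front, ideal)
  sel <- as.numeric(res$selected[1:3])
  expect_true(all(abs(sel - cfg_s$peak_location) < 0.5))
})
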