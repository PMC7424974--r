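#' Fast non-dominated sorting
#'
#' Partitions a set of objective vectors into Pareto fronts. Under
#' `sense = "max"`, point a dominates point b iff a is at least as good as b
#' in every objective and strictly better in at least one; equal vectors do
#' not dominate each other.
#'
#' @param points Numeric matrix (rows = points, columns = objectives) or
#'   data.frame.
#' @param sense `"max"` or `"min"`.
#' @return List of integer vectors: row indices of front 0, front 1, ...
#'   (empty list for empty input).
#' @export
fast_nondominated_sort <- function(points, sense = c("max", "min")) {
  sense <- match.arg(sense)
  P <- as.matrix(points)
  n <- nrow(P)
  if (n == 0) return(list())
  if (sense == "min") P <- -P
  r <- nds_rank(P)
  unname(split(seq_len(n), factor(r, levels = sort(unique(r)))))
}

#' Crowding distance of a Pareto front
#'
#' Per objective the front is sorted; the two boundary points receive
#' `+Inf` and each interior point the gap between its neighbours divided by
#' the objective's range (zero-range objectives contribute nothing). The per-
#' objective contributions are summed.
#'
#' @param front Numeric matrix (rows = points of one front) or data.frame.
#' @return Numeric vector of crowding distances, in the input row order.
#' @export
crowding_distance <- function(front) {
  P <- as.matrix(front)
  m <- nrow(P)
  if (m == 0) stop("empty front")
  if (m <= 2) return(rep(Inf, m))
  d <- numeric(m)
  for (j in seq_len(ncol(P))) {
    f <- P[, j]
    ord <- order(f)
    d[ord[c(1, m)]] <- Inf
    rng <- f[ord[m]] - f[ord[1]]
    if (rng > 0) {
      interior <- ord[2:(m - 1)]
      d[interior] <- d[interior] + (f[ord[3:m]] - f[ord[1:(m - 2)]]) / rng
    }
  }
  d
}

#' NSGA-II run configuration
#'
#' @param pop_size Population size (even, >= 4).
#' @param generations Number of generations.
#' @param crossover_rate Per-pair probability of simulated binary crossover.
#' @param mutation_rate Per-gene probability of polynomial mutation.
#' @param selection Parent selection scheme: `"roulette"` (wheel over fitness
#'   `1 / (1 + rank)`) or `"tournament"` (crowded binary tournament).
#' @param eta_c,eta_m SBX and polynomial-mutation distribution indices.
#' @param seed Optional integer seed.
#' @return An object of class `nsga_config`.
#' @export
nsga_config <- function(pop_size = 200, generations = 1000,
                        crossover_rate = 0.7, mutation_rate = 0.5,
                        selection = c("roulette", "tournament"),
                        eta_c = 20, eta_m = 20, seed = NULL) {
  selection <- match.arg(selection)
  if (pop_size < 4 || pop_size %% 2 != 0) stop("pop_size must be even and >= 4")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 selection = selection, eta_c = eta_c, eta_m = eta_m,
                 seed = seed),
            class = "nsga_config")
}

#' Decision bounds of the experimental design region
#'
#' Default search box for the optimizer: the ranges of the three regulator
#' concentrations spanned by the experiment. Surrogates are not trusted
#' outside the region they were fitted on.
#'
#' @return List with numeric vectors `lower` and `upper` named by input.
#' @export
pgr_bounds <- function() {
  lv <- factor_levels()
  list(lower = vapply(lv, min, numeric(1)),
       upper = vapply(lv, max, numeric(1)))
}

# Bounded simulated binary crossover, vectorized over a population of
# consecutive parent pairs. Each selected pair recombines each gene with
# probability 1/2; children are clipped to the bounds.
.sbx_population <- function(P, lower, upper, eta, crossover_rate) {
  n <- nrow(P); p <- ncol(P); n2 <- n %/% 2
  odd <- seq(1, n, by = 2); even <- seq(2, n, by = 2)
  P1 <- P[odd, , drop = FALSE]; P2 <- P[even, , drop = FALSE]
  L <- matrix(lower, n2, p, byrow = TRUE)
  U <- matrix(upper, n2, p, byrow = TRUE)
  on <- (runif(n2) < crossover_rate) &
    matrix(runif(n2 * p) < 0.5, n2, p)
  y1 <- pmin(P1, P2); y2 <- pmax(P1, P2)
  on <- on & (y2 - y1 > 1e-14)
  u <- matrix(runif(n2 * p), n2, p)
  e1 <- eta + 1
  bq <- function(beta) {
    alpha <- 2 - beta^(-e1)
    ifelse(u <= 1 / alpha, (u * alpha)^(1 / e1),
           (1 / (2 - u * alpha))^(1 / e1))
  }
  span <- y2 - y1
  span[!on] <- 1  # placeholder to avoid 0/0; masked out below
  a <- 0.5 * ((y1 + y2) - bq(1 + 2 * (y1 - L) / span) * span)
  b <- 0.5 * ((y1 + y2) + bq(1 + 2 * (U - y2) / span) * span)
  swap <- matrix(runif(n2 * p) < 0.5, n2, p)
  c1 <- ifelse(swap, a, b); c2 <- ifelse(swap, b, a)
  C1 <- P1; C2 <- P2
  C1[on] <- c1[on]; C2[on] <- c2[on]
  C <- matrix(0, n, p)
  C[odd, ] <- pmin(pmax(C1, L), U)
  C[even, ] <- pmin(pmax(C2, L), U)
  C
}

# Bounded polynomial mutation, vectorized: each gene mutates with the given
# per-gene probability.
.poly_mutate_population <- function(P, lower, upper, eta, rate) {
  n <- nrow(P); p <- ncol(P)
  L <- matrix(lower, n, p, byrow = TRUE)
  U <- matrix(upper, n, p, byrow = TRUE)
  rng <- U - L
  on <- matrix(runif(n * p) < rate, n, p) & (rng > 0)
  u <- matrix(runif(n * p), n, p)
  d1 <- (P - L) / rng
  d2 <- (U - P) / rng
  mp <- 1 / (eta + 1)
  dq <- ifelse(
    u < 0.5,
    (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^mp - 1,
    1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^mp
  )
  out <- P + ifelse(on, dq, 0) * rng
  pmin(pmax(out, L), U)
}

#' Elitist NSGA-II over a bounded continuous decision space
#'
#' Maximizes the given objective functions. Each generation, parents are
#' chosen by the configured selection scheme, recombined by simulated binary
#' crossover, perturbed by polynomial mutation, and the combined
#' parent + child population is reduced back to size by non-domination rank
#' and, within the last admitted front, crowding distance (elitism).
#'
#' @param objectives List of objective functions to maximize; each takes a
#'   numeric matrix of decision vectors (rows = candidates) and returns a
#'   numeric vector. Names become objective column names.
#' @param bounds List with numeric vectors `lower`, `upper` (finite, equal
#'   length); names become decision column names. See [pgr_bounds()].
#' @param config An [nsga_config()].
#' @return data.frame of class `pareto_front`: the final first front with
#'   near-duplicate decision vectors (within 1e-6) removed; decision columns,
#'   objective columns, `rank` (all 0) and `crowding`. The per-generation
#'   best of each objective is attached as attribute `"elite_trace"`.
#' @export
nsga2_optimize <- function(objectives, bounds = pgr_bounds(),
                           config = nsga_config()) {
  stopifnot(inherits(config, "nsga_config"))
  lower <- bounds$lower; upper <- bounds$upper
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower)) {
    stop("bounds must be finite with upper > lower")
  }
  p <- length(lower)
  n <- config$pop_size
  obj_names <- names(objectives)
  if (is.null(obj_names)) obj_names <- paste0("f", seq_along(objectives))
  var_names <- names(lower)
  if (is.null(var_names)) var_names <- paste0("x", seq_len(p))
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  evaluate <- function(X) {
    F <- vapply(objectives, function(f) as.numeric(f(X)), numeric(nrow(X)))
    if (nrow(X) == 1) F <- matrix(F, nrow = 1)
    bad <- which(!is.finite(F), arr.ind = TRUE)
    if (nrow(bad <- unique(bad[, 1, drop = FALSE]))) {
      stop("objective returned a non-finite value at decision vector (",
           paste(signif(X[bad[1], ], 6), collapse = ", "), ")")
    }
    F
  }

  X <- matrix(runif(n * p, rep(lower, each = n), rep(upper, each = n)), n, p)
  F <- evaluate(X)
  trace <- matrix(NA_real_, config$generations, length(objectives))
  colnames(trace) <- obj_names

  rank_of <- function(fronts, size) {
    r <- integer(size)
    for (k in seq_along(fronts)) r[fronts[[k]]] <- k - 1L
    r
  }
  crowd_of <- function(fronts, F) {
    cd <- numeric(nrow(F))
    for (fr in fronts) cd[fr] <- crowding_distance(F[fr, , drop = FALSE])
    cd
  }

  fronts <- fast_nondominated_sort(F)
  rnk <- rank_of(fronts, n)
  cwd <- crowd_of(fronts, F)

  for (gen in seq_len(config$generations)) {
    idx <- if (config$selection == "roulette") {
      fit <- 1 / (1 + rnk)
      sample.int(n, n, replace = TRUE, prob = fit)
    } else {
      a <- sample.int(n, n, replace = TRUE)
      b <- sample.int(n, n, replace = TRUE)
      better <- rnk[a] < rnk[b] | (rnk[a] == rnk[b] & cwd[a] > cwd[b])
      ifelse(better, a, b)
    }
    C <- .sbx_population(X[idx, , drop = FALSE], lower, upper,
                         config$eta_c, config$crossover_rate)
    C <- .poly_mutate_population(C, lower, upper, config$eta_m,
                                 config$mutation_rate)
    CF <- evaluate(C)
    AX <- rbind(X, C); AF <- rbind(F, CF)
    fronts_all <- fast_nondominated_sort(AF)
    # survivors inherit their combined-population front index as rank: every
    # earlier front is kept whole, so relative dominance is unchanged
    keep <- integer(0)
    kept_fronts <- list()
    for (fr in fronts_all) {
      if (length(keep) + length(fr) <= n) {
        kept_fronts[[length(kept_fronts) + 1L]] <- length(keep) + seq_along(fr)
        keep <- c(keep, fr)
      } else {
        cd <- crowding_distance(AF[fr, , drop = FALSE])
        fr <- fr[order(-cd)]
        fr <- fr[seq_len(n - length(keep))]
        kept_fronts[[length(kept_fronts) + 1L]] <- length(keep) + seq_along(fr)
        keep <- c(keep, fr)
      }
      if (length(keep) >= n) break
    }
    X <- AX[keep, , drop = FALSE]
    F <- AF[keep, , drop = FALSE]
    fronts <- kept_fronts
    rnk <- rank_of(fronts, n)
    cwd <- crowd_of(fronts, F)
    trace[gen, ] <- apply(F, 2, max)
  }

  first <- fronts[[1]]
  Xf <- X[first, , drop = FALSE]
  Ff <- F[first, , drop = FALSE]
  dup <- duplicated(round(Xf / 1e-6))
  Xf <- Xf[!dup, , drop = FALSE]
  Ff <- Ff[!dup, , drop = FALSE]
  out <- data.frame(Xf, Ff)
  names(out) <- c(var_names, obj_names)
  out$rank <- 0L
  out$crowding <- crowding_distance(Ff)
  attr(out, "elite_trace") <- trace
  attr(out, "objective_names") <- obj_names
  attr(out, "decision_names") <- var_names
  class(out) <- c("pareto_front", "data.frame")
  out
}

#' Ideal-point selection from a Pareto front
#'
#' Picks the front member whose objective vector minimizes the Euclidean
#' distance, in raw (unnormalized) objective units, to the ideal point --- the
#' component-wise best values observed in the data (see [observed_ideal()]).
#' Ties are broken toward the lower value of the first decision variable
#' (lowest 2,4-D concentration).
#'
#' @param front A `pareto_front` (or data.frame with objective columns).
#' @param observed_best Numeric vector: the ideal objective values, in the
#'   same order as the front's objective columns.
#' @param objective_cols Optional character vector naming the objective
#'   columns (defaults to the front's recorded objective names).
#' @return List of class `optimization_result`: `selected` (one-row
#'   data.frame), `ideal`, `distance`, and the full `front`.
#' @export
select_ideal_point <- function(front, observed_best, objective_cols = NULL) {
  if (nrow(front) == 0) stop("empty front")
  if (is.null(objective_cols)) {
    objective_cols <- attr(front, "objective_names")
  }
  if (is.null(objective_cols)) {
    objective_cols <- setdiff(names(front), c("rank", "crowding"))
    objective_cols <- utils::tail(objective_cols, length(observed_best))
  }
  F <- as.matrix(front[objective_cols])
  if (ncol(F) != length(observed_best)) {
    stop("observed_best length does not match the objective columns")
  }
  dist <- sqrt(rowSums(sweep(F, 2, as.numeric(observed_best))^2))
  best <- which(dist <= min(dist) + 1e-12)
  if (length(best) > 1) {
    dec1 <- front[[1]][best]
    best <- best[which.min(dec1)]
  } else {
    best <- best[1]
  }
  structure(list(
    selected = front[best, , drop = FALSE],
    ideal = as.numeric(observed_best),
    distance = dist[best],
    front = front
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("ideal-point selection from a", nrow(x$front), "point Pareto front\n")
  cat("  ideal:", paste(signif(x$ideal, 6), collapse = ", "),
      " distance:", signif(x$distance, 6), "\n")
  print.data.frame(x$selected, row.names = FALSE, digits = 6)
  invisible(x)
}
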