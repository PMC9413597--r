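#' Optimizer configuration
#'
#' Settings for the bounded continuous whale optimizer. The defaults follow
#' the standard small-budget protocol used throughout the package:
#' 15 whales, 50 iterations.
#'
#' @param pop_size Number of whales N (>= 2, default 15).
#' @param max_iter Iteration budget (default 50).
#' @param variant `"iwoa"` (good-point-set initialization, adaptive weight,
#'   dimension-wise lens-imaging opposition) or `"woa"` (canonical whale
#'   optimizer: uniform random initialization, unit weight, no lens step).
#' @param b_spiral Logarithmic-spiral shape constant b (default 1).
#' @param lens_n Lens-imaging scaling factor n (> 0, default 1000); with
#'   `lens_n = 1` the opposition reduces to the classical reverse point
#'   `a + b - x`.
#' @param seed Integer seed; every random draw in a run derives from it.
#' @param init `"good_point_set"` or `"uniform_random"`; defaults to the
#'   variant's canonical choice when `NULL`.
#' @return A list of class `"optimizer_config"`.
#' @export
optimizer_config <- function(pop_size = 15, max_iter = 50,
                             variant = c("iwoa", "woa"), b_spiral = 1,
                             lens_n = 1000, seed = 1, init = NULL) {
  variant <- match.arg(variant)
  if (pop_size < 2) stop("`pop_size` must be >= 2")
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  if (lens_n <= 0) stop("`lens_n` must be > 0")
  if (is.null(init))
    init <- if (variant == "iwoa") "good_point_set" else "uniform_random"
  init <- match.arg(init, c("good_point_set", "uniform_random"))
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), variant = variant,
                 b_spiral = b_spiral, lens_n = lens_n,
                 seed = as.integer(seed), init = init),
            class = "optimizer_config")
}

is_prime <- function(m) {
  if (m < 2L) return(FALSE)
  if (m < 4L) return(TRUE)
  if (m %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= m) {
    if (m %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

# smallest prime q with (q - 3) / 2 >= s
smallest_gps_prime <- function(s) {
  q <- 2L * as.integer(ceiling(s)) + 3L
  while (!is_prime(q)) q <- q + 1L
  q
}

#' Good-point-set population initialization
#'
#' Number-theoretic low-discrepancy initialization: with `q` the smallest
#' prime satisfying `(q - 3)/2 >= s`, the generating point is
#' `r_i = 2 cos(2 pi i / q)` for dimensions `i = 1..s`, and point `k` has
#' unit-cube coordinates `frac(r_i * k)`, `k = 1..N`, then mapped affinely
#' to the box `[lower, upper]`. The construction is deterministic and more
#' uniform than uniform random sampling, giving the optimizer a
#' better-spread initial population.
#'
#' @param n_points Number of points N.
#' @param lower,upper Per-dimension bounds (recycled to dimension `s`).
#' @param s Dimension; defaults to `length(lower)`.
#' @return An `N x s` matrix inside the bounds.
#' @export
good_point_set_init <- function(n_points, lower, upper, s = length(lower)) {
  lower <- rep_len(lower, s); upper <- rep_len(upper, s)
  q <- smallest_gps_prime(s)
  r <- 2 * cos(2 * pi * seq_len(s) / q)
  k <- seq_len(n_points)
  u <- outer(k, r)            # N x s
  u <- u - floor(u)           # fractional part in [0, 1)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

#' Adaptive inertia weight
#'
#' `omega(t) = sin(pi * t / (2 * tmax) + pi) + 1`, decreasing from 1 at
#' `t = 0` to 0 at `t = tmax`: large early steps for exploration, vanishing
#' steps late for local refinement.
#'
#' @param t Current iteration, `0 <= t <= tmax`.
#' @param tmax Maximum iterations (> 0).
#' @return The weight in `[0, 1]`.
#' @export
adaptive_weight <- function(t, tmax) {
  if (tmax <= 0) stop("`tmax` must be > 0")
  sin(pi * t / (2 * tmax) + pi) + 1
}

#' Per-iteration whale coefficients
#'
#' Draws the stochastic coefficients of one whale's update:
#' `a = 2 (1 - t/tmax)`; `A = 2 a r - a` with `r ~ U[0,1]` (scalar, shared
#' across dimensions so the exploration/exploitation branch is scalar);
#' `C = 2 r'` with `r'` drawn per dimension; `l ~ U[-1, 1]`; `p ~ U[0, 1]`.
#'
#' @param t,tmax Iteration and budget.
#' @param s Dimension (length of `C`).
#' @return List with elements `A`, `C`, `l`, `p`, `a`.
#' @export
woa_coefficients <- function(t, tmax, s) {
  a <- 2 * (1 - t / tmax)
  list(A = 2 * a * stats::runif(1) - a,
       C = 2 * stats::runif(s),
       l = stats::runif(1, -1, 1),
       p = stats::runif(1),
       a = a)
}

#' One whale position update
#'
#' Applies the weighted whale update rules: shrinking encirclement of the
#' best (`p < 0.5`, `|A| < 1`), random-whale exploration (`p < 0.5`,
#' `|A| >= 1`), or the logarithmic-spiral move around the best
#' (`p >= 0.5`), each with the incumbent scaled by the adaptive weight
#' `omega`. The result is clipped to the bounds.
#'
#' @param x Current position.
#' @param best Incumbent best position.
#' @param x_rand A randomly selected whale's position.
#' @param omega Adaptive weight.
#' @param coef Coefficients from [woa_coefficients()].
#' @param lower,upper Bounds.
#' @param b_spiral Spiral shape constant.
#' @return The new, clipped position.
#' @export
position_update <- function(x, best, x_rand, omega, coef, lower, upper,
                            b_spiral = 1) {
  if (coef$p < 0.5) {
    if (abs(coef$A) < 1) {
      D <- abs(coef$C * best - x)
      xn <- omega * best - coef$A * D
    } else {
      D <- abs(coef$C * x_rand - x)
      xn <- omega * x_rand - coef$A * D
    }
  } else {
    Dp <- abs(best - x)
    xn <- omega * best + Dp * exp(b_spiral * coef$l) * cos(2 * pi * coef$l)
  }
  pmin(pmax(xn, lower), upper)
}

#' Lens-imaging opposition weights
#'
#' The three decreasing schedules driving the lens opposition from
#' coarse (all 1 at `t = 0`) to fine (all 0 at `t = tmax`):
#' `r1 = 1 - log2(1 + t/tmax)`, `r2 = 1 - (t/tmax)^2`,
#' `r3 = 1 - (t/tmax)^3`.
#'
#' @param t,tmax Iteration and budget (`tmax > 0`).
#' @return Named numeric vector `c(r1, r2, r3)`.
#' @export
lens_weights <- function(t, tmax) {
  if (tmax <= 0) stop("`tmax` must be > 0")
  u <- t / tmax
  c(r1 = 1 - log2(1 + u), r2 = 1 - u^2, r3 = 1 - u^3)
}

#' Lens-imaging opposite of one coordinate
#'
#' The weighted convex-lens reverse point of a coordinate `x` within
#' `[a, b]`:
#' `r1 (a + b)/2 + r2 (a + b)/(2 n) - r3 x / n`, clipped to the bounds.
#' With `n = 1` and `r1 = r2 = r3 = 1` it reduces to the classical
#' opposition point `a + b - x`.
#'
#' @param x Coordinate of the incumbent best.
#' @param a,b Lower and upper bound of that coordinate.
#' @param n Lens scaling factor (> 0).
#' @param r1,r2,r3 Weights from [lens_weights()].
#' @return The clipped opposite coordinate.
#' @export
lens_opposite <- function(x, a, b, n, r1, r2, r3) {
  if (n <= 0) stop("`n` must be > 0")
  y <- r1 * (a + b) / 2 + r2 * (a + b) / (2 * n) - r3 * x / n
  min(max(y, a), b)
}

#' Dimension-wise lens-imaging refinement of the incumbent best
#'
#' For each dimension in order, proposes the incumbent best with that
#' single coordinate replaced by its lens-imaging opposite and greedily
#' accepts the proposal iff it strictly lowers the fitness. Exactly `s`
#' fitness evaluations are performed.
#'
#' @param best Incumbent best position.
#' @param best_fit Its fitness.
#' @param fn Fitness function (minimized).
#' @param lower,upper Bounds.
#' @param t,tmax Iteration and budget (set the `r1, r2, r3` weights).
#' @param n Lens scaling factor.
#' @return List `position`, `fitness`, `evals`.
#' @export
dimensionwise_lens_refine <- function(best, best_fit, fn, lower, upper,
                                      t, tmax, n = 1000) {
  r <- lens_weights(t, tmax)
  s <- length(best)
  for (j in seq_len(s)) {
    cand <- best
    cand[j] <- lens_opposite(best[j], lower[j], upper[j], n,
                             r[["r1"]], r[["r2"]], r[["r3"]])
    f <- fn(cand)
    if (!is.finite(f))
      stop("non-finite fitness in lens refinement at dimension ", j)
    if (f < best_fit) {
      best <- cand
      best_fit <- f
    }
  }
  list(position = best, fitness = best_fit, evals = s)
}

#' Run the whale optimizer
#'
#' Minimizes `fn` over the box `[lower, upper]`. The `"woa"` variant is the
#' canonical whale optimization algorithm (uniform random initialization,
#' encircling / random-search / spiral updates). The `"iwoa"` variant adds
#' the three mixed strategies: good-point-set initialization, the adaptive
#' inertia weight on the incumbent in every update rule, and a
#' dimension-wise lens-imaging opposition of the incumbent best each
#' iteration (adding `s` fitness evaluations per iteration).
#'
#' Runs are fully reproducible: all randomness derives from `config$seed`
#' and the caller's RNG state is restored afterwards.
#'
#' @param fn Fitness function mapping a position to a finite scalar.
#' @param lower,upper Per-dimension bounds (recycled to a common length).
#' @param config An [optimizer_config()].
#' @return A list of class `"optimization_result"`: `best_position`,
#'   `best_fitness`, `convergence_curve` (best-so-far per iteration,
#'   non-increasing, length `max_iter`), `convergence_iteration` (first
#'   iteration within 1e-12 of the final best), `eval_count`, `variant`,
#'   `seed`.
#' @examples
#' sphere <- benchmark_suite()$sphere$fn
#' res <- woa_optimize(sphere, rep(-100, 5), rep(100, 5),
#'                     optimizer_config(seed = 1, max_iter = 20))
#' res$best_fitness
#' @export
woa_optimize <- function(fn, lower, upper, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  s <- max(length(lower), length(upper))
  lower <- rep_len(lower, s); upper <- rep_len(upper, s)
  if (any(lower >= upper)) stop("`lower` must be < `upper` element-wise")
  N <- config$pop_size; tmax <- config$max_iter
  withr::with_seed(config$seed, {
    X <- if (config$init == "good_point_set")
      good_point_set_init(N, lower, upper)
    else
      matrix(stats::runif(N * s, rep(lower, each = N), rep(upper, each = N)),
             N, s)
    best <- NULL; best_fit <- Inf
    curve <- numeric(tmax)
    evals <- 0L
    for (t in seq_len(tmax)) {
      fit <- apply(X, 1, fn)
      evals <- evals + N
      if (any(!is.finite(fit)))
        stop("non-finite fitness at position [",
             paste(signif(X[which(!is.finite(fit))[1], ], 4), collapse = ", "),
             "]")
      i <- which.min(fit)
      if (fit[i] < best_fit) { best_fit <- fit[i]; best <- X[i, ] }
      if (config$variant == "iwoa") {
        ref <- dimensionwise_lens_refine(best, best_fit, fn, lower, upper,
                                         t, tmax, config$lens_n)
        best <- ref$position; best_fit <- ref$fitness
        evals <- evals + ref$evals
      }
      curve[t] <- best_fit
      omega <- if (config$variant == "iwoa") adaptive_weight(t, tmax) else 1
      for (i in seq_len(N)) {
        coef <- woa_coefficients(t, tmax, s)
        xr <- X[sample.int(N, 1L), ]
        X[i, ] <- position_update(X[i, ], best, xr, omega, coef,
                                  lower, upper, config$b_spiral)
      }
    }
    structure(list(best_position = best, best_fitness = best_fit,
                   convergence_curve = curve,
                   convergence_iteration =
                     which(curve <= best_fit + 1e-12)[1],
                   eval_count = evals, variant = config$variant,
                   seed = config$seed),
              class = "optimization_result")
  })
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<%s run, seed %d>\n", toupper(x$variant), x$seed))
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              x$best_fitness, x$eval_count))
  cat(sprintf("  converged at iteration %d of %d\n",
              x$convergence_iteration, length(x$convergence_curve)))
  invisible(x)
}

#' Standard benchmark functions
#'
#' Classic box-bounded test problems with known global minima at the
#' origin (Rosenbrock: at the all-ones point), used to validate optimizer
#' behavior.
#'
#' @return Named list; each element has `fn`, `lower`, `upper`,
#'   `minimum` (location for dimension `s`, as a function of `s`) and
#'   `min_value`.
#' @export
benchmark_suite <- function() {
  list(
    sphere = list(fn = function(x) sum(x^2),
                  lower = -100, upper = 100,
                  minimum = function(s) rep(0, s), min_value = 0),
    rastrigin = list(fn = function(x)
                       sum(x^2 - 10 * cos(2 * pi * x) + 10),
                     lower = -5.12, upper = 5.12,
                     minimum = function(s) rep(0, s), min_value = 0),
    rosenbrock = list(fn = function(x) {
                        n <- length(x)
                        sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
                      },
                      lower = -5, upper = 10,
                      minimum = function(s) rep(1, s), min_value = 0),
    ackley = list(fn = function(x) {
                    n <- length(x)
                    -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
                      exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
                  },
                  lower = -32.768, upper = 32.768,
                  minimum = function(s) rep(0, s), min_value = 0)
  )
}
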