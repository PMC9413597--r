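test_that("good point set uses the smallest admissible prime", {
  expect_equal(iwoaselect:::smallest_gps_prime(1), 5L)
  expect_equal(iwoaselect:::smallest_gps_prime(2), 7L)
  expect_equal(iwoaselect:::smallest_gps_prime(5), 13L)
  expect_equal(iwoaselect:::smallest_gps_prime(44), 97L)
  g <- good_point_set_init(3, c(0, 0), c(1, 1))
  r1 <- 2 * cos(2 * pi / 7)
  expect_equal(g[1, 1], r1 - floor(r1), tolerance = 1e-12)
  expect_equal(g[2, 1], 2 * r1 - floor(2 * r1), tolerance = 1e-12)
  # affine mapping to general bounds
  gb <- good_point_set_init(5, c(-2, 10), c(2, 20))
  expect_true(all(gb[, 1] >= -2 & gb[, 1] <= 2))
  expect_true(all(gb[, 2] >= 10 & gb[, 2] <= 20))
})

test_that("good point set spreads more evenly than uniform random draws", {
  max_gap <- function(m) max(apply(m, 2, function(v)
    max(diff(c(0, sort(v), 1)))))
  gps <- max_gap(good_point_set_init(100, c(0, 0), c(1, 1)))
  unif <- withr::with_seed(1, mean(replicate(100,
    max_gap(matrix(runif(200), 100, 2)))))
  expect_lt(gps, unif)
})

test_that("adaptive weight decreases from 1 to 0 along the schedule", {
  expect_equal(adaptive_weight(0, 50), 1)
  expect_equal(adaptive_weight(50, 50), 0)
  expect_equal(adaptive_weight(25, 50), 1 - sqrt(2) / 2, tolerance = 1e-9)
  w <- adaptive_weight(seq(0, 50, by = 0.25), 50)
  expect_true(all(diff(w) <= 1e-12))
  expect_error(adaptive_weight(1, 0), "tmax")
})

test_that("whale coefficients follow their schedules and ranges", {
  co <- withr::with_seed(1, woa_coefficients(50, 50, 4))
  expect_equal(co$A, 0)                   # a = 0 at t = tmax
  expect_equal(co$a, 0)
  co0 <- withr::with_seed(1, woa_coefficients(0, 50, 4))
  expect_equal(co0$a, 2)
  expect_length(co0$C, 4)
  expect_true(all(co0$C >= 0 & co0$C <= 2))
  expect_true(co0$l >= -1 && co0$l <= 1)
  expect_true(co0$p >= 0 && co0$p <= 1)
  expect_identical(withr::with_seed(9, woa_coefficients(3, 50, 4)),
                   withr::with_seed(9, woa_coefficients(3, 50, 4)))
})

test_that("position update reproduces hand-computed cases", {
  lo <- rep(-10, 1); hi <- rep(10, 1)
  # encircling collapse: omega = 1, A = 0, C = 1, p < 0.5 -> X* exactly
  co <- list(A = 0, C = 1, l = 0, p = 0.3)
  expect_equal(position_update(5, 2, 7, 1, co, lo, hi), 2)
  # spiral: X = 0, X* = 1, l = -0.5, b = 1 -> 1 - exp(-0.5)
  co <- list(A = 0, C = 1, l = -0.5, p = 0.9)
  expect_equal(position_update(0, 1, 7, 1, co, lo, hi, b_spiral = 1),
               1 - exp(-0.5), tolerance = 1e-12)
  # omega = 0 with A = 0 collapses to the origin (inside bounds)
  co <- list(A = 0, C = 1, l = 0, p = 0.3)
  expect_equal(position_update(5, 2, 7, 0, co, lo, hi), 0)
  # exploration branch uses the random whale when |A| >= 1
  co <- list(A = 1.5, C = 1, l = 0, p = 0.3)
  expect_equal(position_update(5, 2, 7, 1, co, lo, hi), 7 - 1.5 * abs(7 - 5))
  # results are clipped to bounds
  co <- list(A = -3, C = 2, l = 0, p = 0.3)
  expect_equal(position_update(9, 9, 1, 1, co, lo, hi), 10)
})

test_that("lens weights decay from (1,1,1) to (0,0,0) with r3 >= r2", {
  expect_equal(unname(lens_weights(0, 50)), c(1, 1, 1))
  expect_equal(unname(lens_weights(50, 50)), c(0, 0, 0))
  expect_equal(unname(lens_weights(25, 50)),
               c(1 - log2(1.5), 0.75, 0.875), tolerance = 1e-9)
  for (u in seq(0.05, 0.95, by = 0.05)) {
    r <- lens_weights(u * 50, 50)
    expect_gte(r[["r3"]], r[["r2"]])
  }
  expect_error(lens_weights(1, 0), "tmax")
})

test_that("lens opposite reduces to classical opposition at n = 1", {
  expect_equal(lens_opposite(0.3, 0, 1, 1, 1, 1, 1), 0.7)
  expect_equal(lens_opposite(0.3, 0, 1, 2, 1, 1, 1), 0.6)
  # degenerate end-of-run weights send the point to the clipped origin
  expect_equal(lens_opposite(0.3, 0, 1, 1, 0, 0, 0), 0)
  expect_equal(lens_opposite(0.5, 0.2, 1, 1, 0, 0, 0), 0.2)  # clip
  expect_error(lens_opposite(0.3, 0, 1, 0, 1, 1, 1), "n")
})

test_that("dimension-wise lens refinement is greedy with strict acceptance", {
  sphere <- function(x) sum(x^2)
  # optimum stays put: opposite of 0 at t = 0, n = 1 is 0 -> no strict gain
  r <- dimensionwise_lens_refine(c(0, 0), 0, sphere, c(-1, -1), c(1, 1),
                                 0, 50, n = 1)
  expect_equal(r$position, c(0, 0))
  expect_equal(r$evals, 2)
  # |-0.8| = |0.8|: equal fitness is rejected (strict improvement only)
  r <- dimensionwise_lens_refine(c(0.8, 0), 0.64, sphere, c(-1, -1),
                                 c(1, 1), 0, 50, n = 1)
  expect_equal(r$position, c(0.8, 0))
  # a genuinely better opposite is accepted
  f <- function(x) (x - 0.25)^2
  r <- dimensionwise_lens_refine(0.9, f(0.9), f, 0, 1, 0, 50, n = 1)
  expect_equal(r$position, 0.1, tolerance = 1e-12)
  expect_equal(r$fitness, f(0.1), tolerance = 1e-12)
})

test_that("benchmark functions have their known minima", {
  bs <- benchmark_suite()
  for (nm in names(bs)) {
    b <- bs[[nm]]
    expect_lt(abs(b$fn(b$minimum(6)) - b$min_value), 1e-12)
  }
  expect_equal(bs$sphere$fn(c(3, 4)), 25)
  expect_equal(bs$rastrigin$fn(rep(0, 10)), 0)
})

test_that("IWOA minimizes the 10-D sphere well below 1e-2 for seeds 0..4", {
  sphere <- benchmark_suite()$sphere$fn
  for (s in 0:4) {
    r <- woa_optimize(sphere, rep(-100, 10), rep(100, 10),
                      optimizer_config(seed = s))
    expect_lt(r$best_fitness, 1e-2)
  }
})

test_that("optimizer bookkeeping: curve, eval counts, determinism, errors", {
  sphere <- benchmark_suite()$sphere$fn
  cfg <- optimizer_config(pop_size = 12, max_iter = 30, seed = 5)
  r <- woa_optimize(sphere, rep(-5, 6), rep(5, 6), cfg)
  expect_length(r$convergence_curve, 30)
  expect_true(all(diff(r$convergence_curve) <= 0))
  expect_equal(r$eval_count, 12 * 30 + 6 * 30)  # iwoa adds s per iteration
  w <- woa_optimize(sphere, rep(-5, 6), rep(5, 6),
                    optimizer_config(pop_size = 12, max_iter = 30,
                                     variant = "woa", seed = 5))
  expect_equal(w$eval_count, 12 * 30)
  expect_true(all(diff(w$convergence_curve) <= 0))
  # same seed -> bit-identical result
  expect_identical(woa_optimize(sphere, rep(-5, 6), rep(5, 6), cfg), r)
  # constant fitness -> flat curve at the constant
  k <- woa_optimize(function(x) 7, rep(0, 3), rep(1, 3),
                    optimizer_config(max_iter = 5, seed = 1))
  expect_equal(k$best_fitness, 7)
  expect_equal(unique(k$convergence_curve), 7)
  expect_equal(k$convergence_iteration, 1L)
  # non-finite fitness names the offending position
  expect_error(woa_optimize(function(x) NaN, 0, 1,
                            optimizer_config(max_iter = 2, seed = 1)),
               "non-finite")
})

test_that("IWOA beats WOA in the median over paired seeds", {
  bs <- benchmark_suite()
  run <- function(b, v, s) woa_optimize(
    b$fn, rep(b$lower, 10), rep(b$upper, 10),
    optimizer_config(variant = v, seed = s))$best_fitness
  for (nm in c("sphere", "rastrigin")) {
    iwoa <- vapply(1:20, function(s) run(bs[[nm]], "iwoa", s), numeric(1))
    woa <- vapply(1:20, function(s) run(bs[[nm]], "woa", s), numeric(1))
    expect_lte(median(iwoa), median(woa))
  }
})
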