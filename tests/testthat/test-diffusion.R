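test_that("schedule endpoints, shapes and validity guards", {
  sch <- makeSchedule(1000L)
  expect_equal(sch@beta[1], 1e-4)
  expect_equal(sch@beta[1000], 0.02)
  expect_equal(sch@alpha, 1 - sch@beta)
  s1 <- makeSchedule(1L, betaStart = 0.01, betaEnd = 0.01)
  expect_equal(s1@alphaBar, 1 - 0.01)
  expect_error(makeSchedule(10L, betaStart = 0.5, betaEnd = 0.2), "betaStart")
  expect_error(makeSchedule(10L, betaStart = 0, betaEnd = 0.2), "betaStart")
})

test_that("cumulative product matches an explicit product loop at every t", {
  sch <- makeSchedule(1000L)
  prod <- 1
  for (t in 1:1000) {
    prod <- prod * (1 - sch@beta[t])
    expect_equal(sch@alphaBar[t], prod, tolerance = 1e-12)
  }
  expect_true(all(diff(sch@alphaBar) < 0))
})

test_that("closed-form forward noising is exact in the noiseless limit", {
  sch <- makeSchedule(100L)
  x0 <- matrix(c(0.2, 0.3, 0.5), 1)
  z <- matrix(0, 1, 3)
  expect_equal(forwardNoise(x0, 50L, z, sch),
               sqrt(sch@alphaBar[50]) * x0)
  expect_equal(forwardNoise(x0, 1L, z, sch), x0, tolerance = 1e-3)
  expect_error(forwardNoise(x0, 0L, z, sch), "t must be")
})

test_that("forward marginal matches step-by-step simulation moments", {
  # simulate the Markov chain x_t = sqrt(1-beta_t) x_{t-1} + sqrt(beta_t) e_t
  # and compare first/second moments with the closed form at several t
  sch <- makeSchedule(1000L)
  x0 <- c(0.6, 0.1, 0.3)
  set.seed(11)
  n <- 10000
  for (tCheck in c(1L, 100L, 1000L)) {
    xs <- matrix(rep(x0, each = n), n, 3)
    for (t in 1:tCheck)
      xs <- sqrt(1 - sch@beta[t]) * xs +
        sqrt(sch@beta[t]) * matrix(rnorm(n * 3), n, 3)
    ab <- sch@alphaBar[tCheck]
    seMean <- sqrt(1 - ab) / sqrt(n)
    expect_true(all(abs(colMeans(xs) - sqrt(ab) * x0) < 3 * seMean))
    # var of sample variance ~ 2 sigma^4/(n-1)
    seVar <- sqrt(2 / (n - 1)) * (1 - ab)
    expect_true(all(abs(apply(xs, 2, var) - (1 - ab)) < 3 * pmax(seVar, 1e-6)))
  }
})

test_that("noise-prediction loss equals hand-computed MSE", {
  sch <- makeSchedule(10L)
  xt <- matrix(rnorm(6), 2, 3)
  eps <- matrix(rnorm(6), 2, 3)
  cond <- matrix(rnorm(8), 2, 4)
  exact <- function(xt, t, cond) eps
  attr(exact, "K") <- 3L
  expect_equal(noisePredictionLoss(exact, xt, c(1L, 2L), cond, eps), 0)
  offset <- function(xt, t, cond) eps + 0.3
  expect_equal(noisePredictionLoss(offset, xt, c(1L, 2L), cond, eps), 0.3^2,
               tolerance = 1e-12)
  fixedOut <- matrix(c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6), 2, 3)
  fixed <- function(xt, t, cond) fixedOut
  expect_equal(noisePredictionLoss(fixed, xt, c(1L, 2L), cond, eps),
               mean((eps - fixedOut)^2), tolerance = 1e-12)
})

test_that("simplex projection clips, renormalises and falls back to uniform", {
  expect_equal(projectToSimplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(projectToSimplex(c(-0.1, 0.6, 0.6)), c(0, 0.5, 0.5))
  expect_equal(projectToSimplex(c(-1, -2)), c(0.5, 0.5))
  expect_error(projectToSimplex(c(NA, 1)), "finite")
})

test_that("single-step sampling with a zero denoiser is pure algebra", {
  sch <- makeSchedule(1L, betaStart = 0.01, betaEnd = 0.01)
  zero <- function(xt, t, cond) matrix(0, nrow(xt), ncol(xt))
  attr(zero, "K") <- 3L
  out <- ddpmSample(zero, rep(0, 4), sch, seed = 5L)
  set.seed(5L)
  x1 <- rnorm(3)
  expect_equal(out, projectToSimplex(x1 / sqrt(1 - 0.01)))
})

test_that("sampling is deterministic given the seed", {
  sch <- makeSchedule(20L)
  noisy <- function(xt, t, cond) xt * 0.5
  attr(noisy, "K") <- 4L
  a <- ddpmSample(noisy, rep(0.1, 3), sch, seed = 123L)
  b <- ddpmSample(noisy, rep(0.1, 3), sch, seed = 123L)
  expect_identical(a, b)
})

test_that("the analytic oracle denoiser recovers its target", {
  sch <- makeSchedule(200L)
  x0star <- c(0.55, 0.25, 0.15, 0.05)
  oracle <- function(xt, t, cond) {
    ab <- sch@alphaBar[t[1]]
    (xt - sqrt(ab) * matrix(x0star, nrow(xt), 4, byrow = TRUE)) / sqrt(1 - ab)
  }
  attr(oracle, "K") <- 4L
  out <- ddpmSample(oracle, rep(0, 8), sch, seed = 42L, nDraws = 32L)
  expect_lt(max(abs(out - x0star)), 0.02)
})

test_that("the exact linear oracle collapses to its target at the last step", {
  # for eps(x_t) = (x_t - sqrt(ab_t) x0*)/sqrt(1 - ab_t), the t = 1 update
  # multiplies x_1 by (1 - ab_1 - b_1)/((1 - ab_1) sqrt(a_1)) = 0, wiping
  # all accumulated noise: recovery is exact, not merely within tolerance
  sch <- makeSchedule(100L)
  x0star <- c(0.4, 0.35, 0.25)
  oracle <- function(xt, t, cond) {
    ab <- sch@alphaBar[t[1]]
    (xt - sqrt(ab) * matrix(x0star, nrow(xt), 3, byrow = TRUE)) / sqrt(1 - ab)
  }
  attr(oracle, "K") <- 3L
  for (nd in c(1L, 8L))
    expect_lt(max(abs(ddpmSample(oracle, rep(0, 5), sch, seed = 31L,
                                 nDraws = nd) - x0star)), 1e-12)
})

test_that("averaging draws reduces sampler variance on a noisy denoiser", {
  # a deliberately imperfect (damped) oracle keeps residual stochasticity
  # in the output; quadrupling the averaged draws should roughly halve the
  # spread of the sampled proportions across independent runs
  sch <- makeSchedule(100L)
  x0star <- c(0.4, 0.35, 0.25)
  damped <- function(xt, t, cond) {
    ab <- sch@alphaBar[t[1]]
    0.9 * (xt - sqrt(ab) * matrix(x0star, nrow(xt), 3, byrow = TRUE)) /
      sqrt(1 - ab)
  }
  attr(damped, "K") <- 3L
  spread <- function(nd) {
    draws <- t(sapply(1:30, function(s)
      ddpmSample(damped, rep(0, 5), sch, seed = 5000L + s, nDraws = nd)))
    mean(apply(draws, 2, sd))
  }
  s1 <- spread(1L); s4 <- spread(4L); s16 <- spread(16L)
  expect_lt(s4, s1)
  expect_lt(s16, s4)
  expect_lt(s16, 0.5 * s1)
})
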