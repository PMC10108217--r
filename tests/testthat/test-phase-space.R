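test_that("the embedding is deterministic and rejects undersized input", {
  set.seed(1)
  X <- matrix(rnorm(200 * 20), 200, 20)
  a <- embed_profiles(X, perplexity = 10, n_iter = 300, seed = 5)
  b <- embed_profiles(X, perplexity = 10, n_iter = 300, seed = 5)
  expect_identical(a, b)
  expect_equal(mean(a$x), 0, tolerance = 1e-10)  # centred per axis
  expect_equal(mean(a$y), 0, tolerance = 1e-10)
  expect_error(embed_profiles(X[1:10, ], perplexity = 30), "perplexity")
})

test_that("the embedding preserves well-separated cluster structure", {
  set.seed(2)
  n <- 300
  lab <- rep(c(0, 1), each = n)
  X <- rbind(matrix(rnorm(n * 20), n, 20),
             matrix(rnorm(n * 20, mean = 6), n, 20))
  emb <- embed_profiles(X, perplexity = 30, n_iter = 500, seed = 0)
  expect_gte(mean_silhouette(cbind(emb$x, emb$y), lab), 0.5)
})

test_that("axis gradients reproduce exact linear structure", {
  set.seed(3)
  emb <- data.frame(x = rnorm(100), y = rnorm(100))
  g <- fit_axis_gradients(emb, data.frame(phi = 2 + 3 * emb$x))
  expect_equal(g$c, 2, tolerance = 1e-8)
  expect_equal(g$alpha, 3, tolerance = 1e-8)
  expect_equal(g$beta, 0, tolerance = 1e-8)
  expect_equal(g$sigma2, 0, tolerance = 1e-12)
})

test_that("a symmetric quadratic has no linear gradient", {
  xs <- seq(-1, 1, length.out = 21)
  emb <- expand.grid(x = xs, y = xs)
  phi <- emb$y^2
  g <- fit_axis_gradients(emb, data.frame(phi = phi))
  expect_equal(g$alpha, 0, tolerance = 1e-10)
  expect_equal(g$beta, 0, tolerance = 1e-10)
  expect_equal(g$c, mean(phi), tolerance = 1e-10)
})

test_that("gradient fits match an independent normal-equations solve", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:200, 1)
    emb <- data.frame(x = rnorm(n), y = rnorm(n))
    phi <- rnorm(n)
    g <- fit_axis_gradients(emb, data.frame(phi = phi))
    X <- cbind(1, emb$x, emb$y)
    ref <- solve(t(X) %*% X, t(X) %*% phi)  # brute-force least squares
    expect_equal(c(g$c, g$alpha, g$beta), as.vector(ref), tolerance = 1e-8)
  }
  emb_col <- data.frame(x = 1:10, y = 2 * (1:10))  # collinear with intercept? no:
  emb_col$y <- emb_col$x  # x == y is rank-deficient with the intercept
  expect_error(fit_axis_gradients(emb_col, data.frame(phi = rnorm(10))),
               "collinear")
})

test_that("trajectory windows follow the widening delta-t rule", {
  emb <- data.frame(patient_id = 1:8, x = 1:8, y = 1:8,
                    day = c(45, 75, 44, 135, 225, 310, 490, 491))
  tr <- average_trajectory(emb, times = c(60, 180, 400), resample = FALSE)
  expect_equal(tr$delta_t, c(30, 90, 180))
  # t = 60: window [45, 75] closed -> days 45, 75 in; 44 out
  expect_equal(tr$n_profiles[tr$t == 60], 2)
  # t = 180: window [135, 225]
  expect_equal(tr$n_profiles[tr$t == 180], 2)
  # t = 400: window [310, 490] -> 491 out
  expect_equal(tr$n_profiles[tr$t == 400], 2)
  expect_error(average_trajectory(emb, times = c(-5)), "positive")
})

test_that("degenerate windows give exact trajectory points", {
  emb <- data.frame(patient_id = rep(1:5, 2), day = rep(c(50, 60), each = 5),
                    x = 1, y = 2)
  tr <- average_trajectory(emb, times = 55, n_boot = 50, seed = 1)
  expect_equal(tr$mean_x, 1)
  expect_equal(tr$mean_y, 2)
  expect_equal(tr$sd_x, 0)
  expect_equal(tr$sd_y, 0)

  # a single-draw bootstrap with resampling disabled is the window mean
  set.seed(4)
  emb2 <- data.frame(patient_id = 1:20, day = round(runif(20, 40, 70)),
                     x = rnorm(20), y = rnorm(20))
  tr2 <- average_trajectory(emb2, times = 55, n_boot = 1, resample = FALSE)
  inw <- emb2$day >= 40 & emb2$day <= 70
  expect_equal(tr2$mean_x, mean(emb2$x[inw]))
  expect_equal(tr2$mean_y, mean(emb2$y[inw]))

  expect_warning(average_trajectory(emb2, times = 300), "omitted")
})

test_that("trajectory means are invariant to profile ordering and reruns", {
  set.seed(5)
  emb <- data.frame(patient_id = sample(1:30, 100, TRUE),
                    day = round(runif(100, 1, 400)),
                    x = rnorm(100), y = rnorm(100))
  t1 <- average_trajectory(emb, times = c(60, 180), n_boot = 40, seed = 2)
  t2 <- average_trajectory(emb[sample(nrow(emb)), ], times = c(60, 180),
                           n_boot = 40, seed = 2)
  t3 <- average_trajectory(emb, times = c(60, 180), n_boot = 40, seed = 2)
  expect_equal(t1, t2)
  expect_identical(t1, t3)
})

test_that("between-patient variance follows the documented convention", {
  emb <- data.frame(patient_id = c("a", "b"), day = c(60, 60),
                    x = c(0, 2), y = c(0, 0))
  # population (divide-by-n) variance per axis, summed over axes
  expect_equal(variance_over_time(emb, 60)$variance, 1)

  emb2 <- data.frame(patient_id = rep(c("a", "b"), 3), day = 60,
                     x = 1.5, y = -2)
  expect_equal(variance_over_time(emb2, 60)$variance, 0)
})

test_that("simulated cohorts diverge after the earliest follow-up", {
  co <- cached("var_cohort",
               simulate_cohort(sim_config(n_patients = 400, seed = 5)))$cohort
  sc <- fit_rescaler(co$profiles)
  X <- apply_rescaler(sc, co$profiles)
  pc <- stats::prcomp(X, rank. = 2)
  emb <- data.frame(patient_id = co$profiles$patient_id,
                    day = co$profiles$day, x = pc$x[, 1], y = pc$x[, 2])
  v <- variance_over_time(emb, c(30, 60, 90, 180, 270))
  expect_gt(max(v$variance[v$t >= 45]), v$variance[v$t == 30])
})
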