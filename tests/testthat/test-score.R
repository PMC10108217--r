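unit_vec <- function(feature, value = 1) {
  v <- stats::setNames(rep(0, 8),
                       c("wbc", "neut", "lymph_frac_nuc", "lymph",
                         "nk_frac", "t_frac", "cd4_frac", "b_frac"))
  v[feature] <- value
  v
}

test_that("the published formula reproduces its printed coefficients exactly", {
  cf <- c(wbc = 0.7304, neut = -0.4745, lymph_frac_nuc = -16.7825,
          lymph = -1.7612, nk_frac = -7.9450, t_frac = 10.2955,
          cd4_frac = -7.9703, b_frac = -15.7887)
  for (f in names(cf)) {
    expect_identical(published_score(unit_vec(f)), unname(cf[[f]]))
  }
  expect_identical(published_score(unit_vec("wbc", 0)), 0)
  expect_identical(coef(cirs_published()), cf)
})

test_that("a mixed input matches the hand-computed weighted sum", {
  x <- c(wbc = 4, neut = 2, lymph_frac_nuc = 0.3, lymph = 1.2,
         nk_frac = 0.15, t_frac = 0.7, cd4_frac = 0.25, b_frac = 0.05)
  # frozen: sum of the eight products computed by hand
  expect_equal(published_score(x), -1.9425, tolerance = 1e-12)
})

test_that("invalid score inputs fail loudly, naming the culprit", {
  x <- unit_vec("wbc", 2)
  expect_error(published_score(x[-2]), "neut")
  x["nk_frac"] <- 1.2
  expect_error(published_score(x), "nk_frac")
  x["nk_frac"] <- NA
  expect_error(published_score(x), "nk_frac")
})

test_that("the published score is linear in its inputs", {
  set.seed(8)
  counts <- c("wbc", "neut", "lymph")
  fracs <- c("lymph_frac_nuc", "nk_frac", "t_frac", "cd4_frac", "b_frac")
  for (i in 1:20) {
    u <- c(stats::setNames(runif(3, 0, 10), counts),
           stats::setNames(runif(5), fracs))
    v <- c(stats::setNames(runif(3, 0, 10), counts),
           stats::setNames(runif(5), fracs))
    a <- runif(1, 0, 0.6)
    b <- runif(1, 0, 1 - a)  # a + b <= 1 keeps fractions in [0, 1]
    lhs <- published_score(a * u + b * v)
    rhs <- a * published_score(u) + b * published_score(v)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("classification is monotone in each feature with its printed sign", {
  base <- c(wbc = 5, neut = 2, lymph_frac_nuc = 0.3, lymph = 1.5,
            nk_frac = 0.2, t_frac = 0.5, cd4_frac = 0.2, b_frac = 0.1)
  s0 <- published_score(base)
  for (f in c("wbc", "t_frac")) {            # positive coefficients
    up <- base; up[f] <- up[f] + 0.1
    expect_gt(published_score(up), s0)
  }
  for (f in c("neut", "lymph_frac_nuc", "lymph", "nk_frac", "cd4_frac",
              "b_frac")) {                   # negative coefficients
    up <- base; up[f] <- up[f] + 0.1
    expect_lt(published_score(up), s0)
  }
})

test_that("the 2.50 cutoff is strict: the boundary is low-risk", {
  expect_identical(classify_risk(2.50), "low")
  expect_identical(classify_risk(2.50 + 1e-12), "high")
  expect_identical(classify_risk(2.51), "high")
  expect_identical(classify_risk(-5), "low")
  expect_identical(classify_risk(c(1, 3)), c("low", "high"))
})

test_that("patient-period scores are window means, then thresholded", {
  # wbc-only profiles scoring exactly 2.0 and 3.2
  pr <- data.frame(patient_id = c("A", "A", "B", "C"),
                   day = c(100, 150, 120, 400),
                   wbc = c(2.0, 3.2, 2.0, 9) / 0.7304,
                   neut = 0, lymph_frac_nuc = 0, lymph = 0,
                   nk_frac = 0, t_frac = 0, cd4_frac = 0, b_frac = 0)
  out <- score_patient_period(pr, period(91, 180))
  expect_equal(out$score[out$patient_id == "A"], 2.6, tolerance = 1e-9)
  expect_identical(out$risk[out$patient_id == "A"], "high")
  expect_equal(out$score[out$patient_id == "B"], 2.0, tolerance = 1e-9)
  expect_identical(out$risk[out$patient_id == "B"], "low")
  expect_false("C" %in% out$patient_id)  # no in-window profile
})

test_that("stepwise selection recovers a planted logistic truth", {
  set.seed(9)
  n <- 2000
  X <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(X) <- paste0("f", 1:8)
  lp <- -0.5 + 1.5 * X$f1 - 2.0 * X$f2 + 1.0 * X$f3
  y <- runif(n) < plogis(lp)
  m <- fit_score_model(X, y, candidates = names(X))
  expect_true(all(c("f1", "f2", "f3") %in% names(coef(m))))
  expect_equal(unname(coef(m)["f1"]), 1.5, tolerance = 0.25)
  expect_equal(unname(coef(m)["f2"]), -2.0, tolerance = 0.25)
  expect_equal(unname(coef(m)["f3"]), 1.0, tolerance = 0.25)
  expect_identical(m$provenance, "fitted")
  # threshold sits on the intercept-free linear predictor
  s <- predict(m, X)
  j <- mean(s[y] > m$threshold) + mean(s[!y] <= m$threshold) - 1
  expect_gt(j, 0.5)
})

test_that("stepwise matches exhaustive best-subset AIC on small pools", {
  for (seed in c(10, 11, 12)) {
    set.seed(seed)
    n <- 400
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("f", 1:6)
    y <- runif(n) < plogis(-0.3 + 1.8 * X$f1 - 1.2 * X$f4)
    m <- fit_score_model(X, y, candidates = names(X))
    dat <- X
    dat$.y <- y
    ref <- best_subset_aic(dat, names(X))
    expect_setequal(names(coef(m)), ref$set)
  }
})

test_that("null labels keep the selected model small", {
  set.seed(13)
  sizes <- vapply(1:50, function(i) {
    n <- 300
    X <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    names(X) <- paste0("f", 1:8)
    y <- runif(n) < 0.3
    m <- tryCatch(fit_score_model(X, y, candidates = names(X)),
                  error = function(e) NULL)
    if (is.null(m)) 0 else length(coef(m))
  }, numeric(1))
  expect_lte(mean(sizes), 2)
})

test_that("perfect separation triggers the stabilised refit path", {
  set.seed(14)
  n <- 200
  X <- data.frame(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  f2 = rnorm(n))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  expect_warning(m <- fit_score_model(X, y, candidates = c("f1", "f2")),
                 "separation")
  expect_true(all(is.finite(coef(m))))
})

test_that("degenerate label sets are rejected", {
  X <- data.frame(f1 = rnorm(30))
  expect_error(fit_score_model(X, rep(TRUE, 30), candidates = "f1"),
               "single class")
  expect_error(fit_score_model(X[1:10, , drop = FALSE],
                               rep(c(TRUE, FALSE), 5), candidates = "f1"),
               ">= 20")
})

test_that("the calculator mode scores vectors and tables", {
  one <- run_score_only(unit_vec("t_frac"))
  expect_equal(one$score, 10.2955)
  expect_identical(one$risk, "high")
  tab <- as.data.frame(rbind(unit_vec("wbc", 2), unit_vec("b_frac", 0.5)))
  out <- run_score_only(tab)
  expect_equal(nrow(out), 2)
  expect_identical(out$risk, c("low", "low"))
  bad <- tab
  bad$nk_frac[1] <- 5
  expect_error(run_score_only(bad), "nk_frac")
})
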