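test_that("the grid spans the bounding box at the requested resolution", {
  set.seed(1)
  emb <- data.frame(x = runif(50), y = runif(50))
  g <- build_grid(emb)
  expect_equal(nrow(g), 14641)  # 121 x 121
  expect_equal(range(g$x), range(emb$x))
  expect_equal(range(g$y), range(emb$y))

  g2 <- build_grid(data.frame(x = c(0, 1), y = c(0, 1)), n_per_axis = 2)
  expect_equal(g2$x, c(0, 0, 1, 1))
  expect_equal(g2$y, c(0, 1, 0, 1))

  expect_error(build_grid(data.frame(x = c(1, 1, 1), y = 1:3)), "degenerate")
  expect_error(build_grid(data.frame(x = 1, y = 1)), "distinct")
})

test_that("nearness uses the any-profile rule with an inclusive boundary", {
  r <- 0.5
  emb <- data.frame(patient_id = c("at", "boundary", "mixed", "mixed", "far"),
                    x = c(0, r, 1.5 * r, 0.9 * r, 3 * r),
                    y = 0)
  near <- near_labels(c(0, 0), emb, radius = r)
  expect_true(near[["at"]])        # exactly at the grid point
  expect_true(near[["boundary"]])  # distance == radius is near
  expect_true(near[["mixed"]])     # one of {1.5r, 0.9r} suffices
  expect_false(near[["far"]])
  expect_error(near_labels(c(0, 0), emb, radius = 0), "radius")
})

test_that("enlarging the radius never turns a near patient far", {
  set.seed(6)
  emb <- data.frame(patient_id = sample(letters, 200, TRUE),
                    x = rnorm(200), y = rnorm(200))
  for (i in 1:20) {
    gp <- c(rnorm(1), rnorm(1))
    r1 <- runif(1, 0.1, 1)
    r2 <- r1 + runif(1, 0, 1)
    n1 <- near_labels(gp, emb, r1)
    n2 <- near_labels(gp, emb, r2)
    expect_true(all(n2[n1]))
  }
})

test_that("the scan finds anchors inside the planted high-risk region", {
  fx <- planted_fixture()
  anch <- scan_anchor_points(fx$cohort, fx$embedded, period(91, 180),
                             n_per_axis = 61)
  expect_s3_class(anch, "cirs_anchors")
  expect_gt(nrow(anch$anchors), 0)
  expect_true(all(anch$anchors$p < 0.01))
  expect_true(all(anch$anchors$hr > 1))  # planted effect raises hazard

  # anchors concentrate in the convex hull of derailed patients' profiles
  tr <- fx$truth
  der_ids <- tr$patient_id[tr$derailed]
  pts <- fx$embedded[fx$embedded$patient_id %in% der_ids, c("x", "y")]
  hull <- pts[chull(pts), ]
  inside <- mgcv::in.out(as.matrix(rbind(hull, hull[1, ])),
                         as.matrix(anch$anchors[, c("x", "y")]))
  expect_gte(mean(inside), 0.8)

  # alpha = 0 admits nothing
  anch0 <- scan_anchor_points(fx$cohort, fx$embedded, period(91, 180),
                              n_per_axis = 61, alpha = 0)
  expect_equal(nrow(anch0$anchors), 0)
})

test_that("the assigned signature recovers the planted derailed flag", {
  fx <- planted_fixture()
  anch <- scan_anchor_points(fx$cohort, fx$embedded, period(91, 180),
                             n_per_axis = 61)
  sig <- assign_signature(fx$cohort, fx$embedded, anch)
  tr <- fx$truth[match(sig$patient_id, fx$truth$patient_id), ]
  sens <- sum(sig$signature & tr$derailed) / sum(tr$derailed)
  spec <- sum(!sig$signature & !tr$derailed) / sum(!tr$derailed)
  expect_gte(sens, 0.8)
  expect_gte(spec, 0.8)

  # empty anchor set labels everyone negative
  anch0 <- scan_anchor_points(fx$cohort, fx$embedded, period(91, 180),
                              n_per_axis = 61, alpha = 0)
  sig0 <- assign_signature(fx$cohort, fx$embedded, anch0)
  expect_true(all(!sig0$signature))
  expect_true(all(is.infinite(sig0$nearest_anchor_dist)))
})

test_that("permuting outcomes calibrates the anchor rate to the null", {
  fx <- planted_fixture()
  co <- fx$cohort
  fracs <- vapply(1:5, function(s) {
    perm <- with_seed(s, sample(nrow(co$outcomes)))
    co_p <- co
    co_p$outcomes[c("os_time", "death", "cause")] <-
      co$outcomes[perm, c("os_time", "death", "cause")]
    a <- suppressWarnings(
      scan_anchor_points(co_p, fx$embedded, period(91, 180), n_per_axis = 41))
    nrow(a$anchors) / max(1, sum(a$grid$testable))
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("degenerate scans return empty anchor sets with a warning", {
  fx <- planted_fixture()
  co <- fx$cohort
  co$outcomes$death <- FALSE
  co$outcomes$cause <- "none"
  expect_warning(
    a <- scan_anchor_points(co, fx$embedded, period(91, 180),
                            n_per_axis = 41),
    "no deaths")
  expect_equal(nrow(a$anchors), 0)
})

test_that("cross-validated screening flags the planted period", {
  fx <- planted_fixture()
  cv <- cross_validate_period(fx$cohort, fx$embedded, period(91, 180),
                              k = 5, seed = 1, n_per_axis = 41)
  expect_lt(cv$p, 0.05)
  expect_gt(cv$hr, 1)
  expect_error(
    cross_validate_period(fx$cohort, fx$embedded, period(91, 180),
                          k = 10000, seed = 1),
    "number of patients")
})

test_that("null cohorts rarely pass the cross-validated screen", {
  nulls <- cached("null_cv", {
    sim <- simulate_cohort(sim_config(n_patients = 250, derail_fraction = 0,
                                      seed = 31))
    sc <- fit_rescaler(sim$cohort$profiles)
    rows <- sim$cohort$profiles$day >= 91 & sim$cohort$profiles$day <= 180
    pe <- sim$cohort$profiles[rows, ]
    emb <- embed_profiles(apply_rescaler(sc, pe), pe$patient_id, pe$day,
                          seed = 0, perplexity = 20)
    ps <- vapply(1:12, function(s) {
      suppressWarnings(
        cross_validate_period(sim$cohort, emb, period(91, 180), k = 4,
                              seed = s, n_per_axis = 21))$p
    }, numeric(1))
    ps
  })
  expect_lte(mean(nulls < 0.05, na.rm = TRUE), 0.25)
})
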