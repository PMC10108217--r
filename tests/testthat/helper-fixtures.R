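# Shared fixtures and independent oracles, all built in code.

# A tiny, fully valid profile table with hand-chosen values.
tiny_profiles <- function() {
  df <- data.frame(
    patient_id = c("A", "A", "B"),
    day = c(100, 170, 95),
    wbc = c(4.0, 5.0, 6.0), neut = c(2.0, 2.5, 3.5),
    eos = c(0.1, 0.1, 0.2), baso = c(0.02, 0.03, 0.05),
    mono = c(0.4, 0.5, 0.45), lymph = c(1.48, 1.87, 1.80),
    mono_frac_nuc = c(0.10, 0.10, 0.075),
    lymph_frac_nuc = c(0.37, 0.374, 0.30),
    nk_frac = c(0.15, 0.20, 0.10), t_frac = c(0.60, 0.55, 0.70),
    cd4_frac = c(0.25, 0.20, 0.30), cd8_frac = c(0.30, 0.30, 0.35),
    treg_frac = c(0.03, 0.02, 0.04), b_frac = c(0.10, 0.15, 0.12)
  )
  for (f in c("nk_count", "t_count", "cd4_count", "cd8_count",
              "treg_count", "b_count")) df[[f]] <- NA_real_
  derive_counts(df)
}

tiny_outcomes <- function() {
  data.frame(
    patient_id = c("A", "B"), age = c(34, 12), sex = c("M", "F"),
    primary_disease = c("ALL_AML", "BMF"), transplant_type = c("MSD", "UCB"),
    conditioning = c("MAC", "RIC"), atg_used = c(TRUE, FALSE),
    os_time = c(400, 900), death = c(TRUE, FALSE),
    cause = c("infection_nrm", "none"), severe_agvhd_100d = c(FALSE, TRUE),
    infections_p1 = c(1L, 0L), infections_p2 = c(0L, 0L),
    infections_p3 = c(0L, 1L), infections_p4 = c(0L, 0L),
    cohort_split = c("training", "training")
  )
}

tiny_cohort <- function() cohort(tiny_profiles(), tiny_outcomes())

# Cache moderately expensive simulated objects across test files.
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A planted cohort with its scaled/embedded days-91-180 profiles.
planted_fixture <- function(n = 1000, seed = 7) {
  cached(sprintf("planted_%d_%d", n, seed), {
    sim <- simulate_cohort(sim_config(n_patients = n, seed = seed))
    sc <- fit_rescaler(sim$cohort$profiles)
    rows <- sim$cohort$profiles$day >= 91 & sim$cohort$profiles$day <= 180
    pe <- sim$cohort$profiles[rows, ]
    emb <- embed_profiles(apply_rescaler(sc, pe), pe$patient_id, pe$day,
                          seed = 0)
    list(sim = sim, cohort = sim$cohort, truth = sim$truth, embedded = emb)
  })
}

# Independent Efron-ties Cox partial log-likelihood for one binary
# covariate, written from the definition (risk sets enumerated directly).
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t0 in sort(unique(time[status == 1]))) {
    D <- which(time == t0 & status == 1)
    R <- which(time >= t0)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

# Exhaustive best-subset logistic AIC over <= 8 candidates.
best_subset_aic <- function(dat, candidates) {
  best <- list(aic = Inf, set = character(0))
  for (m in 0:(2^length(candidates) - 1)) {
    set <- candidates[bitwAnd(m, 2^(seq_along(candidates) - 1)) > 0]
    fml <- if (length(set) == 0) ".y ~ 1" else
      paste(".y ~", paste(set, collapse = " + "))
    a <- stats::AIC(stats::glm(stats::as.formula(fml),
                               family = stats::binomial(), data = dat))
    if (a < best$aic - 1e-9) best <- list(aic = a, set = set)
  }
  best
}

# Mean silhouette width of true labels in a 2D embedding.
mean_silhouette <- function(xy, labels) {
  s <- cluster::silhouette(as.integer(factor(labels)), stats::dist(xy))
  mean(s[, "sil_width"])
}
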