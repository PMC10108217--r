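#' Embed scaled immune profiles into the 2D phase space
#'
#' Projects min-max-scaled profiles onto a two-dimensional plane with
#' t-distributed stochastic neighbor embedding (Barnes-Hut, PCA
#' initialisation). Coordinates are centred per axis so downstream grid
#' geometry is reproducible. Deterministic given `seed`.
#'
#' @param scaled_matrix numeric matrix from [apply_rescaler()] (rows =
#'   profiles).
#' @param patient_id,day optional per-row identifiers carried into the
#'   result.
#' @param perplexity t-SNE perplexity (requires
#'   `nrow >= 3 * perplexity + 1`).
#' @param n_iter gradient-descent iterations.
#' @param seed RNG seed for the embedding.
#' @return data.frame `patient_id`, `day`, `x`, `y` (class
#'   `cirs_embedding`).
#' @export
embed_profiles <- function(scaled_matrix, patient_id = NULL, day = NULL,
                           perplexity = 30, n_iter = 1000, seed = 0) {
  scaled_matrix <- as.matrix(scaled_matrix)
  n <- nrow(scaled_matrix)
  if (n < 3 * perplexity + 1) {
    stop(sprintf(paste("embed_profiles: %d rows is too few for perplexity",
                       "%g (need >= %d); lower the perplexity"),
                 n, perplexity, ceiling(3 * perplexity + 1)), call. = FALSE)
  }
  if (anyNA(scaled_matrix)) {
    stop("embed_profiles: scaled matrix contains missing values", call. = FALSE)
  }
  force(perplexity); force(n_iter)  # keep lazy args out of the seeded region
  fit <- with_seed(seed, {
    Rtsne::Rtsne(scaled_matrix, dims = 2, perplexity = perplexity,
                 max_iter = n_iter, pca = TRUE, partial_pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE)
  })
  xy <- scale(fit$Y, center = TRUE, scale = FALSE)
  out <- data.frame(
    patient_id = if (is.null(patient_id)) seq_len(n) else patient_id,
    day = if (is.null(day)) rep(NA_real_, n) else day,
    x = xy[, 1], y = xy[, 2]
  )
  class(out) <- c("cirs_embedding", "data.frame")
  out
}

#' Per-feature linear gradients across the phase space
#'
#' For each feature f, fits the ordinary least-squares model
#' `f = c + alpha * x + beta * y + e` over the embedded profiles, so alpha
#' and beta quantify how the feature varies along the horizontal and
#' vertical axes.
#'
#' @param embedded a `cirs_embedding` (or data.frame with `x`, `y`).
#' @param feature_values data.frame / matrix of feature columns, one row per
#'   embedded profile.
#' @return data.frame with one row per feature: `feature`, `c`, `alpha`,
#'   `beta`, `sigma2` (residual variance).
#' @export
fit_axis_gradients <- function(embedded, feature_values) {
  feature_values <- as.data.frame(feature_values)
  if (nrow(feature_values) != nrow(embedded)) {
    stop("fit_axis_gradients: row mismatch between embedding and features",
         call. = FALSE)
  }
  if (nrow(embedded) < 3) {
    stop("fit_axis_gradients needs at least 3 points", call. = FALSE)
  }
  X <- cbind(1, embedded$x, embedded$y)
  if (qr(X)$rank < 3) {
    stop("fit_axis_gradients: coordinates are collinear (singular design)",
         call. = FALSE)
  }
  fits <- lapply(names(feature_values), function(f) {
    y <- feature_values[[f]]
    cf <- stats::lm.fit(X, y)
    res <- cf$residuals
    data.frame(feature = f, c = cf$coefficients[1],
               alpha = cf$coefficients[2], beta = cf$coefficients[3],
               sigma2 = sum(res^2) / max(1, length(y) - 3))
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

# Window half-width rule: delta_t = 30 d for 0 < t <= 90, 90 d for
# 90 < t <= 360, 180 d beyond.
trajectory_delta_t <- function(t) {
  if (any(t <= 0)) stop("trajectory times must be positive", call. = FALSE)
  ifelse(t <= 90, 30, ifelse(t <= 360, 90, 180))
}

#' Bootstrap average trajectory through the phase space
#'
#' The average location at time t is estimated from all profiles collected
#' in the closed window `[t - delta_t/2, t + delta_t/2]`, where the window
#' width grows with follow-up time (30 d up to day 90, 90 d up to day 360,
#' 180 d after). The point estimate is the mean of per-sample means across
#' `n_boot` bootstrap resamples of the in-window profiles; `sd_x`/`sd_y`
#' are the population SDs of the in-window profile coordinates. Empty
#' windows are dropped with a warning.
#'
#' @param embedded a `cirs_embedding` with a `day` column.
#' @param times evaluation days (positive).
#' @param n_boot bootstrap samples (100 by default).
#' @param seed RNG seed for the resampling.
#' @param resample set `FALSE` to use the plain window mean (degenerate
#'   bootstrap, for checking).
#' @return data.frame: `t`, `delta_t`, `mean_x`, `mean_y`, `sd_x`, `sd_y`,
#'   `n_profiles`.
#' @export
average_trajectory <- function(embedded, times, n_boot = 100, seed = 0,
                               resample = TRUE) {
  force(embedded)  # must not be forced lazily inside the seeded region
  force(n_boot); force(resample)
  dt <- trajectory_delta_t(times)
  rows <- with_seed(seed, lapply(seq_along(times), function(k) {
    t0 <- times[k]
    inw <- which(embedded$day >= t0 - dt[k] / 2 &
                   embedded$day <= t0 + dt[k] / 2)
    if (length(inw) == 0) {
      warning(sprintf("no profiles in window around t = %g; point omitted",
                      t0), call. = FALSE)
      return(NULL)
    }
    # canonical row order so trajectory means are invariant to how the
    # profile table happened to be sorted
    ord <- order(embedded$patient_id[inw], embedded$day[inw],
                 embedded$x[inw], embedded$y[inw])
    inw <- inw[ord]
    xs <- embedded$x[inw]
    ys <- embedded$y[inw]
    if (resample) {
      bm <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(inw), replace = TRUE)
        c(mean(xs[idx]), mean(ys[idx]))
      }, numeric(2))
      mx <- mean(bm[1, ]); my <- mean(bm[2, ])
    } else {
      mx <- mean(xs); my <- mean(ys)
    }
    pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
    data.frame(t = t0, delta_t = dt[k], mean_x = mx, mean_y = my,
               sd_x = pop_sd(xs), sd_y = pop_sd(ys),
               n_profiles = length(inw))
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-patient variance of immune status over time
#'
#' For each evaluation day t, each patient's in-window profiles (same window
#' rule as [average_trajectory()]) are averaged to one location; the
#' between-patient variance is the population variance (divide by n) of
#' those locations per axis, summed over the two axes.
#'
#' @inheritParams average_trajectory
#' @return data.frame: `t`, `variance`, `n_patients`.
#' @export
variance_over_time <- function(embedded, times) {
  dt <- trajectory_delta_t(times)
  rows <- lapply(seq_along(times), function(k) {
    t0 <- times[k]
    inw <- embedded$day >= t0 - dt[k] / 2 & embedded$day <= t0 + dt[k] / 2
    if (!any(inw)) return(NULL)
    mx <- tapply(embedded$x[inw], embedded$patient_id[inw], mean)
    my <- tapply(embedded$y[inw], embedded$patient_id[inw], mean)
    pop_var <- function(v) mean((v - mean(v))^2)
    data.frame(t = t0, variance = pop_var(mx) + pop_var(my),
               n_patients = length(mx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
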