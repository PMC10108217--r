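#' Overlay a regular grid on the phase space
#'
#' The grid spans the bounding box of the embedded coordinates with
#' `n_per_axis` equally spaced values per axis (121 by default, i.e. 14,641
#' grid points), endpoints included, returned in row-major order (y varies
#' fastest within x).
#'
#' @param embedded a `cirs_embedding` (or data.frame with `x`, `y`).
#' @param n_per_axis grid resolution per axis.
#' @return data.frame `x`, `y` of grid coordinates, with attributes
#'   `n_per_axis`, `x_range`, `y_range`.
#' @export
build_grid <- function(embedded, n_per_axis = 121) {
  if (nrow(unique(embedded[, c("x", "y")])) < 2) {
    stop("build_grid needs at least 2 distinct coordinates", call. = FALSE)
  }
  xr <- range(embedded$x)
  yr <- range(embedded$y)
  if (diff(xr) <= 0 || diff(yr) <= 0) {
    stop("build_grid: degenerate bounding box (zero extent on an axis)",
         call. = FALSE)
  }
  xs <- seq(xr[1], xr[2], length.out = n_per_axis)
  ys <- seq(yr[1], yr[2], length.out = n_per_axis)
  out <- data.frame(x = rep(xs, each = n_per_axis),
                    y = rep(ys, times = n_per_axis))
  attr(out, "n_per_axis") <- n_per_axis
  attr(out, "x_range") <- xr
  attr(out, "y_range") <- yr
  out
}

#' Nearness labels for one grid point
#'
#' A patient is "near" a grid point if any of their (in-window) profiles
#' lies within Euclidean distance `radius` of it, boundary inclusive. With
#' `spans` set to the axis spans, distance is computed on span-normalised
#' axes, making the neighbourhood elliptical in raw units.
#'
#' @param grid_point numeric length-2 `(x, y)`.
#' @param embedded data.frame with `patient_id`, `x`, `y` (already windowed
#'   to the analysis period).
#' @param radius nearness radius (> 0), in the same units as the
#'   coordinates after dividing by `spans`.
#' @param spans per-axis scale divisors (default `c(1, 1)`: raw Euclidean).
#' @return Named logical vector, one element per patient present in
#'   `embedded`.
#' @export
near_labels <- function(grid_point, embedded, radius, spans = c(1, 1)) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("near_labels: `radius` must be > 0", call. = FALSE)
  }
  d2 <- ((embedded$x - grid_point[1]) / spans[1])^2 +
    ((embedded$y - grid_point[2]) / spans[2])^2
  near <- tapply(d2 <= radius^2, embedded$patient_id, any)
  stats::setNames(as.logical(near), names(near))
}

# In-window profile coordinates on span-normalised axes, restricted to a
# patient set; shared by the scan and signature assignment.
normalise_embedding <- function(embedded, period, x_range, y_range) {
  inw <- embedded$day >= period$start_day & embedded$day <= period$end_day
  e <- embedded[inw, , drop = FALSE]
  e$ux <- (e$x - x_range[1]) / diff(x_range)
  e$uy <- (e$y - y_range[1]) / diff(y_range)
  e
}

# leakage guard used by the pipeline: discovery stages must only ever see
# training-split outcomes
assert_split <- function(outcomes, allowed_split) {
  if (is.null(allowed_split)) return(invisible(TRUE))
  if (!"cohort_split" %in% names(outcomes)) {
    stop("leakage guard: outcomes carry no `cohort_split` column",
         call. = FALSE)
  }
  bad <- setdiff(unique(outcomes$cohort_split), allowed_split)
  if (length(bad) > 0) {
    stop("leakage guard: discovery stage handed outcomes from split(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Grid scan for anchor points
#'
#' For every grid point, the patients with in-window profiles are split into
#' those near the point and those not, and a univariate Cox proportional
#' hazards model (Efron ties) of all-cause death is fitted on that binary
#' label. Survival time starts at the landmark (the period's end day by
#' default); patients who died or were censored on or before the landmark
#' are excluded. Grid points where either group has fewer than `min_group`
#' patients are assigned p = 1 without fitting. Grid points with p < `alpha`
#' are the anchor points. The raw p-value surface is uncorrected for
#' multiplicity by design: the safeguard is validation on held-out data.
#'
#' @param cohort a `cirs_cohort`.
#' @param embedded a `cirs_embedding` of (at least) the cohort's in-window
#'   profiles.
#' @param period the analysis [period()].
#' @param n_per_axis grid resolution (121 by default).
#' @param radius nearness radius on span-normalised axes; defaults to two
#'   grid steps, `2 / (n_per_axis - 1)`.
#' @param alpha anchor significance threshold on the raw Cox p-value.
#' @param landmark_day survival clock origin; defaults to the period's end.
#' @param min_group minimum patients required in each of the near/far
#'   groups for a grid point to be testable.
#' @param allowed_split if non-NULL, error unless every outcome row belongs
#'   to the given split(s) (leakage guard used by [run_discovery()]).
#' @return A `cirs_anchors` object: list with `grid` (data.frame `x`, `y`,
#'   `p`, `hr`, `n_near`, `testable`), `anchors` (the anchor subset),
#'   `radius`, `alpha`, `period`, `landmark_day`, ranges and counts.
#' @export
scan_anchor_points <- function(cohort, embedded, period, n_per_axis = 121,
                               radius = 2 / (n_per_axis - 1), alpha = 0.01,
                               landmark_day = period$end_day, min_group = 5,
                               allowed_split = NULL) {
  stopifnot(inherits(cohort, "cirs_cohort"), inherits(period, "cirs_period"))
  assert_split(cohort$outcomes, allowed_split)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)

  grid <- build_grid(embedded, n_per_axis)
  xr <- attr(grid, "x_range")
  yr <- attr(grid, "y_range")
  e <- normalise_embedding(embedded, period, xr, yr)

  out_grid <- data.frame(x = grid$x, y = grid$y, p = 1, hr = NA_real_,
                         n_near = 0L, testable = FALSE)
  empty <- function(msg) {
    warning(msg, call. = FALSE)
    structure(list(grid = out_grid,
                   anchors = out_grid[0, ], radius = radius, alpha = alpha,
                   period = period, landmark_day = landmark_day,
                   n_per_axis = n_per_axis, x_range = xr, y_range = yr,
                   n_patients = 0L, n_events = 0L),
              class = "cirs_anchors")
  }

  # risk set: in-window data and still at risk at the landmark
  oc <- cohort$outcomes
  at_risk <- oc$os_time > landmark_day
  ids <- intersect(unique(e$patient_id), oc$patient_id[at_risk])
  if (length(ids) == 0) return(empty("no patients at risk after the landmark"))
  oc <- oc[match(ids, oc$patient_id), , drop = FALSE]
  time <- oc$os_time - landmark_day
  status <- as.integer(as.logical(oc$death))
  if (sum(status) == 0) {
    return(empty("no deaths after the landmark; empty anchor set"))
  }
  e <- e[e$patient_id %in% ids, , drop = FALSE]
  pat_idx <- match(e$patient_id, ids)

  # invert the neighbourhood: for each profile, the grid cells within radius
  h <- 1 / (n_per_axis - 1)
  pair_g <- vector("list", nrow(e))
  for (pr in seq_len(nrow(e))) {
    ux <- e$ux[pr]; uy <- e$uy[pr]
    i_lo <- max(1L, as.integer(ceiling((ux - radius) / h)) + 1L)
    i_hi <- min(n_per_axis, as.integer(floor((ux + radius) / h)) + 1L)
    if (i_lo > i_hi) next
    cells <- integer(0)
    for (i in i_lo:i_hi) {
      dx <- (i - 1L) * h - ux
      rem2 <- radius^2 - dx^2
      if (rem2 < 0) next
      rem <- sqrt(rem2)
      j_lo <- max(1L, as.integer(ceiling((uy - rem) / h)) + 1L)
      j_hi <- min(n_per_axis, as.integer(floor((uy + rem) / h)) + 1L)
      if (j_lo > j_hi) next
      js <- j_lo:j_hi
      js <- js[((js - 1L) * h - uy)^2 <= rem2 + 1e-15]
      if (length(js) > 0) cells <- c(cells, (i - 1L) * n_per_axis + js)
    }
    pair_g[[pr]] <- cells
  }
  glen <- lengths(pair_g)
  pairs_grid <- unlist(pair_g, use.names = FALSE)
  pairs_pat <- rep(pat_idx, glen)
  near_sets <- lapply(split(pairs_pat, pairs_grid), unique)

  n_pat <- length(ids)
  for (gk in names(near_sets)) {
    gi <- as.integer(gk)
    pats <- near_sets[[gk]]
    out_grid$n_near[gi] <- length(pats)
    if (length(pats) < min_group || n_pat - length(pats) < min_group) next
    lab <- logical(n_pat)
    lab[pats] <- TRUE
    res <- cox_wald_uni(time, status, lab)
    out_grid$p[gi] <- res[["p"]]
    out_grid$hr[gi] <- res[["hr"]]
    out_grid$testable[gi] <- TRUE
  }

  anchors <- out_grid[out_grid$testable & out_grid$p < alpha, , drop = FALSE]
  structure(list(grid = out_grid, anchors = anchors, radius = radius,
                 alpha = alpha, period = period, landmark_day = landmark_day,
                 n_per_axis = n_per_axis, x_range = xr, y_range = yr,
                 n_patients = n_pat, n_events = sum(status)),
            class = "cirs_anchors")
}

#' @export
print.cirs_anchors <- function(x, ...) {
  cat(sprintf(paste0("<cirs_anchors> days %d-%d: %d anchor(s) among %d",
                     " testable of %d grid points\n"),
              x$period$start_day, x$period$end_day, nrow(x$anchors),
              sum(x$grid$testable), nrow(x$grid)))
  cat(sprintf("  radius %.4g (normalised), alpha %g, landmark day %g, %d patients / %d events\n",
              x$radius, x$alpha, x$landmark_day, x$n_patients, x$n_events))
  invisible(x)
}

#' Assign the high-risk composite immune signature
#'
#' A patient carries the signature for a period if any of their in-window
#' profiles lies within the scan radius of any anchor point. Patients with
#' no in-window profile are excluded, not labelled negative.
#'
#' @param cohort a `cirs_cohort`.
#' @param embedded a `cirs_embedding`.
#' @param anchors a `cirs_anchors` from [scan_anchor_points()].
#' @param period the analysis [period()]; defaults to the anchors' period.
#' @return data.frame `patient_id`, `signature` (logical),
#'   `nearest_anchor_dist` (span-normalised units; `Inf` when the anchor
#'   set is empty).
#' @export
assign_signature <- function(cohort, embedded, anchors,
                             period = anchors$period) {
  stopifnot(inherits(anchors, "cirs_anchors"))
  e <- normalise_embedding(embedded, period, anchors$x_range, anchors$y_range)
  e <- e[e$patient_id %in% cohort$outcomes$patient_id, , drop = FALSE]
  ids <- unique(e$patient_id)
  if (nrow(anchors$anchors) == 0) {
    return(data.frame(patient_id = ids, signature = FALSE,
                      nearest_anchor_dist = Inf))
  }
  ax <- (anchors$anchors$x - anchors$x_range[1]) / diff(anchors$x_range)
  ay <- (anchors$anchors$y - anchors$y_range[1]) / diff(anchors$y_range)
  # per profile, distance to the closest anchor
  dmin <- rep(Inf, nrow(e))
  for (a in seq_along(ax)) {
    d2 <- (e$ux - ax[a])^2 + (e$uy - ay[a])^2
    dmin <- pmin(dmin, d2)
  }
  dmin <- sqrt(dmin)
  pat_min <- tapply(dmin, e$patient_id, min)
  data.frame(patient_id = names(pat_min),
             signature = as.numeric(pat_min) <= anchors$radius,
             nearest_anchor_dist = as.numeric(pat_min),
             row.names = NULL)
}

#' Ten-fold cross-validated screening of a candidate period
#'
#' Patients are partitioned into `k` seeded folds. For each fold, anchors
#' are discovered on the other folds' patients only, the held-out patients'
#' signature labels are recorded, and after all folds the pooled held-out
#' labels are tested with one Cox regression of post-landmark all-cause
#' death. A small pooled p-value indicates a reproducible high-risk region
#' in that period. Run this on the training split only.
#'
#' @inheritParams scan_anchor_points
#' @param k number of folds (>= 2, <= number of patients).
#' @param seed RNG seed for the fold assignment.
#' @return list with `p`, `hr`, `labels` (pooled held-out signature table),
#'   `period`, `k`.
#' @export
cross_validate_period <- function(cohort, embedded, period, k = 10,
                                  seed = 0, n_per_axis = 121,
                                  radius = 2 / (n_per_axis - 1),
                                  alpha = 0.01,
                                  landmark_day = period$end_day,
                                  min_group = 5, allowed_split = NULL) {
  stopifnot(inherits(cohort, "cirs_cohort"))
  assert_split(cohort$outcomes, allowed_split)
  ids <- cohort$outcomes$patient_id
  if (k < 2 || k > length(ids)) {
    stop("`k` must be between 2 and the number of patients", call. = FALSE)
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(k), length(ids))))
  lab_list <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- ids[fold != f]
    test_ids <- ids[fold == f]
    co_tr <- cohort
    co_tr$outcomes <- cohort$outcomes[cohort$outcomes$patient_id %in%
                                        train_ids, , drop = FALSE]
    co_tr$profiles <- cohort$profiles[cohort$profiles$patient_id %in%
                                        train_ids, , drop = FALSE]
    emb_tr <- embedded[embedded$patient_id %in% train_ids, , drop = FALSE]
    if (nrow(emb_tr) == 0) {
      warning(sprintf("fold %d has no in-window training profiles; skipped",
                      f), call. = FALSE)
      next
    }
    anch <- suppressWarnings(
      scan_anchor_points(co_tr, emb_tr, period, n_per_axis = n_per_axis,
                         radius = radius, alpha = alpha,
                         landmark_day = landmark_day, min_group = min_group))
    co_te <- cohort
    co_te$outcomes <- cohort$outcomes[cohort$outcomes$patient_id %in%
                                        test_ids, , drop = FALSE]
    sig <- assign_signature(co_te, embedded, anch, period)
    if (nrow(sig) > 0) lab_list[[f]] <- sig
  }
  labels <- do.call(rbind, lab_list)
  if (is.null(labels) || nrow(labels) == 0) {
    return(list(p = NA_real_, hr = NA_real_, labels = NULL,
                period = period, k = k))
  }
  oc <- cohort$outcomes[match(labels$patient_id,
                              cohort$outcomes$patient_id), , drop = FALSE]
  keep <- oc$os_time > landmark_day
  res <- cox_wald_uni(oc$os_time[keep] - landmark_day,
                      as.integer(as.logical(oc$death[keep])),
                      labels$signature[keep])
  list(p = res[["p"]], hr = res[["hr"]], labels = labels,
       period = period, k = k)
}
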