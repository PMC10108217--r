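#' Min-max rescaling of the 20 profile features
#'
#' The embedding operates on features linearly rescaled so that, over the
#' fitted profile set, every feature runs from 0 (its observed minimum) to 1
#' (its observed maximum). The map is fitted once on the full profile set
#' under analysis and then frozen; profiles transformed later are clipped
#' into \[0, 1\] so they cannot leave the fitted range.
#'
#' @param profiles data.frame containing the feature columns.
#' @param features feature names; defaults to all 20 of
#'   [profile_features()].
#' @return `fit_rescaler`: a `cirs_scaler` holding per-feature min and max.
#' @export
fit_rescaler <- function(profiles, features = profile_features()) {
  miss <- setdiff(features, names(profiles))
  if (length(miss) > 0) {
    stop("fit_rescaler: missing feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(profiles) < 2) {
    stop("fit_rescaler needs at least 2 profiles", call. = FALSE)
  }
  mins <- vapply(profiles[features], min, numeric(1), na.rm = TRUE)
  maxs <- vapply(profiles[features], max, numeric(1), na.rm = TRUE)
  const <- maxs <= mins
  if (any(const)) {
    warning("constant feature(s) mapped to 0: ",
            paste(features[const], collapse = ", "), call. = FALSE)
  }
  structure(list(features = features, min = mins, max = maxs),
            class = "cirs_scaler")
}

#' @rdname fit_rescaler
#' @param map a `cirs_scaler` from `fit_rescaler`.
#' @return `apply_rescaler`: numeric matrix (rows = profiles, columns =
#'   features) with every value in \[0, 1\].
#' @export
apply_rescaler <- function(map, profiles) {
  stopifnot(inherits(map, "cirs_scaler"))
  miss <- setdiff(map$features, names(profiles))
  if (length(miss) > 0) {
    stop("apply_rescaler: missing feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(profiles), length(map$features),
                dimnames = list(NULL, map$features))
  for (f in map$features) {
    span <- map$max[[f]] - map$min[[f]]
    out[, f] <- if (span <= 0) 0 else (profiles[[f]] - map$min[[f]]) / span
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
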