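#' Post-transplant time periods
#'
#' A period is a closed integer interval of days post-transplant (both
#' endpoints included). Day 1 is the first day after transplant. The four
#' canonical screening periods are days 1-90, 91-180, 181-270 and 271-360.
#'
#' @param start_day,end_day closed interval bounds in days (> 0).
#' @param label optional label; defaults to `"start-end"`.
#' @return A `cirs_period` list with `label`, `start_day`, `end_day`.
#' @export
period <- function(start_day, end_day,
                   label = paste0(start_day, "-", end_day)) {
  if (!is.numeric(start_day) || !is.numeric(end_day) ||
      start_day <= 0 || end_day < start_day) {
    stop("period requires 0 < start_day <= end_day", call. = FALSE)
  }
  structure(list(label = label, start_day = start_day, end_day = end_day),
            class = "cirs_period")
}

#' @rdname period
#' @export
canonical_periods <- function() {
  list(period(1, 90), period(91, 180), period(181, 270), period(271, 360))
}

#' @export
print.cirs_period <- function(x, ...) {
  cat(sprintf("<period> days %d-%d\n", x$start_day, x$end_day))
  invisible(x)
}

#' Select each patient's profiles inside a period
#'
#' Boundary days are inclusive on both ends. Patients with no in-window
#' profile are reported in the `absent` attribute rather than imputed.
#'
#' @param x a `cirs_cohort` or a profiles data.frame.
#' @param period a [period()].
#' @return A named list (one data.frame of profiles per patient with at least
#'   one in-window profile), with attribute `absent` holding the patient ids
#'   that have none.
#' @export
window_profiles <- function(x, period) {
  profiles <- if (inherits(x, "cirs_cohort")) x$profiles else x
  stopifnot(inherits(period, "cirs_period"))
  inw <- profiles$day >= period$start_day & profiles$day <= period$end_day
  win <- profiles[inw, , drop = FALSE]
  out <- split(win, win$patient_id)
  all_ids <- unique(profiles$patient_id)
  attr(out, "absent") <- setdiff(all_ids, names(out))
  out
}

#' Per-patient mean of one feature over a period
#'
#' @inheritParams window_profiles
#' @param feature one of [profile_features()].
#' @return Named numeric vector over all patients present in the profile
#'   table; `NA` for patients without in-window profiles.
#' @export
average_features <- function(x, period, feature) {
  profiles <- if (inherits(x, "cirs_cohort")) x$profiles else x
  if (!feature %in% names(profiles)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  wins <- window_profiles(profiles, period)
  ids <- unique(profiles$patient_id)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  got <- vapply(wins, function(df) mean(df[[feature]]), numeric(1))
  out[names(got)] <- got
  out
}

#' Per-patient window means for all 20 features
#'
#' Convenience wrapper used by the score-fitting stage: one row per patient
#' with at least one in-window profile, columns are the window means of the
#' 20 profile features.
#'
#' @inheritParams window_profiles
#' @return data.frame with `patient_id` and the 20 feature means.
#' @export
period_feature_matrix <- function(x, period) {
  profiles <- if (inherits(x, "cirs_cohort")) x$profiles else x
  wins <- window_profiles(profiles, period)
  feats <- profile_features()
  rows <- lapply(wins, function(df) colMeans(df[feats]))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(patient_id = names(wins), out)
  rownames(out) <- NULL
  out
}
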