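#' The 20 immune-profile features
#'
#' One immune profile is a single blood draw summarised by 20 clinical
#' features: six complete-blood-count cell counts (10^9/L), two fractions of
#' nucleated cells, six flow-cytometry fractions of lymphocytes, and six
#' lymphocyte-subset counts derived as lymphocyte count times the matching
#' fraction.
#'
#' @return Character vector of the 20 feature column names, in canonical
#'   order.
#' @export
profile_features <- function() {
  c("wbc", "neut", "eos", "baso", "mono", "lymph",
    "mono_frac_nuc", "lymph_frac_nuc",
    "nk_frac", "t_frac", "cd4_frac", "cd8_frac", "treg_frac", "b_frac",
    "nk_count", "t_count", "cd4_count", "cd8_count", "treg_count", "b_count")
}

.count_features <- function() {
  c("wbc", "neut", "eos", "baso", "mono", "lymph",
    "nk_count", "t_count", "cd4_count", "cd8_count", "treg_count", "b_count")
}

.frac_features <- function() {
  c("mono_frac_nuc", "lymph_frac_nuc",
    "nk_frac", "t_frac", "cd4_frac", "cd8_frac", "treg_frac", "b_frac")
}

# derived count -> source fraction
.derived_map <- c(nk_count = "nk_frac", t_count = "t_frac",
                  cd4_count = "cd4_frac", cd8_count = "cd8_frac",
                  treg_count = "treg_frac", b_count = "b_frac")

.outcome_cols <- function() {
  c("patient_id", "age", "sex", "primary_disease", "transplant_type",
    "conditioning", "atg_used", "os_time", "death", "cause",
    "severe_agvhd_100d", "infections_p1", "infections_p2",
    "infections_p3", "infections_p4", "cohort_split")
}

#' Construct a validated cohort
#'
#' A cohort bundles the longitudinal profile table (one row per blood draw)
#' with the per-patient outcome/covariate table. Hard invariant violations in
#' the profile table (negative counts, fractions outside \[0, 1\],
#' non-positive days) cause the offending rows to be rejected with a per-row
#' report; soft violations (lymphocyte count exceeding the white cell count)
#' only warn, since rounding in real laboratory exports can produce them.
#'
#' @param profiles data.frame with columns `patient_id`, `day`, and the 20
#'   features of [profile_features()].
#' @param outcomes data.frame with one row per patient: `patient_id`, `age`,
#'   `sex`, `primary_disease`, `transplant_type`, `conditioning`, `atg_used`,
#'   `os_time` (days), `death` (logical), `cause` (`relapse`,
#'   `infection_nrm`, `other_nrm`, `none`), `severe_agvhd_100d`,
#'   `infections_p1` .. `infections_p4`, `cohort_split`.
#' @return An object of class `cirs_cohort`: a list with elements `profiles`,
#'   `outcomes`, and `rejected` (the rejected profile rows with a `reason`
#'   column).
#' @export
cohort <- function(profiles, outcomes) {
  need_p <- c("patient_id", "day", profile_features())
  miss <- setdiff(need_p, names(profiles))
  if (length(miss) > 0) {
    stop("profiles table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss_o <- setdiff(c("patient_id", "os_time", "death", "cause"),
                    names(outcomes))
  if (length(miss_o) > 0) {
    stop("outcomes table is missing required column(s): ",
         paste(miss_o, collapse = ", "), call. = FALSE)
  }
  for (col in c("day", profile_features())) {
    if (!is.numeric(profiles[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(profiles[[col]]))) &
                     !is.na(profiles[[col]]))
      stop(sprintf("non-numeric value in profiles column `%s` (row %s)",
                   col, if (length(bad)) bad[1] else "?"), call. = FALSE)
    }
  }

  reason <- rep(NA_character_, nrow(profiles))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  flag(!is.finite(profiles$day) | profiles$day <= 0,
       "day must be a positive integer")
  for (col in .count_features()) {
    flag(is.finite(profiles[[col]]) & profiles[[col]] < 0,
         sprintf("count `%s` must be >= 0", col))
  }
  for (col in .frac_features()) {
    flag(is.finite(profiles[[col]]) &
           (profiles[[col]] < 0 | profiles[[col]] > 1),
         sprintf("fraction `%s` must lie in [0, 1]", col))
  }
  rejected <- profiles[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- reason[!is.na(reason)]
    warning(sprintf("rejected %d profile row(s) violating hard invariants; see $rejected",
                    nrow(rejected)), call. = FALSE)
    profiles <- profiles[is.na(reason), , drop = FALSE]
  }
  soft <- is.finite(profiles$lymph) & is.finite(profiles$wbc) &
    profiles$lymph > profiles$wbc + 1e-9
  if (any(soft)) {
    warning(sprintf("%d profile row(s) have lymph > wbc (kept; check units)",
                    sum(soft)), call. = FALSE)
  }

  if (!all(outcomes$os_time > 0)) {
    stop("outcomes: `os_time` must be > 0 for every patient", call. = FALSE)
  }
  death <- as.logical(outcomes$death)
  if (any((outcomes$cause == "none") != !death)) {
    stop("outcomes: `cause` must be 'none' exactly when `death` is FALSE",
         call. = FALSE)
  }
  rownames(profiles) <- NULL
  structure(list(profiles = profiles, outcomes = outcomes,
                 rejected = rejected),
            class = "cirs_cohort")
}

#' @export
print.cirs_cohort <- function(x, ...) {
  cat(sprintf("<cirs_cohort> %d profiles from %d patients (%d deaths)\n",
              nrow(x$profiles), nrow(x$outcomes),
              sum(as.logical(x$outcomes$death))))
  if (nrow(x$rejected) > 0) {
    cat(sprintf("  %d rejected profile rows\n", nrow(x$rejected)))
  }
  invisible(x)
}

#' Load a cohort from delimited text files
#'
#' Reads the two standard comma-separated tables (see [write_cohort()]) and
#' validates them through [cohort()].
#'
#' @param profiles_path path to the profiles CSV (columns `patient_id`,
#'   `day`, then the 20 features; fractions as proportions in \[0, 1\]).
#' @param outcomes_path path to the per-patient outcomes CSV.
#' @return A `cirs_cohort`.
#' @export
load_cohort <- function(profiles_path, outcomes_path) {
  for (p in c(profiles_path, outcomes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  profiles <- utils::read.csv(profiles_path, stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  if ("death" %in% names(outcomes)) outcomes$death <- as.logical(outcomes$death)
  if ("atg_used" %in% names(outcomes)) {
    outcomes$atg_used <- as.logical(outcomes$atg_used)
  }
  if ("severe_agvhd_100d" %in% names(outcomes)) {
    outcomes$severe_agvhd_100d <- as.logical(outcomes$severe_agvhd_100d)
  }
  cohort(profiles, outcomes)
}

#' Write a cohort (and optional ground truth) to CSV files
#'
#' @param x a `cirs_cohort`.
#' @param dir output directory (created if needed); writes `profiles.csv`
#'   and `outcomes.csv`.
#' @param truth optional ground-truth table (from [simulate_cohort()]),
#'   written as `ground_truth.csv`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir, truth = NULL) {
  stopifnot(inherits(x, "cirs_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(profiles = file.path(dir, "profiles.csv"),
             outcomes = file.path(dir, "outcomes.csv"))
  utils::write.csv(x$profiles, paths[["profiles"]], row.names = FALSE)
  utils::write.csv(x$outcomes, paths[["outcomes"]], row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "ground_truth.csv"))
    utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Recompute the six derived lymphocyte-subset counts
#'
#' Each derived count is the product of the lymphocyte count and the matching
#' fraction of lymphocytes (e.g. the NK cell count is lymphocyte count times
#' NK fraction). Other columns are left untouched; missing inputs propagate
#' as missing.
#'
#' @param profiles data.frame with at least `lymph` and the six subset
#'   fractions.
#' @return The data.frame with `nk_count`, `t_count`, `cd4_count`,
#'   `cd8_count`, `treg_count`, `b_count` (re)computed.
#' @export
derive_counts <- function(profiles) {
  need <- c("lymph", unname(.derived_map))
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    stop("derive_counts: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cnt in names(.derived_map)) {
    profiles[[cnt]] <- profiles$lymph * profiles[[.derived_map[[cnt]]]]
  }
  profiles
}
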