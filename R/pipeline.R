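#' Configuration for the end-to-end discovery run
#'
#' @param sim a [sim_config()] used when no cohort files are given.
#' @param profiles_path,outcomes_path optional CSV paths of a real cohort
#'   (see [load_cohort()]); when `NULL` a cohort is simulated from `sim`.
#' @param analysis_period the [period()] whose signature is discovered and
#'   distilled (days 91-180 by default).
#' @param screen_periods optional list of periods to screen first by
#'   cross-validated Cox p-value within the training split.
#' @param n_per_axis,radius,alpha,min_group grid-scan settings; see
#'   [scan_anchor_points()].
#' @param k_folds folds for the period screening.
#' @param perplexity,n_iter embedding settings; see [embed_profiles()].
#' @param split_fractions named training/validation/test fractions used when
#'   the cohort has no `cohort_split` column.
#' @param seed mandatory integer seed for every stochastic stage.
#' @return A `cirs_run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       profiles_path = NULL, outcomes_path = NULL,
                       analysis_period = period(91, 180),
                       screen_periods = NULL,
                       n_per_axis = 121,
                       radius = 2 / (n_per_axis - 1),
                       alpha = 0.01, min_group = 5, k_folds = 10,
                       perplexity = 30, n_iter = 1000,
                       split_fractions = c(training = 0.50,
                                           validation = 0.25, test = 0.25),
                       seed = 0) {
  if (is.null(seed) || !is.finite(seed)) stop_config("seed", "is mandatory")
  if (abs(sum(split_fractions) - 1) > 1e-9 || any(split_fractions <= 0)) {
    stop_config("split_fractions", "must be positive and sum to 1")
  }
  structure(list(sim = sim, profiles_path = profiles_path,
                 outcomes_path = outcomes_path,
                 analysis_period = analysis_period,
                 screen_periods = screen_periods,
                 n_per_axis = n_per_axis, radius = radius, alpha = alpha,
                 min_group = min_group, k_folds = k_folds,
                 perplexity = perplexity, n_iter = n_iter,
                 split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "cirs_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `sim` is a nested
#' map passed to [sim_config()], and periods are two-element `[start, end]`
#' sequences. `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A `cirs_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop_config("seed", "is mandatory in a config file")
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$analysis_period)) {
    args$analysis_period <- period(raw$analysis_period[[1]],
                                   raw$analysis_period[[2]])
  }
  if (!is.null(raw$screen_periods)) {
    args$screen_periods <- lapply(raw$screen_periods,
                                  function(p) period(p[[1]], p[[2]]))
  }
  for (k in c("profiles_path", "outcomes_path", "n_per_axis", "radius",
              "alpha", "min_group", "k_folds", "perplexity", "n_iter",
              "seed")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$split_fractions)) {
    args$split_fractions <- unlist(raw$split_fractions)
  }
  do.call(run_config, args)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(config, f, version = 3)
  unname(tools::md5sum(f))
}

#' Run the end-to-end signature discovery pipeline
#'
#' Simulates (or loads) a cohort, fits the min-max scaler on the full
#' profile set, embeds the profiles of the analysed periods into the phase
#' space, optionally screens candidate periods by cross-validated Cox
#' p-value within the training split, discovers anchor points and fits the
#' risk-score model on the training split only (a leakage guard errors if a
#' discovery stage is handed non-training outcomes), and then verifies the
#' fitted score by a landmark Cox model in each split separately.
#'
#' @param config a [run_config()].
#' @return A `cirs_run` object with `print`, `summary`, `coef` and `predict`
#'   methods. Key elements: `anchors`, `score_model`, `split_results`,
#'   `signature` (training labels), `scores`, `screening`, `truth` (for
#'   simulated cohorts), `config`, `config_hash`, `versions`.
#' @export
run_discovery <- function(config = run_config()) {
  stopifnot(inherits(config, "cirs_run_config"))
  simulated <- is.null(config$profiles_path)
  if (simulated) {
    sim <- simulate_cohort(config$sim)
    co <- sim$cohort
    truth <- sim$truth
  } else {
    co <- load_cohort(config$profiles_path, config$outcomes_path)
    truth <- NULL
  }
  if (!"cohort_split" %in% names(co$outcomes)) {
    co$outcomes$cohort_split <- with_seed(config$seed + 1L,
      sample(names(config$split_fractions), nrow(co$outcomes), TRUE,
             config$split_fractions))
  }
  splits <- c("training", "validation", "test")
  cnt <- table(factor(co$outcomes$cohort_split, levels = splits))
  if (any(cnt == 0)) {
    stop_config("split", paste("has empty subset(s):",
                               paste(splits[cnt == 0], collapse = ", ")))
  }

  scaler <- fit_rescaler(co$profiles)

  periods <- c(list(config$analysis_period), config$screen_periods)
  lo <- min(vapply(periods, `[[`, numeric(1), "start_day"))
  hi <- max(vapply(periods, `[[`, numeric(1), "end_day"))
  emb_rows <- co$profiles$day >= lo & co$profiles$day <= hi
  prof_emb <- co$profiles[emb_rows, , drop = FALSE]
  embedded <- embed_profiles(apply_rescaler(scaler, prof_emb),
                             patient_id = prof_emb$patient_id,
                             day = prof_emb$day,
                             perplexity = config$perplexity,
                             n_iter = config$n_iter, seed = config$seed)

  subset_cohort <- function(split) {
    out <- co
    out$outcomes <- co$outcomes[co$outcomes$cohort_split %in% split, ,
                                drop = FALSE]
    out$profiles <- co$profiles[co$profiles$patient_id %in%
                                  out$outcomes$patient_id, , drop = FALSE]
    out
  }
  co_train <- subset_cohort("training")
  emb_train <- embedded[embedded$patient_id %in%
                          co_train$outcomes$patient_id, , drop = FALSE]

  screening <- NULL
  if (!is.null(config$screen_periods)) {
    screening <- do.call(rbind, lapply(config$screen_periods, function(p) {
      cv <- cross_validate_period(co_train, emb_train, p,
                                  k = config$k_folds, seed = config$seed,
                                  n_per_axis = config$n_per_axis,
                                  radius = config$radius,
                                  alpha = config$alpha,
                                  min_group = config$min_group,
                                  allowed_split = "training")
      data.frame(period = p$label, p = cv$p, hr = cv$hr)
    }))
  }

  anchors <- scan_anchor_points(co_train, emb_train, config$analysis_period,
                                n_per_axis = config$n_per_axis,
                                radius = config$radius, alpha = config$alpha,
                                min_group = config$min_group,
                                allowed_split = "training")
  signature <- assign_signature(co_train, emb_train, anchors)

  score_model <- NULL
  if (nrow(anchors$anchors) > 0 && length(unique(signature$signature)) == 2) {
    feats <- period_feature_matrix(co_train, config$analysis_period)
    feats <- feats[match(signature$patient_id, feats$patient_id), ,
                   drop = FALSE]
    score_model <- fit_score_model(feats, signature$signature)
  } else {
    warning("no usable training signature; score model not fitted",
            call. = FALSE)
  }

  scores <- NULL
  split_results <- NULL
  if (!is.null(score_model)) {
    lmk <- anchors$landmark_day
    per_split <- lapply(splits, function(s) {
      cs <- subset_cohort(s)
      sc <- score_patient_period(cs, config$analysis_period, score_model)
      if (is.null(sc) || nrow(sc) == 0) return(NULL)
      sc$cohort_split <- s
      oc <- cs$outcomes[match(sc$patient_id, cs$outcomes$patient_id), ,
                        drop = FALSE]
      keep <- oc$os_time > lmk
      res <- cox_wald_uni(oc$os_time[keep] - lmk,
                          as.integer(as.logical(oc$death[keep])),
                          sc$risk[keep] == "high")
      list(scores = sc,
           row = data.frame(split = s, hr = res[["hr"]], p = res[["p"]],
                            n = sum(keep),
                            events = sum(as.logical(oc$death[keep])),
                            n_high = sum(sc$risk[keep] == "high")))
    })
    per_split <- per_split[!vapply(per_split, is.null, logical(1))]
    scores <- do.call(rbind, lapply(per_split, `[[`, "scores"))
    split_results <- do.call(rbind, lapply(per_split, `[[`, "row"))
    rownames(split_results) <- NULL
  }

  structure(list(config = config, seed = config$seed,
                 config_hash = config_hash(config),
                 versions = c(R = R.version.string,
                              cirs = as.character(
                                utils::packageVersion("cirs"))),
                 scaler = scaler, embedded = embedded, anchors = anchors,
                 signature = signature, score_model = score_model,
                 screening = screening, scores = scores,
                 split_results = split_results, truth = truth),
            class = "cirs_run")
}

#' Score patients with the published model only
#'
#' The calculator mode: applies the fixed published score to a single named
#' feature vector or to a table with the eight feature columns.
#'
#' @param x named numeric vector or data.frame.
#' @param threshold decision cutoff.
#' @return data.frame `score`, `risk`.
#' @export
run_score_only <- function(x, threshold = 2.50) {
  s <- published_score(x)
  data.frame(score = s, risk = classify_risk(s, threshold))
}

#' @export
print.cirs_run <- function(x, ...) {
  cat("<cirs_run>\n")
  print(x$anchors)
  if (!is.null(x$score_model)) print(x$score_model)
  if (!is.null(x$split_results)) {
    cat("split verification (landmark Cox, high vs low):\n")
    print(x$split_results, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cirs_run <- function(object, ...) {
  cat(sprintf("Discovery period: days %d-%d (landmark day %g)\n",
              object$anchors$period$start_day, object$anchors$period$end_day,
              object$anchors$landmark_day))
  if (!is.null(object$screening)) {
    cat("Cross-validated period screening (training split):\n")
    print(object$screening, row.names = FALSE)
  }
  print(object)
  invisible(object)
}

#' @export
coef.cirs_run <- function(object, ...) {
  if (is.null(object$score_model)) NULL else object$score_model$coefficients
}

#' @export
predict.cirs_run <- function(object, newdata, type = c("score", "risk"),
                             ...) {
  if (is.null(object$score_model)) {
    stop("this run fitted no score model", call. = FALSE)
  }
  predict(object$score_model, newdata, type = match.arg(type))
}
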