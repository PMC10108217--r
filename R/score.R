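new_cirs_model <- function(coefficients, intercept, threshold, provenance) {
  stopifnot(all(is.finite(coefficients)), is.finite(threshold))
  structure(list(coefficients = coefficients, intercept = intercept,
                 threshold = threshold, provenance = provenance),
            class = "cirs_model")
}

#' The published Composite Immune Risk Score
#'
#' The fixed eight-feature linear score for days 91-180 post-transplant,
#' with cell counts in 10^9/L and fractions as proportions in \[0, 1\]:
#'
#' \deqn{0.7304\,\mathrm{wbc} - 0.4745\,\mathrm{neut}
#'   - 16.7825\,\mathrm{lymph\_frac\_nuc} - 1.7612\,\mathrm{lymph}
#'   - 7.9450\,\mathrm{nk\_frac} + 10.2955\,\mathrm{t\_frac}
#'   - 7.9703\,\mathrm{cd4\_frac} - 15.7887\,\mathrm{b\_frac}}
#'
#' There is no intercept; a patient is deemed high-risk when the score
#' strictly exceeds 2.50.
#'
#' @return A `cirs_model` with provenance `"published"`.
#' @export
cirs_published <- function() {
  new_cirs_model(
    coefficients = c(wbc = 0.7304, neut = -0.4745,
                     lymph_frac_nuc = -16.7825, lymph = -1.7612,
                     nk_frac = -7.9450, t_frac = 10.2955,
                     cd4_frac = -7.9703, b_frac = -15.7887),
    intercept = NULL, threshold = 2.50, provenance = "published")
}

#' Evaluate the published score on one or more feature sets
#'
#' @param features named numeric vector, list, or data.frame providing the
#'   eight inputs `wbc`, `neut`, `lymph_frac_nuc`, `lymph`, `nk_frac`,
#'   `t_frac`, `cd4_frac`, `b_frac`. Counts in 10^9/L; fractions must be
#'   proportions in \[0, 1\] (percentages are rejected, not silently
#'   rescaled).
#' @return Numeric score(s): the bare weighted sum, no intercept.
#' @export
published_score <- function(features) {
  model <- cirs_published()
  score_features(model, features)
}

score_features <- function(model, features) {
  feats <- names(model$coefficients)
  if (is.data.frame(features)) {
    tab <- features
  } else {
    tab <- as.data.frame(as.list(unlist(features)))
  }
  miss <- setdiff(feats, names(tab))
  if (length(miss) > 0) {
    stop("missing score input(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(tab[feats])
  if (any(!is.finite(X))) {
    bad <- feats[apply(!is.finite(X), 2, any)]
    stop("non-finite score input(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  frac <- intersect(feats, .frac_features())
  bad <- frac[vapply(frac, function(f) any(X[, f] < 0 | X[, f] > 1),
                     logical(1))]
  if (length(bad) > 0) {
    stop("fraction input(s) outside [0, 1] (supply proportions, not percentages): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  drop(X %*% model$coefficients) +
    if (is.null(model$intercept)) 0 else model$intercept
}

#' Binarise a score into high/low risk
#'
#' High risk requires the score to strictly exceed the threshold: a score
#' exactly at the cutoff is low-risk.
#'
#' @param score numeric score(s).
#' @param threshold decision cutoff (2.50 for the published model).
#' @return character vector of `"high"` / `"low"`.
#' @export
classify_risk <- function(score, threshold = 2.50) {
  ifelse(score > threshold, "high", "low")
}

#' Score every patient over a period
#'
#' Each in-window profile is scored, profile scores are averaged per patient,
#' and the patient mean is thresholded. Patients without in-window profiles
#' are excluded.
#'
#' @param cohort a `cirs_cohort` (or profiles data.frame).
#' @param period a [period()].
#' @param model a `cirs_model`; the published score by default.
#' @return data.frame `patient_id`, `score`, `risk` (`"high"`/`"low"`).
#' @export
score_patient_period <- function(cohort, period, model = cirs_published()) {
  stopifnot(inherits(model, "cirs_model"))
  profiles <- if (inherits(cohort, "cirs_cohort")) cohort$profiles else cohort
  wins <- window_profiles(profiles, period)
  rows <- lapply(names(wins), function(id) {
    s <- mean(score_features(model, wins[[id]]))
    data.frame(patient_id = id, score = s,
               risk = classify_risk(s, model$threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distill a signature into a linear risk score
#'
#' Fits a logistic regression of the signature labels on the candidate
#' features with bidirectional (forward-and-backward) stepwise selection by
#' AIC, starting from the empty model. The reported score is the
#' intercept-free linear predictor, for interface parity with the published
#' formula; its decision threshold is set where Youden's J (sensitivity +
#' specificity - 1) against the supplied labels is maximal. Deterministic
#' given the input ordering (AIC ties resolve by candidate order).
#'
#' @param feature_table data.frame of candidate features (one row per
#'   patient), e.g. from [period_feature_matrix()].
#' @param labels logical signature labels, same length as rows.
#' @param candidates candidate feature names; defaults to all feature
#'   columns of `feature_table`.
#' @param coef_cap absolute coefficient size beyond which (quasi-)separation
#'   is declared and a ridge-stabilised refit is used.
#' @return A `cirs_model` with provenance `"fitted"` (the logistic
#'   intercept is kept in `$intercept_logit` for reference; `$intercept` is
#'   `NULL` so scores are intercept-free).
#' @export
fit_score_model <- function(feature_table, labels,
                            candidates = intersect(profile_features(),
                                                   names(feature_table)),
                            coef_cap = 20) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("fit_score_model: labels contain a single class", call. = FALSE)
  }
  if (length(labels) != nrow(feature_table)) {
    stop("fit_score_model: labels/features length mismatch", call. = FALSE)
  }
  if (sum(stats::complete.cases(feature_table[candidates])) < 20) {
    stop("fit_score_model needs >= 20 complete labelled patients",
         call. = FALSE)
  }
  dat <- feature_table[candidates]
  dat$.y <- labels
  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  scope <- stats::as.formula(paste("~", paste(candidates, collapse = " + ")))
  # separation shows up as non-convergence noise from glm.fit; it is
  # detected below via the coefficient cap, so keep the stepping quiet
  sel <- suppressWarnings(
    stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                direction = "both", trace = 0))
  cf <- stats::coef(sel)
  separated <- any(abs(cf) > coef_cap) || !sel$converged
  if (separated) {
    warning("separation detected in stepwise logistic fit; using a ridge-stabilised refit",
            call. = FALSE)
    keep <- setdiff(names(cf), "(Intercept)")
    if (length(keep) == 0) keep <- candidates
    if (requireNamespace("glmnet", quietly = TRUE) && length(keep) >= 2) {
      X <- as.matrix(dat[keep])
      rf <- glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                           lambda = 0.01, standardize = TRUE)
      cf <- c(`(Intercept)` = as.numeric(rf$a0),
              stats::setNames(as.numeric(rf$beta), keep))
    } else {
      # penalised fallback via data augmentation towards 0.5
      aug <- dat[rep(1, 2), , drop = FALSE]
      aug$.y <- c(TRUE, FALSE)
      aug[keep] <- 0
      rf <- suppressWarnings(stats::glm(stats::as.formula(
        paste(".y ~", paste(keep, collapse = " + "))),
        family = stats::binomial(), data = rbind(dat, aug)))
      cf <- stats::coef(rf)
    }
  }
  beta <- cf[setdiff(names(cf), "(Intercept)")]
  if (length(beta) == 0) {
    stop("stepwise selection retained no features", call. = FALSE)
  }
  lp <- as.matrix(feature_table[names(beta)]) %*% beta
  threshold <- youden_threshold(drop(lp), labels)
  out <- new_cirs_model(coefficients = beta, intercept = NULL,
                        threshold = threshold, provenance = "fitted")
  out$intercept_logit <- unname(cf["(Intercept)"])
  out$aic <- if (separated) NA_real_ else stats::AIC(sel)
  out
}

# cutoff on the linear predictor maximising sensitivity + specificity - 1;
# candidate cutoffs are midpoints between adjacent distinct scores (ties:
# the lowest maximising cutoff wins)
youden_threshold <- function(lp, labels) {
  s <- sort(unique(lp))
  if (length(s) == 1) return(s)
  cand <- (s[-1] + s[-length(s)]) / 2
  j <- vapply(cand, function(th) {
    pred <- lp > th
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' @export
print.cirs_model <- function(x, digits = 4, ...) {
  cat(sprintf("<cirs_model> (%s) %d features, threshold > %.4g\n",
              x$provenance, length(x$coefficients), x$threshold))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.cirs_model <- function(object, ...) object$coefficients

#' Score new data with a risk-score model
#'
#' @param object a `cirs_model`.
#' @param newdata data.frame of feature columns (one row per observation).
#' @param type `"score"` for numeric scores, `"risk"` for high/low labels.
#' @param ... unused.
#' @return numeric scores or character risk labels.
#' @export
predict.cirs_model <- function(object, newdata, type = c("score", "risk"),
                               ...) {
  type <- match.arg(type)
  s <- score_features(object, newdata)
  if (type == "score") s else classify_risk(s, object$threshold)
}
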