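survival_result <- function(term, hr, lo, hi, p, n, events, model) {
  data.frame(term = term, hr = hr, ci_low = lo, ci_high = hi, p = p,
             n = n, events = events, model = model)
}

#' Kaplan-Meier curves by group with a log-rank test
#'
#' @param times follow-up times.
#' @param status event indicator (1/TRUE = death).
#' @param labels group labels.
#' @return list with `fit` (a [survival::survfit] object with Greenwood
#'   standard errors), `p` (two-sided log-rank p-value) and `table`
#'   (per-group n and events).
#' @export
km_by_group <- function(times, status, labels) {
  status <- as.integer(as.logical(status))
  group <- factor(labels)
  dat <- data.frame(times = times, status = status, group = group)
  fit <- survival::survfit(survival::Surv(times, status) ~ group, data = dat,
                           error = "greenwood", conf.type = "log")
  p <- if (nlevels(group) < 2 || sum(status) == 0) {
    NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(times, status) ~ group,
                             data = dat)
    stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  }
  list(fit = fit, p = p,
       table = data.frame(group = levels(group),
                          n = as.vector(table(group)),
                          events = as.vector(tapply(status, group, sum))))
}

#' Multivariate Cox model with landmark exclusion
#'
#' Patients whose event or censoring falls on or before `landmark_day` are
#' excluded and the survival clock restarts at the landmark (avoiding
#' immortal-time bias). Ties use the Efron approximation; confidence
#' intervals and p-values are Wald on the log-hazard scale.
#'
#' @param times,status survival times (days) and event indicators.
#' @param covariate_table data.frame of covariates (numeric, logical or
#'   factor), one row per patient.
#' @param landmark_day survival clock origin (0 = time of transplant).
#' @return data.frame of per-term results: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `n`, `events`, `model`.
#' @export
cox_fit <- function(times, status, covariate_table, landmark_day = 0) {
  covariate_table <- as.data.frame(covariate_table)
  lm <- landmark_survival(times, as.logical(status), landmark_day)
  if (sum(lm$status) < 1) {
    stop("cox_fit: no events after the landmark", call. = FALSE)
  }
  dat <- covariate_table[lm$keep, , drop = FALSE]
  const <- vapply(dat, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  if (any(const)) {
    stop("cox_fit: constant covariate(s): ",
         paste(names(dat)[const], collapse = ", "), call. = FALSE)
  }
  dat$.time <- lm$time
  dat$.status <- lm$status
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(names(covariate_table), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(!is.finite(stats::coef(fit)))) {
    stop("cox_fit did not converge: non-finite coefficient(s) for ",
         paste(names(stats::coef(fit))[!is.finite(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  survival_result(rownames(sm$coefficients),
                  sm$coefficients[, "exp(coef)"],
                  sm$conf.int[, "lower .95"],
                  sm$conf.int[, "upper .95"],
                  sm$coefficients[, "Pr(>|z|)"],
                  n = sm$n, events = sm$nevent, model = "cox")
}

#' Cumulative incidence and subdistribution hazards under competing risks
#'
#' Per-cause cumulative incidence is the Aalen-Johansen estimator; the
#' group effect on each cause is the Fine-Gray subdistribution hazard ratio
#' (IPCW-weighted Cox formulation, as implemented in \pkg{cmprsk}).
#'
#' @param times follow-up times.
#' @param status event indicator (1/TRUE = death of any cause).
#' @param cause death-cause labels (`"none"` for censored rows).
#' @param labels binary exposure (e.g. high vs low risk).
#' @return list with `cif` (data.frame `time`, `cause`, `group`, `cuminc`)
#'   and `results` (per-cause `survival_result` rows, model `"fine_gray"`).
#' @export
competing_risks <- function(times, status, cause, labels) {
  status <- as.integer(as.logical(status))
  cause <- as.character(cause)
  if (any(status == 1 & cause == "none")) {
    stop("competing_risks: deaths must carry a cause", call. = FALSE)
  }
  causes <- sort(unique(cause[status == 1]))
  group <- factor(labels)

  ev <- factor(ifelse(status == 1, cause, "censor"),
               levels = c("censor", causes))
  cif_fit <- survival::survfit(survival::Surv(times, ev) ~ group)
  st <- summary(cif_fit)
  state_names <- colnames(st$pstate)
  grp <- if (is.null(st$strata)) rep(levels(group)[1], length(st$time)) else
    sub("^group=", "", as.character(st$strata))
  cif <- do.call(rbind, lapply(causes, function(cs) {
    data.frame(time = st$time, cause = cs, group = grp,
               cuminc = st$pstate[, match(cs, state_names)])
  }))

  if (nlevels(group) < 2) {
    warning("competing_risks: single exposure group; returning cumulative incidence only",
            call. = FALSE)
    return(list(cif = cif, results = NULL))
  }
  res <- lapply(causes, function(cs) {
    fstatus <- ifelse(status == 0, 0L, match(cause, causes))
    fg <- cmprsk::crr(ftime = times, fstatus = fstatus,
                      cov1 = matrix(as.numeric(group == levels(group)[2]),
                                    ncol = 1),
                      failcode = match(cs, causes), cencode = 0L)
    est <- fg$coef[1]
    se <- sqrt(fg$var[1, 1])
    survival_result(term = paste0(cs, ": ", levels(group)[2]),
                    hr = exp(est), lo = exp(est - 1.96 * se),
                    hi = exp(est + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(est / se)),
                    n = length(times),
                    events = sum(status == 1 & cause == cs),
                    model = "fine_gray")
  })
  list(cif = cif, results = do.call(rbind, res))
}

#' Risk factors for carrying a high score
#'
#' Multivariable logistic regression of the high/low label on peri-transplant
#' covariates (by default: severe acute GVHD within 100 days, infection
#' episodes during days 1-90, and age). Odds ratios with 95% Wald intervals.
#'
#' @param outcomes per-patient outcome table (see [cohort()]).
#' @param labels logical high-score indicator, aligned with `outcomes` rows.
#' @param covariates covariate column names in `outcomes`.
#' @return data.frame of per-term results (`hr` column holds the odds
#'   ratio), model `"logistic"`.
#' @export
high_score_risk_factors <- function(outcomes, labels,
                                    covariates = c("severe_agvhd_100d",
                                                   "infections_p1", "age")) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("high_score_risk_factors: labels contain a single class",
         call. = FALSE)
  }
  miss <- setdiff(covariates, names(outcomes))
  if (length(miss) > 0) {
    stop("unknown covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- outcomes[covariates]
  dat$.y <- labels
  fit <- stats::glm(stats::as.formula(
    paste(".y ~", paste(covariates, collapse = " + "))),
    family = stats::binomial(), data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  survival_result(rownames(cf), exp(cf[, "Estimate"]),
                  exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
                  exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
                  cf[, "Pr(>|z|)"], n = nrow(dat), events = sum(labels),
                  model = "logistic")
}
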