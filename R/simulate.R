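#' Default recovery-kinetics parameters for the synthetic generator
#'
#' Each blood lineage recovers along a saturating-exponential mean curve,
#' `plateau * (1 - exp(-t / rise_time))` on the natural count scale
#' (10^9/L), with multiplicative log-normal noise. CD8 T cells rise fastest
#' among lymphocytes; CD4 T and B cells are slowest, so that early and late
#' reconstitution occupy different regions of feature space. `t_other`
#' (non-CD4/CD8 T cells) and `lymph_other` (remaining lymphocytes) keep the
#' subset fractions strictly below 1.
#'
#' @return data.frame with columns `lineage`, `plateau`, `rise_time`,
#'   `noise_sd`, `lymphoid`.
#' @export
default_lineage_params <- function() {
  data.frame(
    lineage   = c("neut", "eos", "baso", "mono", "nk", "cd8", "cd4",
                  "t_other", "b", "lymph_other"),
    plateau   = c(3.2, 0.15, 0.04, 0.45, 0.30, 0.60, 0.35,
                  0.10, 0.25, 0.05),
    rise_time = c(12, 30, 30, 15, 40, 60, 150, 80, 180, 60),
    noise_sd  = c(0.30, 0.50, 0.50, 0.35, 0.40, 0.40, 0.40,
                  0.40, 0.45, 0.40),
    lymphoid  = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates visit-scheduled multivariate immune recovery after
#' transplant with a latent "derailed" subgroup: derailed patients have their
#' lymphoid plateaus multiplied by `exp(-derail_shift)` (myeloid lineages
#' unchanged), which places their profiles in a distinct region of the phase
#' space, and their all-cause hazard multiplied by `exp(derail_log_hr)`.
#' Death causes are drawn from `cause_mix` independently of event time.
#'
#' @param n_patients number of patients.
#' @param visit_days nominal profiling days post-transplant (strictly
#'   increasing, positive).
#' @param visit_jitter_sd SD (days) of Gaussian jitter around nominal visit
#'   days.
#' @param lineage_params recovery-curve parameters; see
#'   [default_lineage_params()].
#' @param patient_effect_sd between-patient log-scale SD of the lineage
#'   plateau random effects.
#' @param rise_time_sd between-patient log-scale SD of a shared recovery
#'   speed multiplier on every lineage's rise time. Speed heterogeneity
#'   spreads patients out along the recovery trajectory at intermediate
#'   follow-up and lets them converge once plateaus are reached, so the
#'   between-patient variance of immune status peaks a few weeks
#'   post-transplant.
#' @param derail_fraction probability a patient is latently derailed.
#' @param derail_shift log-scale plateau displacement of derailed patients'
#'   lymphoid lineages.
#' @param baseline_hazard all-cause hazard (events/day) for non-derailed
#'   patients.
#' @param derail_log_hr log hazard ratio of derailment.
#' @param cause_mix named probabilities over `relapse`, `infection_nrm`,
#'   `other_nrm`; must sum to 1.
#' @param censor_day administrative censoring day.
#' @param seed integer RNG seed.
#' @return A validated `cirs_sim_config` list.
#' @export
sim_config <- function(n_patients = 2000,
                       visit_days = c(30, 60, 90, 135, 180, 270, 360),
                       visit_jitter_sd = 3,
                       lineage_params = default_lineage_params(),
                       patient_effect_sd = 0.30,
                       rise_time_sd = 0.50,
                       derail_fraction = 0.15,
                       derail_shift = 1.5,
                       baseline_hazard = 3e-4,
                       derail_log_hr = log(3),
                       cause_mix = c(relapse = 0.40, infection_nrm = 0.35,
                                     other_nrm = 0.25),
                       censor_day = 1095,
                       seed = 0) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_config("n_patients", "must be a positive count")
  }
  if (any(visit_days <= 0) || is.unsorted(visit_days, strictly = TRUE)) {
    stop_config("visit_days", "must be strictly increasing and positive")
  }
  if (visit_jitter_sd < 0) stop_config("visit_jitter_sd", "must be >= 0")
  need <- c("lineage", "plateau", "rise_time", "noise_sd", "lymphoid")
  if (!all(need %in% names(lineage_params)) ||
      any(lineage_params$plateau <= 0) || any(lineage_params$rise_time <= 0) ||
      any(lineage_params$noise_sd < 0)) {
    stop_config("lineage_params",
                "needs positive plateau/rise_time and noise_sd >= 0")
  }
  if (patient_effect_sd < 0) stop_config("patient_effect_sd", "must be >= 0")
  if (rise_time_sd < 0) stop_config("rise_time_sd", "must be >= 0")
  if (derail_fraction < 0 || derail_fraction > 1) {
    stop_config("derail_fraction", "must lie in [0, 1]")
  }
  if (baseline_hazard <= 0) stop_config("baseline_hazard", "must be > 0")
  if (!is.finite(derail_log_hr)) stop_config("derail_log_hr", "must be finite")
  if (abs(sum(cause_mix) - 1) > 1e-12 || any(cause_mix < 0)) {
    stop_config("cause_mix", "must be non-negative and sum to 1")
  }
  if (censor_day < 0) stop_config("censor_day", "must be >= 0")
  if (is.null(seed) || !is.finite(seed)) stop_config("seed", "is mandatory")
  structure(list(n_patients = as.integer(n_patients),
                 visit_days = visit_days,
                 visit_jitter_sd = visit_jitter_sd,
                 lineage_params = lineage_params,
                 patient_effect_sd = patient_effect_sd,
                 rise_time_sd = rise_time_sd,
                 derail_fraction = derail_fraction,
                 derail_shift = derail_shift,
                 baseline_hazard = baseline_hazard,
                 derail_log_hr = derail_log_hr,
                 cause_mix = cause_mix,
                 censor_day = censor_day,
                 seed = as.integer(seed)),
            class = "cirs_sim_config")
}

#' Simulate survival times with competing causes
#'
#' Event times are exponential with per-patient hazard
#' `baseline_hazard * exp(linear_predictor)`; times beyond `censor_day` are
#' administratively censored. The death cause is drawn from `cause_mix`
#' independently of the event time. Uses the current RNG state (seed it, or
#' call via [simulate_cohort()] which seeds everything from the config).
#'
#' @param linear_predictor per-patient log relative hazard.
#' @param config a [sim_config()].
#' @return data.frame with `os_time`, `death` (logical), `cause`.
#' @export
simulate_survival <- function(linear_predictor, config) {
  stopifnot(inherits(config, "cirs_sim_config"))
  if (any(!is.finite(linear_predictor))) {
    stop("simulate_survival: non-finite linear predictor", call. = FALSE)
  }
  n <- length(linear_predictor)
  raw <- stats::rexp(n, rate = config$baseline_hazard * exp(linear_predictor))
  death <- raw <= config$censor_day
  cause <- rep("none", n)
  if (any(death)) {
    cause[death] <- sample(names(config$cause_mix), sum(death),
                           replace = TRUE, prob = config$cause_mix)
  }
  data.frame(os_time = ifelse(death, raw, config$censor_day),
             death = death, cause = cause)
}

#' Simulate a cohort with planted ground truth
#'
#' Generates the longitudinal profile table and the per-patient outcome
#' table with the statistical structure the downstream analysis assumes.
#' All profile invariants hold by construction: the six derived subset
#' counts equal lymphocyte count times the matching fraction, subset
#' fractions of lymphocytes sum to at most 1 (CD4 + CD8 below the total-T
#' fraction, Tregs within CD4), the white cell count is the sum of its
#' components, and no profile is dated after the patient's event or
#' censoring day. Reproducible: identical configs give byte-identical
#' tables.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a `cirs_cohort`) and `truth` (data.frame:
#'   `patient_id`, `derailed`, `true_log_hr`, `cause`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cirs_sim_config"))
  if (config$censor_day <= 0) {
    stop_config("censor_day", "must be > 0 when simulating a full cohort")
  }
  lp <- config$lineage_params
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  with_seed(config$seed, {
    derailed <- stats::rbinom(n, 1, config$derail_fraction) == 1
    surv <- simulate_survival(config$derail_log_hr * as.numeric(derailed),
                              config)

    # peri-transplant covariates; derailment raises early aGVHD and
    # infection burden so the score's upstream risk factors are non-trivial
    age <- round(stats::runif(n, 2, 65))
    sex <- sample(c("M", "F"), n, TRUE, c(0.55, 0.45))
    primary_disease <- sample(c("ALL_AML", "MDS", "other_neoplasm", "BMF"),
                              n, TRUE, c(0.65, 0.15, 0.07, 0.13))
    transplant_type <- sample(c("MSD", "haplo", "MUD", "UCB"),
                              n, TRUE, c(0.45, 0.25, 0.06, 0.24))
    conditioning <- sample(c("MAC", "RIC"), n, TRUE, c(0.85, 0.15))
    atg_used <- stats::runif(n) < 0.40
    severe_agvhd <- stats::runif(n) < stats::plogis(-2.2 + 1.0 * derailed)
    inf1 <- stats::rpois(n, 0.35 + 0.40 * derailed)
    inf2 <- stats::rpois(n, 0.15 + 0.20 * derailed)
    inf3 <- stats::rpois(n, 0.15 + 0.20 * derailed)
    inf4 <- stats::rpois(n, 0.10 + 0.15 * derailed)
    split <- sample(c("training", "validation", "test"), n, TRUE,
                    c(0.50, 0.25, 0.25))

    # per patient x lineage log-normal random effects
    nl <- nrow(lp)
    u <- matrix(stats::rnorm(n * nl, 0, config$patient_effect_sd), n, nl,
                dimnames = list(NULL, lp$lineage))
    # shared recovery-speed multiplier: slow reconstituters have longer
    # rise times on every lineage
    speed <- exp(stats::rnorm(n, 0, config$rise_time_sd))
    treg_share <- stats::plogis(stats::qlogis(0.10) + stats::rnorm(n, 0, 0.3))

    prof_list <- vector("list", n)
    for (i in seq_len(n)) {
      days <- config$visit_days
      if (config$visit_jitter_sd > 0) {
        days <- days + stats::rnorm(length(days), 0, config$visit_jitter_sd)
      }
      days <- sort(unique(pmax(1, round(days))))
      days <- days[days <= surv$os_time[i]]
      if (length(days) == 0) next
      shift <- ifelse(lp$lymphoid & derailed[i],
                      exp(-config$derail_shift), 1)
      m <- length(days)
      counts <- matrix(NA_real_, m, nl, dimnames = list(NULL, lp$lineage))
      for (l in seq_len(nl)) {
        mu <- lp$plateau[l] * shift[l] *
          (1 - exp(-days / (lp$rise_time[l] * speed[i])))
        eps <- stats::rnorm(m, 0, lp$noise_sd[l])
        counts[, l] <- mu * exp(u[i, l] + eps)
      }
      lymph <- counts[, "nk"] + counts[, "cd8"] + counts[, "cd4"] +
        counts[, "t_other"] + counts[, "b"] + counts[, "lymph_other"]
      wbc <- counts[, "neut"] + counts[, "eos"] + counts[, "baso"] +
        counts[, "mono"] + lymph
      t_cnt <- counts[, "cd8"] + counts[, "cd4"] + counts[, "t_other"]
      treg_cnt <- treg_share[i] * counts[, "cd4"]
      df <- data.frame(
        patient_id = ids[i], day = days,
        wbc = wbc, neut = counts[, "neut"], eos = counts[, "eos"],
        baso = counts[, "baso"], mono = counts[, "mono"], lymph = lymph,
        mono_frac_nuc = counts[, "mono"] / wbc,
        lymph_frac_nuc = lymph / wbc,
        nk_frac = counts[, "nk"] / lymph,
        t_frac = t_cnt / lymph,
        cd4_frac = counts[, "cd4"] / lymph,
        cd8_frac = counts[, "cd8"] / lymph,
        treg_frac = treg_cnt / lymph,
        b_frac = counts[, "b"] / lymph
      )
      prof_list[[i]] <- df
    }
    profiles <- do.call(rbind, prof_list)
    rownames(profiles) <- NULL
    for (f in names(.derived_map)) profiles[[f]] <- NA_real_
    profiles <- derive_counts(profiles)

    outcomes <- data.frame(
      patient_id = ids, age = age, sex = sex,
      primary_disease = primary_disease, transplant_type = transplant_type,
      conditioning = conditioning, atg_used = atg_used,
      os_time = surv$os_time, death = surv$death, cause = surv$cause,
      severe_agvhd_100d = severe_agvhd,
      infections_p1 = inf1, infections_p2 = inf2,
      infections_p3 = inf3, infections_p4 = inf4,
      cohort_split = split
    )
    truth <- data.frame(patient_id = ids, derailed = derailed,
                        true_log_hr = config$derail_log_hr *
                          as.numeric(derailed),
                        cause = surv$cause)
    list(cohort = cohort(profiles, outcomes), truth = truth)
  })
}
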