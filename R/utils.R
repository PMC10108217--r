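# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# Landmark exclusion shared by the anchor scan and the validation battery:
# survival is re-timed from `landmark_day`; patients whose event or censoring
# falls on or before the landmark are dropped (immortal-time guard).
landmark_survival <- function(time, status, landmark_day) {
  stopifnot(length(time) == length(status))
  keep <- is.finite(time) & time > landmark_day
  list(time = time[keep] - landmark_day,
       status = as.integer(status[keep]),
       keep = keep)
}

# Fast univariate Cox Wald test used inside the grid scan. `x` is a 0/1
# exposure vector; returns c(p, hr). Degenerate fits fall back to p = 1.
cox_wald_uni <- function(time, status, x) {
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(matrix(as.numeric(x), ncol = 1L),
                          survival::Surv(time, status),
                          strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = "efron",
                          rownames = seq_along(time))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients[1L]) ||
      !is.finite(fit$var[1L]) || fit$var[1L] <= 0) {
    return(c(p = 1, hr = NA_real_))
  }
  z <- fit$coefficients[1L] / sqrt(fit$var[1L])
  c(p = 2 * stats::pnorm(-abs(z)), hr = exp(fit$coefficients[1L]))
}
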