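#' Time to onset between therapy start and event date
#'
#' TTO is the interval, in whole days, between the adverse-event date
#' (EVENT_DT) and the drug start date (START_DT). Either date missing gives
#' exclusion reason `"excluded-missing"`; a negative interval (event before
#' start, an erroneous record) gives `"excluded-erroneous"`. A zero-day
#' interval (same-day onset) is retained.
#'
#' @param event_date,start_date `Date` vectors (already validated, e.g. by
#'   [parse_faers_date()]); recycled to a common length.
#' @return data.table with columns `days` (integer, `NA` when excluded) and
#'   `status` (`"retained"`, `"excluded-missing"`, `"excluded-erroneous"`).
#' @export
#' @examples
#' compute_tto(as.Date("2023-01-10"), as.Date("2023-01-01"))  # 9 days
compute_tto <- function(event_date, start_date) {
  n <- max(length(event_date), length(start_date))
  event_date <- rep_len(as.Date(event_date), n)
  start_date <- rep_len(as.Date(start_date), n)
  days <- as.integer(event_date - start_date)
  status <- rep("retained", n)
  status[is.na(event_date) | is.na(start_date)] <- "excluded-missing"
  status[!is.na(days) & days < 0] <- "excluded-erroneous"
  days[status != "retained"] <- NA_integer_
  data.table(days = days, status = status)
}

#' Extract one drug's time-to-onset sample from a case set
#'
#' For each target-event case reporting the drug as primary suspect, the
#' therapy start date of the drug's lowest-`drug_seq` PS entry is paired
#' with the case's event date and passed through [compute_tto()].
#'
#' @param case_set A `case_set`.
#' @param drug Normalized drug name.
#' @return List of class `tto_sample`: `drug`, `days` (retained intervals,
#'   zero-day onsets kept as 0), `n`, `n_excluded_missing`,
#'   `n_excluded_negative`, `n_candidates`.
#' @export
tto_sample <- function(case_set, drug) {
  stopifnot(inherits(case_set, "case_set"))
  ids <- .drug_case_ids(case_set, drug)
  cs <- case_set$cases
  ids <- ids[ids %in% cs$primaryid[cs$has_target_event]]
  sd <- case_set$start_dates
  sd <- sd[sd$primaryid %in% ids & sd$drug == drug, ]
  ev <- cs[match(sd$primaryid, cs$primaryid), event_date]
  tt <- compute_tto(ev, sd$start_date)
  structure(list(
    drug = drug,
    days = tt$days[tt$status == "retained"],
    n = sum(tt$status == "retained"),
    n_excluded_missing = sum(tt$status == "excluded-missing"),
    n_excluded_negative = sum(tt$status == "excluded-erroneous"),
    n_candidates = nrow(tt)
  ), class = "tto_sample")
}

#' Median and interquartile range of a time-to-onset sample
#'
#' Quantiles use the linear-interpolation convention (`type = 7`,
#' R's default). Raw day values are used, including zero-day onsets.
#'
#' @param sample A `tto_sample` or numeric vector of days.
#' @return Named numeric vector `c(median, q1, q3)` in days.
#' @export
summarize_tto <- function(sample) {
  days <- if (inherits(sample, "tto_sample")) sample$days else sample
  if (length(days) == 0L) stop("empty time-to-onset sample", call. = FALSE)
  q <- stats::quantile(days, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# Weibull log-likelihood for sample t at scale alpha, shape beta.
.weib_loglik <- function(t, alpha, beta) {
  n <- length(t)
  n * log(beta) - n * beta * log(alpha) + (beta - 1) * sum(log(t)) -
    sum((t / alpha)^beta)
}

# Profile score in beta: d/dbeta of the profile log-likelihood, i.e.
# 1/beta + mean(log t) - sum(t^beta log t) / sum(t^beta). Computed on the
# scaled sample t/geomean(t) by the caller for numerical range safety.
.weib_profile_score <- function(t, beta) {
  tb <- t^beta
  1 / beta + mean(log(t)) - sum(tb * log(t)) / sum(tb)
}

#' Fit a two-parameter Weibull distribution by maximum likelihood
#'
#' Fits the scale (`alpha`, days) and shape (`beta`) of a Weibull law to a
#' positive time-to-onset sample via the profile likelihood: for fixed
#' `beta` the scale MLE is `alpha(beta) = (mean(t^beta))^(1/beta)`, and the
#' shape MLE is the root of the profile score
#' `1/beta + mean(log t) - sum(t^beta log t)/sum(t^beta) = 0`, found by
#' bracketed root finding on `beta` in `[0.01, 50]` to relative tolerance
#' 1e-8. Zero-day onsets are mapped to 0.5 day for fitting only (the
#' log-likelihood is undefined at 0).
#'
#' 95% Wald intervals come from the inverse of the 2x2 observed information
#' matrix (analytic second derivatives of the log-likelihood at the MLE),
#' on the natural parameter scale, truncated below at 0. The shape interval
#' classifies the hazard ("failure type"): see [classify_failure()].
#'
#' @param sample A `tto_sample` or numeric vector of days (>= 0; zeros are
#'   shifted to 0.5 for fitting).
#' @param level Confidence level for the Wald intervals (default 0.95).
#' @return List of class `weibull_fit`: `alpha`, `beta`, `alpha_ci`,
#'   `beta_ci` (length-2 vectors, `NA` when the information matrix is
#'   singular), `loglik`, `n`, `failure_type`, `converged`.
#' @export
#' @examples
#' f <- fit_weibull(c(1, 2, 4, 8))
#' c(f$alpha, f$beta)
fit_weibull <- function(sample, level = 0.95) {
  days <- if (inherits(sample, "tto_sample")) sample$days else sample
  days <- as.numeric(days)
  if (length(days) < 3L)
    stop("Weibull fit needs at least 3 observations", call. = FALSE)
  if (any(is.na(days) | days < 0))
    stop("Weibull fit needs non-negative, non-missing days", call. = FALSE)
  t <- ifelse(days == 0, 0.5, days)
  if (length(unique(t)) < 2L)
    return(structure(list(alpha = NA_real_, beta = NA_real_,
                          alpha_ci = c(NA_real_, NA_real_),
                          beta_ci = c(NA_real_, NA_real_),
                          loglik = NA_real_, n = length(t),
                          failure_type = NA_character_, converged = FALSE,
                          degenerate = TRUE), class = "weibull_fit"))
  # work on a geometric-mean-scaled sample: t^beta stays in range for
  # beta up to the bracket edge even with day counts in the thousands
  g <- exp(mean(log(t)))
  ts <- t / g
  lo <- 0.01; hi <- 50
  f_lo <- .weib_profile_score(ts, lo)
  f_hi <- .weib_profile_score(ts, hi)
  if (f_lo < 0) {
    beta_hat <- lo; converged <- FALSE   # boundary: extremely heavy tail
  } else if (f_hi > 0) {
    beta_hat <- hi; converged <- FALSE   # boundary: near-degenerate sample
  } else {
    r <- stats::uniroot(function(b) .weib_profile_score(ts, b),
                        interval = c(lo, hi), tol = 1e-9)
    beta_hat <- r$root; converged <- TRUE
  }
  alpha_hat <- g * mean(ts^beta_hat)^(1 / beta_hat)
  ll <- .weib_loglik(t, alpha_hat, beta_hat)
  ci <- .weib_wald_ci(t, alpha_hat, beta_hat, level = level)
  structure(list(alpha = alpha_hat, beta = beta_hat,
                 alpha_ci = ci$alpha_ci, beta_ci = ci$beta_ci,
                 loglik = ll, n = length(t),
                 failure_type = classify_failure(ci$beta_ci[1], ci$beta_ci[2]),
                 converged = converged, degenerate = FALSE),
            class = "weibull_fit")
}

# Analytic observed information of the Weibull log-likelihood at (alpha,
# beta) and the implied natural-scale Wald intervals, truncated at 0.
.weib_wald_ci <- function(t, alpha, beta, level = 0.95) {
  n <- length(t)
  u <- (t / alpha)^beta
  v <- log(t / alpha)
  S <- sum(u)
  d2a <- -(beta / alpha^2) * (S - n) - beta^2 * S / alpha^2
  d2b <- -n / beta^2 - sum(u * v^2)
  dab <- (1 / alpha) * (-n + S + beta * sum(u * v))
  info <- -matrix(c(d2a, dab, dab, d2b), 2, 2)
  det_i <- info[1, 1] * info[2, 2] - info[1, 2]^2
  if (!is.finite(det_i) || det_i <= 0 || info[1, 1] <= 0)
    return(list(alpha_ci = c(NA_real_, NA_real_),
                beta_ci = c(NA_real_, NA_real_)))
  cov <- matrix(c(info[2, 2], -info[1, 2], -info[2, 1], info[1, 1]),
                2, 2) / det_i
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(cov))
  list(alpha_ci = pmax(0, alpha + c(-1, 1) * z * se[1]),
       beta_ci = pmax(0, beta + c(-1, 1) * z * se[2]))
}

#' Classify hazard evolution from the Weibull shape interval
#'
#' The shape parameter `beta` of a Weibull onset law determines how the
#' hazard of the event evolves with time on the drug: `beta < 1` means a
#' decreasing hazard (early failure), `beta > 1` an increasing hazard
#' (wear-out failure), `beta = 1` a constant hazard (random failure,
#' the exponential special case). Classification uses the 95% confidence
#' interval: early iff the upper bound is below 1, wear-out iff the lower
#' bound is above 1, random otherwise (interval contains 1).
#'
#' @param ci_low,ci_high Bounds of the shape-parameter confidence interval.
#' @return `"early"`, `"random"`, `"wear-out"`, or `NA` if unavailable.
#' @export
#' @examples
#' classify_failure(0.52, 0.59)  # early
#' classify_failure(0.93, 1.23)  # random
classify_failure <- function(ci_low, ci_high) {
  if (is.na(ci_low) || is.na(ci_high)) return(NA_character_)
  if (ci_high < 1) "early" else if (ci_low > 1) "wear-out" else "random"
}

#' Time-to-onset summary table for a set of drugs
#'
#' For each drug: retained sample size, median and interquartile range of
#' the onset interval, Weibull scale and shape with 95% Wald intervals, and
#' the failure type. Drugs whose retained sample is smaller than `min_n`
#' are skipped.
#'
#' @param case_set A `case_set`.
#' @param drugs Character vector of normalized drug names; default all PS
#'   drugs in the case set.
#' @param min_n Minimum retained TTO sample size (default 3).
#' @param level Confidence level (default 0.95).
#' @return data.table with columns `drug`, `n`, `median`, `q1`, `q3`,
#'   `alpha`, `alpha_lo`, `alpha_hi`, `beta`, `beta_lo`, `beta_hi`,
#'   `failure_type`, ordered by `n` descending then drug name.
#' @export
tto_table <- function(case_set, drugs = NULL, min_n = 3, level = 0.95) {
  if (is.null(drugs)) drugs <- sort(unique(case_set$ps_drugs$drug))
  rows <- lapply(drugs, function(g) {
    s <- tto_sample(case_set, g)
    if (s$n < min_n || length(unique(s$days)) < 2L) return(NULL)
    q <- summarize_tto(s)
    f <- fit_weibull(s, level = level)
    data.table(drug = g, n = s$n, median = q["median"], q1 = q["q1"],
               q3 = q["q3"], alpha = f$alpha, alpha_lo = f$alpha_ci[1],
               alpha_hi = f$alpha_ci[2], beta = f$beta,
               beta_lo = f$beta_ci[1], beta_hi = f$beta_ci[2],
               failure_type = f$failure_type)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table(drug = character(0), n = integer(0), median = numeric(0),
                      q1 = numeric(0), q3 = numeric(0), alpha = numeric(0),
                      alpha_lo = numeric(0), alpha_hi = numeric(0),
                      beta = numeric(0), beta_lo = numeric(0),
                      beta_hi = numeric(0), failure_type = character(0)))
  setorder(out, -n, drug)
  out[]
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Weibull fit: degenerate sample (all values identical), n =",
        x$n, "\n")
    return(invisible(x))
  }
  cat(sprintf("Weibull fit (n = %d): scale alpha = %.3f [%.3f, %.3f], ",
              x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2]))
  cat(sprintf("shape beta = %.3f [%.3f, %.3f]\n",
              x$beta, x$beta_ci[1], x$beta_ci[2]))
  cat("failure type:", x$failure_type,
      if (!x$converged) "(boundary solution)", "\n")
  invisible(x)
}
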