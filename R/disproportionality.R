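#' Two-by-two contingency table for one drug-event pair
#'
#' Counts deduplicated cases into the standard disproportionality table:
#' `a` = cases with the target event reporting the drug as primary suspect,
#' `b` = the drug's cases with other events, `c` = target-event cases of all
#' other drugs, `d` = the remainder. Cells always sum to the number of cases
#' in scope. The counting unit is the case, not the report or the drug-event
#' pair multiplicity.
#'
#' @param case_set A `case_set` from [build_case_set()].
#' @param drug Normalized drug name.
#' @return List of class `contingency_table` with integer fields
#'   `a`, `b`, `c`, `d`, `n` and the `drug` name.
#' @export
contingency_table <- function(case_set, drug) {
  stopifnot(inherits(case_set, "case_set"))
  drug_ids <- .drug_case_ids(case_set, drug)
  cs <- case_set$cases
  n <- nrow(cs)
  in_drug <- cs$primaryid %in% drug_ids
  ev <- cs$has_target_event
  a <- sum(in_drug & ev); b <- sum(in_drug & !ev)
  c_ <- sum(!in_drug & ev); d <- n - a - b - c_
  structure(list(drug = drug, a = as.integer(a), b = as.integer(b),
                 c = as.integer(c_), d = as.integer(d), n = as.integer(n)),
            class = "contingency_table")
}

#' Reporting odds ratio with Wald confidence interval
#'
#' For a 2x2 table (a, b, c, d) the reporting odds ratio is
#' `ROR = a*d / (b*c)`; the Wald interval is
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile for the confidence level (1.96 at 0.95). Any
#' zero cell makes the estimate non-estimable: no continuity correction is
#' applied, since the downstream signal criterion requires at least three
#' target cases anyway.
#'
#' @param table A `contingency_table`, or a numeric vector/list with
#'   elements a, b, c, d.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return List with `ror`, `ci_low`, `ci_high` (all `NA` with
#'   `estimable = FALSE` when a cell is zero), `level`.
#' @export
#' @examples
#' ror_ci(c(a = 5, b = 10, c = 20, d = 400))
ror_ci <- function(table, level = 0.95) {
  stopifnot(level > 0, level < 1)
  a <- as.numeric(table[["a"]]); b <- as.numeric(table[["b"]])
  cc <- as.numeric(table[["c"]]); d <- as.numeric(table[["d"]])
  stopifnot(a >= 0, b >= 0, cc >= 0, d >= 0)
  if (min(a, b, cc, d) == 0)
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                estimable = FALSE, level = level))
  ror <- a * d / (b * cc)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(ror = ror, ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se), estimable = TRUE, level = level)
}

#' Disproportionality signal criterion
#'
#' A drug-event pair is a potential risk signal when the target-event case
#' count satisfies `a >= 3` and the lower bound of the 95% confidence
#' interval for the reporting odds ratio exceeds 1. A non-estimable interval
#' (zero cell) is never a signal.
#'
#' @param a Target-event case count of the drug.
#' @param ci_low Lower confidence bound of the ROR (`NA` if non-estimable).
#' @param min_cases Minimum case count (default 3).
#' @return Logical.
#' @export
signal_flag <- function(a, ci_low, min_cases = 3) {
  !is.na(a) & a >= min_cases & !is.na(ci_low) & ci_low > 1
}

#' Screen every primary-suspect drug for a disproportionality signal
#'
#' Builds the contingency table for each distinct normalized primary-suspect
#' drug with at least `min_cases` target-event cases, computes the reporting
#' odds ratio and Wald interval, and applies the signal criterion. The
#' result is ranked by target-event case count `a` (descending), ties broken
#' lexicographically by drug name, so output order is deterministic.
#'
#' @param case_set A `case_set`.
#' @param min_cases Minimum `a` for a drug to be reported (default 3,
#'   matching the signal criterion).
#' @param level Confidence level (default 0.95).
#' @param top_k Optional: keep only the first `top_k` rows after ranking.
#' @return data.table of class `signal_screen` with columns `drug`, `a`,
#'   `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`, `is_signal`.
#' @export
screen_signals <- function(case_set, min_cases = 3, level = 0.95,
                           top_k = NULL) {
  stopifnot(inherits(case_set, "case_set"))
  drugs <- sort(unique(case_set$ps_drugs$drug))
  rows <- lapply(drugs, function(g) {
    tab <- contingency_table(case_set, g)
    if (tab$a < min_cases) return(NULL)
    est <- ror_ci(tab, level = level)
    data.table(drug = g, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
               is_signal = signal_flag(tab$a, est$ci_low,
                                       min_cases = min_cases))
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    out <- data.table(drug = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), ror = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      is_signal = logical(0))
  setorder(out, -a, drug)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  class(out) <- c("signal_screen", class(out))
  out[]
}

#' Recover a Wald point estimate from its confidence bounds
#'
#' A Wald interval on the log-odds scale is symmetric about the log point
#' estimate, so the point estimate is the geometric midpoint
#' `exp((ln lo + ln hi) / 2)` of its bounds. Useful for verifying published
#' ROR tables against their printed intervals.
#'
#' @param ci_low,ci_high Positive confidence bounds, `ci_low <= ci_high`.
#' @return The implied point estimate.
#' @export
#' @examples
#' recover_ror_from_ci(22.91, 25.37)  # ~ 24.11
recover_ror_from_ci <- function(ci_low, ci_high) {
  if (any(!is.finite(ci_low) | !is.finite(ci_high) |
            ci_low <= 0 | ci_high <= 0))
    stop("confidence bounds must be positive and finite", call. = FALSE)
  if (any(ci_low > ci_high))
    stop("ci_low must not exceed ci_high", call. = FALSE)
  exp((log(ci_low) + log(ci_high)) / 2)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 table for", x$drug, "\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target ADE", "other ADEs")))
  print(m)
  invisible(x)
}
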