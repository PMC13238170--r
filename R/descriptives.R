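#' Demographic and reporting descriptives for target-event cases
#'
#' Tabulates sex, age band, reporter qualification, reporter country and
#' receipt year over the target-event cases (optionally restricted to cases
#' of a drug subset). Missing values form an explicit `"unknown"` bucket and
#' the denominator for every proportion is the full selection, so the
#' reported percentages follow the convention of showing unknowns separately
#' rather than dropping them.
#'
#' @param case_set A `case_set`.
#' @param drugs Optional character vector: keep only cases with a
#'   primary-suspect drug in this set.
#' @param age_bands Ascending band edges in years; default
#'   `c(0, 18, 45, 65, 85, Inf)` gives bands (0,18], (18,45], (45,65],
#'   (65,85], (85,Inf).
#' @return data.table of class `descriptive_report` in long format:
#'   `tabulation`, `bucket`, `count`, `proportion`. Counts within each
#'   tabulation sum to the selected case total.
#' @export
describe_cases <- function(case_set, drugs = NULL,
                           age_bands = c(0, 18, 45, 65, 85, Inf)) {
  stopifnot(inherits(case_set, "case_set"))
  cs <- case_set$cases[has_target_event == TRUE]
  if (!is.null(drugs)) {
    ids <- unique(unlist(lapply(drugs, .drug_case_ids,
                                case_set = case_set)))
    cs <- cs[primaryid %in% ids]
  }
  n <- nrow(cs)
  bucketize <- function(x, unknown = c("", "UNK")) {
    x <- as.character(x)
    x[is.na(x) | x %in% unknown] <- "unknown"
    x
  }
  age_bucket <- function(a) {
    lab <- paste0(utils::head(age_bands, -1), "-",
                  utils::tail(age_bands, -1))
    lab <- sub("-Inf$", "+", lab)
    b <- as.character(cut(a, breaks = age_bands, labels = lab,
                          include.lowest = TRUE, right = TRUE))
    b[is.na(b)] <- "unknown"
    b
  }
  one <- function(name, values) {
    tb <- table(values)
    data.table(tabulation = name, bucket = names(tb),
               count = as.integer(tb),
               proportion = if (n > 0) as.numeric(tb) / n else 0)
  }
  out <- rbindlist(list(
    one("sex", bucketize(cs$sex)),
    one("age_band", age_bucket(cs$age_years)),
    one("reporter", bucketize(cs$reporter_qualification)),
    one("country", bucketize(cs$reporter_country)),
    one("year", bucketize(as.character(cs$receipt_year), unknown = "NA"))
  ))
  if (nrow(out) == 0L)
    out <- data.table(tabulation = character(0), bucket = character(0),
                      count = integer(0), proportion = numeric(0))
  setorder(out, tabulation, -count, bucket)
  class(out) <- c("descriptive_report", class(out))
  attr(out, "n_cases") <- n
  out[]
}

#' Proportion of a drug's target-event cases with severe outcomes
#'
#' "Severe" means a death (`DE`) or life-threatening (`LT`) outcome code on
#' the case; a case with both counts once. The denominator is the drug's
#' target-event case count.
#'
#' @param case_set A `case_set`.
#' @param drug Normalized drug name.
#' @return List `severe` (count), `total` (the drug's target-event cases),
#'   `proportion` (`NA` when `total` is 0).
#' @export
outcome_severity <- function(case_set, drug) {
  stopifnot(inherits(case_set, "case_set"))
  ids <- .drug_case_ids(case_set, drug)
  cs <- case_set$cases
  ids <- ids[ids %in% cs$primaryid[cs$has_target_event]]
  oc <- case_set$outcomes
  severe_ids <- unique(oc$primaryid[oc$outc_cod %in% c("DE", "LT")])
  severe <- sum(ids %in% severe_ids)
  total <- length(ids)
  list(severe = severe, total = total,
       proportion = if (total > 0) severe / total else NA_real_)
}

#' Severity table over many drugs
#'
#' @param case_set A `case_set`.
#' @param drugs Character vector of drugs; default all PS drugs.
#' @return data.table `drug`, `severe`, `total`, `proportion`, ordered by
#'   proportion descending.
#' @export
outcome_severity_table <- function(case_set, drugs = NULL) {
  if (is.null(drugs)) drugs <- sort(unique(case_set$ps_drugs$drug))
  out <- rbindlist(lapply(drugs, function(g) {
    s <- outcome_severity(case_set, g)
    data.table(drug = g, severe = s$severe, total = s$total,
               proportion = s$proportion)
  }))
  setorder(out, -proportion, drug, na.last = TRUE)
  out[]
}
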