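#' Default target preferred-term set for hyponatremia
#'
#' FAERS REAC stores the MedDRA preferred-term text; the PT for this event is
#' spelled "Hyponatraemia" (British) in MedDRA, while reports and summaries
#' also use the American spelling. Matching is case-insensitive, so both
#' spellings are covered by default. The MedDRA code 10021036 is metadata
#' only: the dictionary files are licensed and never read.
#' @export
target_pts_hyponatremia <- function() {
  structure(c("HYPONATREMIA", "HYPONATRAEMIA"), meddra_code = "10021036")
}

#' Parse a FAERS date string to a calendar date
#'
#' FAERS dates are 8-digit `YYYYMMDD` strings, frequently truncated to
#' `YYYYMM` or `YYYY` or left empty. Only a complete, real calendar date is
#' accepted; partial, empty, or impossible dates (e.g. `"20230230"`) return
#' `NA`, matching the policy of excluding erroneous or missing dates from
#' date-based analyses.
#'
#' @param raw Character vector of raw date strings.
#' @return A `Date` vector with `NA` where the string is not a valid full date.
#' @export
#' @examples
#' parse_faers_date(c("20230110", "202301", "20230230", ""))
parse_faers_date <- function(raw) {
  raw <- trimws(as.character(raw))
  out <- rep(as.Date(NA), length(raw))
  ok <- !is.na(raw) & grepl("^[0-9]{8}$", raw)
  if (any(ok)) {
    d <- as.Date(raw[ok], format = "%Y%m%d")
    # round-trip check guards against lenient strptime implementations
    d[!is.na(d) & format(d, "%Y%m%d") != raw[ok]] <- NA
    out[ok] <- d
  }
  out
}

#' Normalize a drug name to a generic name
#'
#' Case-folds, trims and collapses whitespace, then resolves brand names and
#' salt forms through a user-supplied synonym map (raw name to generic name).
#' Unmapped names pass through case-folded: with no map this is a pure
#' canonical-form fold. Automatic ATC-style coding against the real WHO
#' catalogue is out of scope; the map carries whatever standardization the
#' analyst curates.
#'
#' @param raw Character vector of verbatim drug names.
#' @param synonym_map Named character vector or two-column data.frame
#'   (raw, normalized). Keys are matched after the same case/space fold.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name(c("LASIX", "Furosemide "), c(lasix = "furosemide"))
normalize_drug_name <- function(raw, synonym_map = character(0)) {
  fold <- function(x) gsub("[[:space:]]+", " ", tolower(trimws(x)))
  x <- fold(as.character(raw))
  if (is.data.frame(synonym_map)) {
    m <- fold(as.character(synonym_map[[2L]]))
    names(m) <- fold(as.character(synonym_map[[1L]]))
    synonym_map <- m
  } else if (length(synonym_map)) {
    m <- fold(as.character(synonym_map))
    names(m) <- fold(names(synonym_map))
    synonym_map <- m
  }
  hit <- x %in% names(synonym_map)
  x[hit] <- unname(synonym_map[x[hit]])
  x
}

#' Read a two-column synonym map file
#'
#' @param path Path to a delimiter-separated two-column text file
#'   (raw name, normalized name) with a header row.
#' @param sep Field delimiter (default `"$"`, matching the data dialect).
#' @return Named character vector suitable for [normalize_drug_name()].
#' @export
read_synonym_map <- function(path, sep = "$") {
  dt <- fread(path, sep = sep, colClasses = "character", header = TRUE,
              na.strings = NULL, quote = "")
  stats::setNames(dt[[2L]], dt[[1L]])
}

#' Deduplicate FAERS reports by case
#'
#' Applies the FDA-preferred rule: among the reports sharing one CASEID, keep
#' the report with the maximum FDA receipt date (FDA_DT); among reports tied
#' on FDA_DT, keep the highest PRIMARYID. Unparseable FDA_DT values sort
#' lowest, so a dated revision always supersedes an undated one. PRIMARYID is
#' compared numerically when every contender is numeric, else lexically.
#'
#' @param demo data.table/data.frame of DEMO entries with columns
#'   `primaryid`, `caseid`, `fda_dt` (raw strings).
#' @return Character vector of kept primaryids, one per caseid.
#' @export
#' @examples
#' demo <- data.frame(primaryid = c("1001", "1002", "1003"),
#'                    caseid = "100",
#'                    fda_dt = c("20230101", "20230301", "20230301"))
#' deduplicate_reports(demo)  # "1003"
deduplicate_reports <- function(demo) {
  d <- as.data.table(demo)[, .(primaryid, caseid, fda_dt)]
  if (nrow(d) == 0L) return(character(0))
  fda_key <- d$fda_dt
  fda_key[!grepl("^[0-9]{8}$", fda_key) | is.na(parse_faers_date(fda_key))] <- ""
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  d[, `:=`(.fda_key = fda_key, .pid_num = pid_num)]
  if (anyNA(pid_num)) {
    # mixed alphanumeric ids: fall back to lexicographic comparison
    setorder(d, caseid, .fda_key, primaryid)
  } else {
    setorder(d, caseid, .fda_key, .pid_num)
  }
  d[, .SD[.N], by = caseid]$primaryid
}

.convert_age_years <- function(age, age_cod, cap = 120) {
  a <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(age_cod))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
            DY = 1 / 365.25, HR = 1 / 8766)
  f <- mult[u]
  f[u == "" & !is.na(a)] <- 1  # blank unit with a plausible value: assume years
  yrs <- a * unname(f)
  yrs[!is.finite(yrs) | yrs < 0 | yrs > cap] <- NA_real_
  yrs
}

#' Build the analysis-ready case set from quarter bundles
#'
#' Assembles one record per case from one or more parsed quarter bundles:
#' deduplicate reports (FDA case rule), join drugs/reactions/therapy/outcomes
#' on the kept primaryids, restrict drug entries to the primary-suspect (PS)
#' role, normalize drug names, and flag target-event cases by case-insensitive
#' preferred-term match. Per-stage provenance counts are recorded.
#'
#' @param bundles A `quarter_bundle` or list of them (quarters are
#'   concatenated before deduplication).
#' @param target_pts Character vector of preferred terms defining the target
#'   event (default [target_pts_hyponatremia()]); matching ignores letter
#'   case and surrounding whitespace.
#' @param synonym_map Drug-name synonym map, see [normalize_drug_name()].
#' @param drug_window Optional data.frame (drug, `YYYYMMDD` start) restricting
#'   each drug's statistics to cases received on/after that date, e.g. an
#'   FDA-approval-date table. Default: no window.
#' @param age_cap Ages in years above this (default 120) become missing.
#' @return A `case_set`: list with data.tables `cases` (one row per caseid:
#'   identifiers, parsed dates, demographics in years, `has_target_event`,
#'   `receipt_year`), `ps_drugs` (case-drug pairs with `drug_seq`),
#'   `start_dates` (per case-drug therapy start), `outcomes`; plus
#'   `target_pts`, `drug_window` and `provenance` counts.
#' @export
build_case_set <- function(bundles, target_pts = target_pts_hyponatremia(),
                           synonym_map = character(0), drug_window = NULL,
                           age_cap = 120) {
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  stopifnot(length(target_pts) > 0L)
  demo <- rbindlist(lapply(bundles, `[[`, "demo"))
  drug <- rbindlist(lapply(bundles, `[[`, "drug"))
  reac <- rbindlist(lapply(bundles, `[[`, "reac"))
  ther <- rbindlist(lapply(bundles, `[[`, "ther"))
  outc <- rbindlist(lapply(bundles, `[[`, "outc"))

  prov <- list(reports_in = nrow(demo))
  kept <- deduplicate_reports(demo)
  prov$cases_after_dedup <- length(kept)

  demo <- demo[primaryid %in% kept]
  drug <- drug[primaryid %in% kept]
  reac <- reac[primaryid %in% kept]
  ther <- ther[primaryid %in% kept]
  outc <- outc[primaryid %in% kept]

  ps <- drug[toupper(trimws(role_cod)) == "PS"]
  prov$drug_rows_ps <- nrow(ps)
  ps[, drug := normalize_drug_name(drugname, synonym_map)]
  ps[, drug_seq := suppressWarnings(as.integer(drug_seq))]
  ps <- unique(ps[!is.na(drug_seq), .(primaryid, drug_seq, drug)])

  tgt <- unique(toupper(trimws(target_pts)))
  reac[, .pt_key := toupper(trimws(pt))]
  event_ids <- unique(reac[.pt_key %in% tgt, primaryid])
  reac[, .pt_key := NULL]

  ther[, drug_seq := suppressWarnings(as.integer(dsg_drug_seq))]
  starts <- merge(ps, ther[!is.na(drug_seq),
                           .(primaryid, drug_seq, start_dt)],
                  by = c("primaryid", "drug_seq"), all.x = TRUE)
  # one therapy record per case-drug: the lowest drug_seq PS entry
  setorder(starts, primaryid, drug, drug_seq)
  starts <- starts[, .SD[1L], by = .(primaryid, drug)]
  starts[, start_date := parse_faers_date(start_dt)]

  cases <- demo[, .(
    primaryid, caseid,
    fda_date = parse_faers_date(fda_dt),
    event_date = parse_faers_date(event_dt),
    age_years = .convert_age_years(age, age_cod, cap = age_cap),
    sex = toupper(trimws(sex)),
    reporter_qualification = toupper(trimws(occp_cod)),
    reporter_country = toupper(trimws(reporter_country))
  )]
  cases[, receipt_year := as.integer(format(fda_date, "%Y"))]
  cases[, has_target_event := primaryid %in% event_ids]

  prov$cases_total <- nrow(cases)
  prov$cases_with_target_event <- sum(cases$has_target_event)
  prov$cases_with_ps_drug <- length(unique(ps$primaryid))

  dw <- NULL
  if (!is.null(drug_window)) {
    dw <- as.data.table(drug_window)
    setnames(dw, c("drug", "window_start"))
    dw[, drug := normalize_drug_name(drug, synonym_map)]
    dw[, window_start := parse_faers_date(window_start)]
  }

  structure(list(
    cases = cases,
    ps_drugs = unique(ps[, .(primaryid, drug, drug_seq)]),
    start_dates = starts[, .(primaryid, drug, start_date)],
    outcomes = unique(outc[, .(primaryid,
                               outc_cod = toupper(trimws(outc_cod)))]),
    target_pts = target_pts,
    drug_window = dw,
    provenance = prov
  ), class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat("FAERS case set:", nrow(x$cases), "cases,",
      length(unique(x$ps_drugs$drug)), "distinct PS drugs,",
      sum(x$cases$has_target_event), "target-event cases\n")
  cat("  target PTs:", paste(x$target_pts, collapse = ", "), "\n")
  invisible(x)
}

# Case ids (primaryid) of a drug's cases, honouring the optional per-drug
# receipt-date window.
.drug_case_ids <- function(case_set, drug_name) {
  ps <- case_set$ps_drugs
  ids <- unique(ps$primaryid[ps$drug == drug_name])
  dw <- case_set$drug_window
  if (!is.null(dw) && drug_name %in% dw$drug) {
    ws <- dw$window_start[dw$drug == drug_name][1L]
    if (!is.na(ws)) {
      cs <- case_set$cases
      ok <- cs$primaryid[!is.na(cs$fda_date) & cs$fda_date >= ws]
      ids <- ids[ids %in% ok]
    }
  }
  ids
}
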