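#' @importFrom data.table fread fwrite data.table as.data.table setnames
#'   setcolorder setorder := .N .SD copy rbindlist fifelse setkey
NULL

# Canonical lowercase column schema per table, in file order.
# Legacy column names (pre-2012 ISR-keyed files and assorted renames) are
# accepted through .faers_aliases and mapped onto this schema.
.faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "outc_cod")
)

.faers_aliases <- c(
  isr = "primaryid", "case" = "caseid", gndr_cod = "sex",
  i_f_cod = "init_fda_dt", occr_country = "reporter_country",
  drugname_raw = "drugname", drug_rec_act = "drug_rec_act",
  outc_code = "outc_cod"
)

# Columns that must be non-empty for a row to be kept.
.faers_required <- list(
  demo = c("primaryid", "caseid"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq"),
  outc = c("primaryid", "outc_cod")
)

.role_codes    <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Read one FAERS-style quarter of ASCII tables
#'
#' Parses the five quarterly tables (DEMO, DRUG, REAC, THER, OUTC) from
#' `$`-delimited text files with a header row, as distributed in the FAERS
#' quarterly data extracts. Column names are matched case-insensitively and
#' legacy aliases (e.g. `ISR`, `CASE`, `GNDR_COD`) are renamed to the modern
#' lowercase schema. All values are kept as raw character strings at this
#' layer; date parsing and validation happen downstream (see
#' [build_case_set()]).
#'
#' Malformed rows -- rows with an empty mandatory field, a drug role code
#' outside `PS`/`SS`/`C`/`I`, or an outcome code outside the seven-code FAERS
#' vocabulary -- are dropped and counted, never fatal. Identifiers appearing
#' in DRUG/REAC/THER/OUTC but not in DEMO are counted as orphans.
#'
#' @param path Directory containing one file per table whose name starts with
#'   the table name (case-insensitive, e.g. `DEMO23Q4.txt`), or a named
#'   character vector/list with elements `demo`, `drug`, `reac`, `ther`,
#'   `outc` giving explicit file paths.
#' @param dialect List of reader options: `sep` (default `"$"`).
#' @param quarter_label Optional label such as `"2023Q4"` stored on the bundle.
#' @return A `quarter_bundle`: a list with data.tables `demo`, `drug`, `reac`,
#'   `ther`, `outc` (character columns, canonical names), `quarter_label`,
#'   and `parse_report` -- per-table `rows_read`, `rows_kept`, `rows_dropped`
#'   plus the orphan primaryid counts.
#' @seealso [write_quarter()] for the inverse operation.
#' @export
#' @examples
#' b <- generate_faers(synthetic_spec(n_cases = 50, seed = 1))$bundle
#' d <- tempfile(); dir.create(d)
#' write_quarter(b, d)
#' b2 <- read_quarter(d)
#' b2$parse_report
read_quarter <- function(path, dialect = list(sep = "$"),
                         quarter_label = NULL) {
  sep <- if (is.null(dialect$sep)) "$" else dialect$sep
  files <- .locate_quarter_files(path)
  tables <- list()
  report <- list()
  for (tab in names(.faers_schema)) {
    f <- files[[tab]]
    if (is.na(f) || !file.exists(f))
      stop("missing mandatory FAERS table file for '", toupper(tab),
           "' under ", if (is.character(path) && length(path) == 1L)
             path else "supplied paths", call. = FALSE)
    dt <- fread(f, sep = sep, colClasses = "character", na.strings = NULL,
                header = TRUE, quote = "", fill = TRUE, strip.white = FALSE,
                showProgress = FALSE)
    setnames(dt, tolower(names(dt)))
    hit <- names(dt) %in% names(.faers_aliases)
    if (any(hit))
      setnames(dt, names(dt)[hit], unname(.faers_aliases[names(dt)[hit]]))
    missing_cols <- setdiff(.faers_schema[[tab]], names(dt))
    if (length(missing_cols) == length(.faers_schema[[tab]]))
      stop("unparseable header in ", f, ": none of the expected ",
           toupper(tab), " columns found", call. = FALSE)
    for (mc in missing_cols) dt[, (mc) := ""]
    dt <- dt[, .faers_schema[[tab]], with = FALSE]
    rows_read <- nrow(dt)
    keep <- rep(TRUE, rows_read)
    for (rc in .faers_required[[tab]])
      keep <- keep & !is.na(dt[[rc]]) & trimws(dt[[rc]]) != ""
    if (tab == "drug")
      keep <- keep & toupper(trimws(dt$role_cod)) %in% .role_codes
    if (tab == "outc")
      keep <- keep & toupper(trimws(dt$outc_cod)) %in% .outcome_codes
    dt <- dt[keep]
    tables[[tab]] <- dt
    report[[tab]] <- list(rows_read = rows_read, rows_kept = nrow(dt),
                          rows_dropped = rows_read - sum(keep))
  }
  if (anyDuplicated(tables$demo$primaryid)) {
    # primaryid must be unique within DEMO; keep first occurrence, count rest
    dup <- duplicated(tables$demo$primaryid)
    report$demo$rows_dropped <- report$demo$rows_dropped + sum(dup)
    report$demo$rows_kept <- report$demo$rows_kept - sum(dup)
    tables$demo <- tables$demo[!dup]
  }
  known <- tables$demo$primaryid
  orphans <- lapply(c("drug", "reac", "ther", "outc"), function(tab) {
    unique(setdiff(tables[[tab]]$primaryid, known))
  })
  names(orphans) <- c("drug", "reac", "ther", "outc")
  report$orphan_primaryids <- orphans
  structure(list(demo = tables$demo, drug = tables$drug, reac = tables$reac,
                 ther = tables$ther, outc = tables$outc,
                 quarter_label = quarter_label, parse_report = report),
            class = "quarter_bundle")
}

.locate_quarter_files <- function(path) {
  tabs <- names(.faers_schema)
  if (is.character(path) && length(path) == 1L && dir.exists(path)) {
    found <- vapply(tabs, function(tab) {
      hits <- list.files(path, pattern = paste0("^", tab), ignore.case = TRUE,
                         full.names = TRUE)
      if (length(hits) == 0L) NA_character_ else sort(hits)[1L]
    }, character(1))
    return(as.list(found))
  }
  path <- as.list(path)
  names(path) <- tolower(names(path))
  out <- lapply(tabs, function(tab)
    if (is.null(path[[tab]])) NA_character_ else path[[tab]])
  names(out) <- tabs
  out
}

#' Write a quarter bundle as FAERS-style ASCII tables
#'
#' Emits one `$`-delimited file per table (`DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#' `THER.txt`, `OUTC.txt`) with a header row, byte-stable for a fixed bundle.
#' The FAERS dialect has no quoting, so a field containing the delimiter
#' cannot be represented; such fields are rejected with an error rather than
#' silently corrupted, which keeps write-then-read an exact inverse.
#'
#' @param bundle A `quarter_bundle` (from [read_quarter()],
#'   [generate_faers()] or [worked_fixture()]).
#' @param path Output directory (created if absent).
#' @param dialect List of writer options: `sep` (default `"$"`).
#' @return Invisibly, the named vector of files written.
#' @export
write_quarter <- function(bundle, path, dialect = list(sep = "$")) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  sep <- if (is.null(dialect$sep)) "$" else dialect$sep
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory ", path, call. = FALSE)
  out <- character(0)
  for (tab in names(.faers_schema)) {
    dt <- copy(as.data.table(bundle[[tab]]))
    for (j in names(dt)) {
      v <- as.character(dt[[j]])
      v[is.na(v)] <- ""
      if (any(grepl(sep, v, fixed = TRUE)))
        stop("field in table '", tab, "' column '", j,
             "' contains the delimiter '", sep,
             "'; the FAERS dialect has no quoting", call. = FALSE)
      dt[, (j) := v]
    }
    f <- file.path(path, paste0(toupper(tab), ".txt"))
    fwrite(dt, f, sep = sep, quote = FALSE, na = "")
    out[tab] <- f
  }
  invisible(out)
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat("FAERS quarter bundle",
      if (!is.null(x$quarter_label)) paste0("[", x$quarter_label, "]"), "\n")
  for (tab in names(.faers_schema))
    cat(sprintf("  %-5s %6d rows\n", toupper(tab), nrow(x[[tab]])))
  pr <- x$parse_report
  if (!is.null(pr)) {
    dropped <- sum(vapply(pr[names(.faers_schema)],
                          function(r) r$rows_dropped, numeric(1)))
    orph <- sum(lengths(pr$orphan_primaryids))
    cat(sprintf("  parse: %d rows dropped, %d orphan primaryids\n",
                dropped, orph))
  }
  invisible(x)
}
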