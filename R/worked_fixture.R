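#' A small, fully hand-auditable quarter bundle
#'
#' Returns a deterministic 14-report / 12-case bundle built in code, sized
#' so that every downstream quantity -- deduplication survivors,
#' contingency cells, reporting odds ratios, time-to-onset values,
#' severity proportions -- can be checked by hand. The enumerated expected
#' values live in the packaged expectation file
#' (`extdata/worked_fixture_expected.json`, see
#' [worked_fixture_expected()]).
#'
#' The bundle exercises the rules the pipeline must honour: a later-dated
#' revision superseding an earlier report, an FDA-date tie broken by the
#' higher primaryid, both MedDRA spellings of the target term plus
#' case/whitespace variants, a concomitant-only drug entry (excluded from
#' primary-suspect statistics), a case with no primary-suspect drug, a
#' negative onset interval, a missing event date, an age reported in
#' months, and a case carrying both a death and a life-threatening outcome
#' (severe counted once).
#'
#' @return A `quarter_bundle` with drugs `drugx`/`drugy`/`drugz` and the
#'   hyponatremia preferred terms.
#' @export
worked_fixture <- function() {
  demo <- data.table(
    primaryid = c("1011", "1012", "1021", "1031", "1032", "1041", "1051",
                  "1061", "1071", "1081", "1091", "1101", "1111", "1121"),
    caseid = c("101", "101", "102", "103", "103", "104", "105", "106",
               "107", "108", "109", "110", "111", "112"),
    fda_dt = c("20200110", "20200215", "20200210", "20200301", "20200301",
               "20200405", "20200501", "20200601", "20200701", "20200801",
               "20200901", "20201001", "20201101", "20201201"),
    event_dt = c("20200131", "20200131", "20200210", "20200220", "20200215",
                 "20200401", "20200415", "20200520", "20200625", "20200720",
                 "20200810", "20200915", "", "20200311"),
    age = c("72", "72", "65", "840", "840", "55", "", "81", "45", "33",
            "60", "50", "77", "68"),
    age_cod = c("YR", "YR", "YR", "MON", "MON", "YR", "", "YR", "YR", "YR",
                "YR", "YR", "YR", "YR"),
    sex = c("F", "F", "M", "F", "F", "M", "F", "F", "M", "", "M", "F",
            "F", "M"),
    occp_cod = c("MD", "MD", "PH", "CN", "CN", "MD", "CN", "MD", "OT",
                 "LW", "MD", "PH", "MD", "MD"),
    reporter_country = c("US", "US", "US", "JP", "JP", "FR", "US", "GB",
                         "US", "DE", "US", "JP", "US", "US"))
  drug <- data.table(
    primaryid = c("1011", "1012", "1021", "1031", "1032", "1041", "1041",
                  "1051", "1061", "1071", "1081", "1091", "1101", "1101",
                  "1111", "1121"),
    drug_seq = c("1", "1", "1", "1", "1", "1", "2", "1", "1", "1", "1",
                 "1", "1", "2", "1", "1"),
    role_cod = c("PS", "PS", "PS", "PS", "PS", "C", "PS", "PS", "PS",
                 "PS", "SS", "PS", "PS", "C", "PS", "PS"),
    drugname = c("DrugX", "DrugX", "DRUGX", "DrugX", "DrugX", "DrugX",
                 "DrugY", "DrugY", "drugy", "DrugY", "DrugZ", "DrugX",
                 "DrugX", "DrugY", "DrugY", " DrugX "))
  reac <- data.table(
    primaryid = c("1011", "1012", "1021", "1021", "1031", "1032", "1041",
                  "1051", "1061", "1071", "1081", "1091", "1101", "1111",
                  "1121"),
    pt = c("Hyponatraemia", "Hyponatraemia", "HYPONATREMIA", "Nausea",
           "Nausea", "Nausea", "Hyponatraemia", "Headache", "HYPONATREMIA",
           "Nausea", "Hyponatraemia", "hyponatraemia", "Rash", "Dizziness",
           " hyponatraemia "))
  ther <- data.table(
    primaryid = c("1012", "1021", "1032", "1041", "1051", "1061", "1091",
                  "1121"),
    dsg_drug_seq = c("1", "1", "1", "2", "1", "1", "1", "1"),
    start_dt = c("20200101", "20200210", "20200201", "20200320", "20200410",
                 "20200510", "20200820", "20200301"))
  outc <- data.table(
    primaryid = c("1021", "1041", "1061", "1091", "1091", "1121"),
    outc_cod = c("HO", "OT", "DE", "DE", "LT", "HO"))
  structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, quarter_label = "fixture",
                 parse_report = NULL),
            class = "quarter_bundle")
}

#' Hand-enumerated expectations for the worked fixture
#'
#' Reads the packaged expectation file recording, once, the hand-derived
#' answers for [worked_fixture()]: deduplication survivors, contingency
#' cells and reporting odds ratios per drug, retained onset intervals and
#' their quartiles, and severity proportions. Requires the `jsonlite`
#' package.
#'
#' @return Nested list mirroring the JSON file.
#' @export
worked_fixture_expected <- function() {
  f <- system.file("extdata", "worked_fixture_expected.json",
                   package = "faerssignal", mustWork = TRUE)
  jsonlite::fromJSON(f, simplifyVector = TRUE)
}
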