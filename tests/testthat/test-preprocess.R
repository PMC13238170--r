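test_that("deduplication keeps max FDA_DT, then max PRIMARYID", {
  demo <- data.table(primaryid = c("1001", "1002", "1003"),
                     caseid = "100",
                     fda_dt = c("20230101", "20230301", "20230301"))
  expect_equal(deduplicate_reports(demo), "1003")
  single <- data.table(primaryid = "7", caseid = "9", fda_dt = "20200101")
  expect_equal(deduplicate_reports(single), "7")
  # unparseable fda_dt sorts lowest: the dated revision wins
  demo2 <- data.table(primaryid = c("5", "4"), caseid = "1",
                      fda_dt = c("", "20200101"))
  expect_equal(deduplicate_reports(demo2), "4")
})

test_that("dedup on generator output recovers the recorded survivors", {
  g <- generate_faers(synthetic_spec(n_cases = 800, duplicate_rate = 0.4,
                                     seed = 19))
  kept <- deduplicate_reports(g$bundle$demo)
  expect_equal(length(kept), 800L)
  expect_setequal(kept, g$truth$survivors$survivor_primaryid)
})

test_that("date parsing accepts only complete real calendar dates", {
  expect_equal(parse_faers_date("20230110"), as.Date("2023-01-10"))
  expect_true(is.na(parse_faers_date("202301")))    # partial
  expect_true(is.na(parse_faers_date("2023")))      # partial
  expect_true(is.na(parse_faers_date("20230230")))  # impossible
  expect_true(is.na(parse_faers_date("")))
  expect_true(is.na(parse_faers_date("2023011X")))
  expect_equal(parse_faers_date("20040229"), as.Date("2004-02-29"))  # leap
})

test_that("drug-name normalization folds case/space and applies the map", {
  expect_equal(normalize_drug_name("LASIX", c(lasix = "furosemide")),
               "furosemide")
  expect_equal(normalize_drug_name("Furosemide "), "furosemide")
  expect_equal(normalize_drug_name("drugX123"), "drugx123")
  expect_equal(normalize_drug_name("FUROSEMIDE  SODIUM",
                                   c("furosemide sodium" = "furosemide")),
               "furosemide")
})

test_that("build_case_set applies PS restriction and PT matching", {
  b <- tiny_bundle(
    demo = data.table(primaryid = c("1", "2"), caseid = c("1", "2"),
                      fda_dt = "20200101"),
    drug = data.table(primaryid = c("1", "2", "2"),
                      drug_seq = c("1", "1", "2"),
                      role_cod = c("PS", "C", "PS"),
                      drugname = c("DrugX", "DrugX", "DrugY")),
    reac = data.table(primaryid = c("1", "2"),
                      pt = c("  hypoNATRAEMIA ", "Nausea")))
  cs <- build_case_set(b)
  expect_equal(nrow(cs$cases), 2L)
  expect_true(cs$cases[primaryid == "1", has_target_event])
  expect_false(cs$cases[primaryid == "2", has_target_event])
  # role C never contributes to ps_drugs
  expect_equal(cs$ps_drugs[primaryid == "2", drug], "drugy")
  expect_false("drugx" %in% cs$ps_drugs[primaryid == "2", drug])
})

test_that("case sets are idempotent under rebuilds and caseid-unique", {
  g <- generate_faers(synthetic_spec(n_cases = 500, seed = 23))
  cs1 <- build_case_set(g$bundle)
  expect_equal(anyDuplicated(cs1$cases$caseid), 0L)
  # rebuilding from the already-deduplicated demo yields identical cases
  dedup_bundle <- g$bundle
  keep <- dedup_bundle$demo$primaryid %in% cs1$cases$primaryid
  dedup_bundle$demo <- dedup_bundle$demo[keep]
  cs2 <- build_case_set(dedup_bundle)
  expect_equal(data.table::setorder(data.table::copy(cs1$cases), primaryid),
               data.table::setorder(data.table::copy(cs2$cases), primaryid))
  # provenance counts never increase along the filter sequence
  expect_lte(cs1$provenance$cases_after_dedup, cs1$provenance$reports_in)
  expect_lte(cs1$provenance$cases_with_target_event,
             cs1$provenance$cases_total)
})

test_that("target matching is invariant to PT case and whitespace", {
  for (pt in c("HYPONATREMIA", "hyponatraemia", " Hyponatraemia  ",
               "HypoNatremia")) {
    b <- flat_bundle("drugx", TRUE)
    b$reac$pt <- pt
    cs <- build_case_set(b)
    expect_true(all(cs$cases$has_target_event), info = pt)
  }
})

test_that("age conversion honours FAERS unit codes and the cap", {
  b <- tiny_bundle(demo = data.table(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = "20200101",
    age = c("7", "840", "24", "104", "730.5", "999"),
    age_cod = c("DEC", "MON", "MON", "WK", "DY", "YR")))
  cs <- build_case_set(b)
  a <- cs$cases[order(as.integer(caseid)), age_years]
  expect_equal(a[1:5], c(70, 70, 2, 2, 2))
  expect_true(is.na(a[6]))  # above the 120-year cap
})

test_that("per-drug receipt windows drop early cases from that drug only", {
  b <- flat_bundle(c("drugx", "drugx", "drugy"), c(TRUE, TRUE, TRUE))
  b$demo$fda_dt <- c("20100101", "20200101", "20100101")
  dw <- data.frame(drug = "drugx", start = "20150101")
  cs <- build_case_set(b, drug_window = dw)
  tab <- contingency_table(cs, "drugx")
  expect_equal(tab$a, 1L)       # the 2010 drugx case is outside the window
  expect_equal(contingency_table(cs, "drugy")$a, 1L)
})
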