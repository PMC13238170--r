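#' Specification for the synthetic FAERS-shaped data generator
#'
#' Describes a population of spontaneous reports with known ground truth:
#' per-drug prescription and event probabilities (hence planted reporting
#' odds ratios), per-drug Weibull onset laws, report duplication, date
#' missingness and errors, demographic mixtures and outcome severity. The
#' defaults emulate the statistical structure of a drug-induced
#' hyponatremia screen of spontaneous reports at desk scale: a handful of
#' named drugs spanning strong to null signals (diuretic-like, SSRI-like,
#' checkpoint-inhibitor-like profiles, with onset laws in the range reported
#' for those classes), a 2% background event rate among other-drug cases so
#' contingency cells are populated at a few thousand cases, and the sex,
#' age, severity and reporting-window mixtures of a 2004-2023 surveillance
#' population.
#'
#' @param n_cases Number of distinct cases (caseids) to generate.
#' @param drugs data.frame with columns `name`, `p_assign` (marginal
#'   probability a case's primary-suspect drug is this one), `p_event`
#'   (target-event probability given the drug), `alpha`, `beta` (Weibull
#'   onset law, days), `severity` (probability of a DE/LT outcome given the
#'   target event). Defaults described above.
#' @param background_event_rate Target-event probability for cases assigned
#'   to a background drug.
#' @param n_background_drugs Number of filler drugs sharing the residual
#'   assignment probability.
#' @param duplicate_rate Probability a case emits more than one report
#'   version (2 with probability 0.8, 3 with 0.2, given duplicated).
#' @param missing_date_rate Probability a case's event or therapy start
#'   date is blanked.
#' @param negative_date_rate Probability the two dates are swapped to
#'   produce an erroneous negative onset interval.
#' @param background_severity Severity probability for background drugs.
#' @param sex_probs,age_band_probs,country_probs,reporter_probs Named
#'   probability vectors for the demographic mixtures (an `unknown` entry
#'   produces missing values).
#' @param date_range Character vector of two `YYYYMMDD` bounds for therapy
#'   start dates (the 2004-2023 surveillance window by default).
#' @param seed Integer seed; [generate_faers()] is reproducible given it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_cases = 5000,
    drugs = data.frame(
      name = c("furosemide", "hydrochlorothiazide", "sertraline",
               "nivolumab", "pregabalin"),
      p_assign = c(0.05, 0.03, 0.04, 0.02, 0.03),
      p_event = c(0.33, 0.49, 0.102, 0.14, 0.02),
      alpha = c(190.9, 374.36, 36.96, 82.99, 10.69),
      beta = c(0.56, 0.50, 0.50, 0.78, 1.08),
      severity = c(0.18, 0.15, 0.10, 0.37, 0.08)
    ),
    background_event_rate = 0.02,
    n_background_drugs = 20,
    duplicate_rate = 0.10,
    missing_date_rate = 0.15,
    negative_date_rate = 0.02,
    background_severity = 0.178,
    sex_probs = c(F = 0.539, M = 0.360, unknown = 0.101),
    age_band_probs = c("0-18" = 0.03, "18-45" = 0.15, "45-65" = 0.30,
                       "65-85" = 0.401, "85-105" = 0.05, unknown = 0.069),
    country_probs = c(US = 0.27, JP = 0.12, FR = 0.10, GB = 0.08,
                      DE = 0.08, CA = 0.05, other = 0.30),
    reporter_probs = c(MD = 0.40, PH = 0.12, OT = 0.10, CN = 0.33,
                       unknown = 0.05),
    date_range = c("20040101", "20230630"),
    seed = 20231231L) {
  drugs <- as.data.frame(drugs)
  probs <- c(drugs$p_assign, drugs$p_event, background_event_rate,
             duplicate_rate, missing_date_rate, negative_date_rate,
             drugs$severity, background_severity, sex_probs,
             age_band_probs, country_probs, reporter_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (sum(drugs$p_assign) >= 1)
    stop("drug assignment probabilities must sum to < 1 to leave room ",
         "for background drugs", call. = FALSE)
  if (any(drugs$alpha <= 0) || any(drugs$beta <= 0))
    stop("Weibull laws need positive scale and shape", call. = FALSE)
  stopifnot(n_cases >= 1, n_background_drugs >= 1)
  structure(list(
    n_cases = as.integer(n_cases), drugs = drugs,
    background_event_rate = background_event_rate,
    n_background_drugs = as.integer(n_background_drugs),
    duplicate_rate = duplicate_rate,
    missing_date_rate = missing_date_rate,
    negative_date_rate = negative_date_rate,
    background_severity = background_severity,
    sex_probs = sex_probs, age_band_probs = age_band_probs,
    country_probs = country_probs, reporter_probs = reporter_probs,
    date_range = date_range, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' True reporting odds ratios implied by a synthetic spec
#'
#' The estimand of the per-drug screen in closed form: for drug z with
#' event probability p_z, the population odds ratio against the mixture of
#' all other assignment categories is
#' `[p_z/(1-p_z)] / [p_rest/(1-p_rest)]`, where `p_rest` is the
#' assignment-weighted mean event probability among non-z cases.
#'
#' @param spec A `synthetic_spec`.
#' @return data.table `drug`, `p_event`, `true_or`.
#' @export
true_odds_ratios <- function(spec) {
  d <- spec$drugs
  w <- c(d$p_assign, 1 - sum(d$p_assign))
  p <- c(d$p_event, spec$background_event_rate)
  rbindlist(lapply(seq_len(nrow(d)), function(i) {
    p_rest <- sum(w[-i] * p[-i]) / sum(w[-i])
    data.table(drug = d$name[i], p_event = d$p_event[i],
               true_or = (p[i] / (1 - p[i])) / (p_rest / (1 - p_rest)))
  }))
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a FAERS-shaped quarter bundle with recorded ground truth
#'
#' Draws `n_cases` cases per the spec: each case gets one primary-suspect
#' drug (a named drug or a background filler), a Bernoulli target event at
#' that drug's rate, a therapy start date uniform in the surveillance
#' window, an event date equal to start plus a Weibull onset draw (rounded
#' to whole days), an FDA receipt date shortly after the event, MedDRA-style
#' preferred-term lists (the target PT in its MedDRA spelling for event
#' cases), demographics, and outcome codes (DE/LT at the drug's severity
#' rate for event cases). Date missingness and swapped (negative-interval)
#' dates are injected at the configured rates. Duplicated cases emit extra
#' earlier-or-equal-dated report versions of the same caseid whose correct
#' survivor under the FDA deduplication rule is recorded, so deduplication
#' has a unique known answer.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `bundle` (a `quarter_bundle`) and `truth`: per-drug
#'   realized assignment/event counts joined to [true_odds_ratios()] and
#'   the planted Weibull laws and severity rates; `survivors` (caseid,
#'   surviving primaryid, n_versions); and the per-case assignment table
#'   `cases` (caseid, drug, event, tto_days, date_status).
#' @export
generate_faers <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases
  d <- spec$drugs
  bg_names <- sprintf("backgrounddrug%02d", seq_len(spec$n_background_drugs))
  assign_names <- c(d$name, bg_names)
  assign_probs <- c(d$p_assign,
                    rep((1 - sum(d$p_assign)) / spec$n_background_drugs,
                        spec$n_background_drugs))
  p_event_by <- stats::setNames(c(d$p_event, rep(spec$background_event_rate,
                                                 spec$n_background_drugs)),
                                assign_names)
  alpha_by <- stats::setNames(c(d$alpha, rep(60, spec$n_background_drugs)),
                              assign_names)
  beta_by <- stats::setNames(c(d$beta, rep(0.8, spec$n_background_drugs)),
                             assign_names)
  sev_by <- stats::setNames(c(d$severity, rep(spec$background_severity,
                                              spec$n_background_drugs)),
                            assign_names)

  caseid <- as.character(1000000L + seq_len(n))
  drug_of <- sample(assign_names, n, replace = TRUE, prob = assign_probs)
  event <- stats::runif(n) < p_event_by[drug_of]

  d0 <- as.Date(spec$date_range[1], "%Y%m%d")
  d1 <- as.Date(spec$date_range[2], "%Y%m%d")
  start_date <- d0 + floor(stats::runif(n) * (as.numeric(d1 - d0) + 1))
  tto_days <- round(stats::rweibull(n, shape = beta_by[drug_of],
                                    scale = alpha_by[drug_of]))
  event_date <- start_date + tto_days
  fda_date <- event_date + sample(0:90, n, replace = TRUE)

  # date corruption: missing (blank one of the two dates) or swapped
  u <- stats::runif(n)
  date_status <- rep("ok", n)
  date_status[u < spec$missing_date_rate] <- "missing"
  date_status[u >= spec$missing_date_rate &
                u < spec$missing_date_rate + spec$negative_date_rate &
                tto_days > 0] <- "swapped"
  blank_event <- date_status == "missing" & stats::runif(n) < 0.5
  blank_start <- date_status == "missing" & !blank_event
  sw <- date_status == "swapped"
  tmp <- start_date[sw]; start_date[sw] <- event_date[sw]
  event_date[sw] <- tmp

  fmt <- function(x) format(x, "%Y%m%d")
  event_raw <- fmt(event_date); event_raw[blank_event] <- ""
  start_raw <- fmt(start_date); start_raw[blank_start] <- ""

  sex <- .sample_cat(n, spec$sex_probs)
  sex[sex == "unknown"] <- ""
  band <- .sample_cat(n, spec$age_band_probs)
  band_lo <- c("0-18" = 0, "18-45" = 18, "45-65" = 45, "65-85" = 65,
               "85-105" = 85)
  band_hi <- c("0-18" = 18, "18-45" = 45, "45-65" = 65, "65-85" = 85,
               "85-105" = 105)
  age <- rep("", n); age_cod <- rep("", n)
  known <- band != "unknown"
  age_years <- numeric(n)
  age_years[known] <- band_lo[band[known]] +
    stats::runif(sum(known)) * (band_hi[band[known]] - band_lo[band[known]])
  # a slice of reports carries age in months, exercising unit conversion
  in_months <- known & stats::runif(n) < 0.05
  age[known] <- as.character(round(age_years[known], 0))
  age_cod[known] <- "YR"
  age[in_months] <- as.character(round(age_years[in_months] * 12, 0))
  age_cod[in_months] <- "MON"

  country <- .sample_cat(n, spec$country_probs)
  country[country == "other"] <- sample(c("IT", "ES", "AU", "CN", "BR"),
                                        sum(country == "other"),
                                        replace = TRUE)
  occp <- .sample_cat(n, spec$reporter_probs)
  occp[occp == "unknown"] <- ""

  # outcomes: DE/LT at the drug severity rate for event cases; otherwise a
  # non-severe code
  severe <- event & stats::runif(n) < sev_by[drug_of]
  outc <- ifelse(severe,
                 ifelse(stats::runif(n) < 0.6, "DE", "LT"),
                 sample(c("HO", "OT", "DS"), n, replace = TRUE,
                        prob = c(0.4, 0.5, 0.1)))

  bg_pts <- c("Nausea", "Headache", "Dizziness", "Fatigue", "Rash",
              "Pyrexia", "Vomiting", "Diarrhoea")
  target_pt <- ifelse(stats::runif(n) < 0.5, "Hyponatraemia", "HYPONATREMIA")
  extra_pt <- sample(bg_pts, n, replace = TRUE)

  # report versions: duplicated cases carry k in {2,3} versions; the
  # survivor (max fda_dt, then max primaryid) is always the last version
  dup <- stats::runif(n) < spec$duplicate_rate
  k <- ifelse(dup, ifelse(stats::runif(n) < 0.8, 2L, 3L), 1L)
  ver_case <- rep(seq_len(n), k)
  ver_no <- sequence(k)
  n_ver <- length(ver_case)
  primaryid <- paste0(caseid[ver_case], ver_no)
  back <- (k[ver_case] - ver_no) * sample(0:15, n_ver, replace = TRUE)
  ver_fda <- fda_date[ver_case] - back

  demo <- data.table(
    primaryid = primaryid, caseid = caseid[ver_case],
    fda_dt = fmt(ver_fda), event_dt = event_raw[ver_case],
    age = age[ver_case], age_cod = age_cod[ver_case],
    sex = sex[ver_case], occp_cod = occp[ver_case],
    reporter_country = country[ver_case])

  # PS row per version; ~30% of cases also list a concomitant drug
  conco <- stats::runif(n) < 0.3
  conco_name <- sample(bg_names, n, replace = TRUE)
  drug_tab <- rbind(
    data.table(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
               drugname = toupper(drug_of[ver_case])),
    data.table(primaryid = primaryid[conco[ver_case]], drug_seq = "2",
               role_cod = "C",
               drugname = toupper(conco_name[ver_case[conco[ver_case]]])))

  reac <- rbind(
    data.table(primaryid = primaryid[event[ver_case]],
               pt = target_pt[ver_case[event[ver_case]]]),
    data.table(primaryid = primaryid, pt = extra_pt[ver_case]))

  ther <- data.table(primaryid = primaryid, dsg_drug_seq = "1",
                     start_dt = start_raw[ver_case])
  ther <- ther[start_dt != ""]

  outc_tab <- data.table(primaryid = primaryid, outc_cod = outc[ver_case])

  for (tb in list(demo, drug_tab, reac, ther, outc_tab)) setkey(tb, NULL)
  setorder(drug_tab, primaryid, drug_seq)
  setorder(reac, primaryid, pt)

  bundle <- structure(list(demo = demo, drug = drug_tab, reac = reac,
                           ther = ther, outc = outc_tab,
                           quarter_label = "synthetic",
                           parse_report = NULL),
                      class = "quarter_bundle")

  survivors <- data.table(caseid = caseid,
                          survivor_primaryid = paste0(caseid, k),
                          n_versions = k)
  case_truth <- data.table(caseid = caseid, drug = drug_of, event = event,
                           tto_days = tto_days, date_status = date_status,
                           severe = severe)
  realized <- case_truth[, .(n_assigned = .N, n_event = sum(event)),
                         by = drug]
  drug_truth <- merge(
    data.table(drug = assign_names,
               p_event = unname(p_event_by),
               alpha = unname(alpha_by), beta = unname(beta_by),
               severity = unname(sev_by)),
    realized, by = "drug", all.x = TRUE)
  drug_truth[is.na(n_assigned), `:=`(n_assigned = 0L, n_event = 0L)]
  drug_truth <- merge(drug_truth,
                      true_odds_ratios(spec)[, .(drug, true_or)],
                      by = "drug", all.x = TRUE)

  list(bundle = bundle,
       truth = list(drugs = drug_truth[], survivors = survivors,
                    cases = case_truth, spec = spec))
}
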