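# faerssignal

Pharmacovigilance signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse-event reports, focused on drug-induced
hyponatremia (serum sodium < 135 mmol/L) but configurable for any MedDRA
preferred-term target.

Spontaneous-report databases have no denominator, so risk is screened by
*disproportionality*: for each drug, deduplicated cases are
cross-classified into the 2×2 table (a, b, c, d) of target-event vs other
events by target-drug vs all other drugs, and the reporting odds ratio

    ROR = ad / bc,   95% CI = exp( ln ROR ± 1.96 · √(1/a + 1/b + 1/c + 1/d) )

is flagged as a potential signal when **a ≥ 3 and the lower 95% bound
exceeds 1**. For flagged drugs, the days between therapy start and event
onset are summarized (median, IQR) and fitted with a two-parameter Weibull
law by profile-likelihood maximum likelihood; the shape parameter β and
its 95% Wald interval classify the hazard as *early failure* (β < 1,
falling hazard), *random failure* (β ≈ 1, constant) or *wear-out failure*
(β > 1, rising).

The package covers the full pipeline:

- `read_quarter()` / `write_quarter()` — the five `$`-delimited FAERS
  quarterly ASCII tables (DEMO, DRUG, REAC, THER, OUTC), with a parse
  report and legacy-column handling;
- `build_case_set()` — FDA-rule deduplication (max FDA_DT, then max
  PRIMARYID per CASEID), primary-suspect restriction, preferred-term case
  identification, date/age validation;
- `screen_signals()`, `ror_ci()`, `signal_flag()`,
  `recover_ror_from_ci()` — the disproportionality screen;
- `tto_table()`, `fit_weibull()`, `classify_failure()` — the
  time-to-onset analysis;
- `describe_cases()`, `outcome_severity()` — demographic and
  outcome-severity tabulations;
- `generate_faers()` — a synthetic-report generator with recorded ground
  truth (planted odds ratios, Weibull onset laws, duplicate structure),
  making every stage testable without external downloads;
- `run_pipeline()` — end-to-end orchestration with deterministic tabular
  outputs (also scriptable via `inst/scripts/faerssignal-cli.R`).

## Worked example

```r
library(faerssignal)

g  <- generate_faers(synthetic_spec(n_cases = 4000, seed = 42))
cs <- build_case_set(g$bundle)
screen_signals(cs, top_k = 4)
#>                   drug     a     b     c     d        ror     ci_low   ci_high is_signal
#> 1:          furosemide    82   124   168  3626 14.2728495 10.3747347 19.635609      TRUE
#> 2: hydrochlorothiazide    64    61   186  3689 20.8087432 14.2248354 30.439986      TRUE
#> 3:          sertraline    27   131   223  3619  3.3448465  2.1633529  5.171601      TRUE
#> 4:           nivolumab     9    64   241  3686  2.1508039  1.0576289  4.373895      TRUE

tto_table(cs, drugs = c("furosemide", "sertraline"))
#>          drug  n median   q1     q3     alpha  alpha_lo  alpha_hi      beta   beta_lo   beta_hi failure_type
#> 1: furosemide 70  109.5 23.5 441.50 195.97713 106.30602 285.64823 0.5399220 0.4420629 0.6377811        early
#> 2: sertraline 22   12.0  2.0  37.50  25.04719   5.38188  44.71249 0.5628700 0.3834187 0.7423212        early
```

The generator planted furosemide-like and hydrochlorothiazide-like drugs
with strong excess event rates (closed-form odds ratios ≈ 11.6 and 22.0
under these defaults, `true_odds_ratios()`): the screen flags both, with
intervals consistent with truth. The planted onset law for the
furosemide-like drug was Weibull(α = 190.9 days, β = 0.56): the fit
recovers α ≈ 196, β ≈ 0.54 and classifies the hazard `early`, i.e. onset
risk concentrates soon after starting therapy (median 109.5 days here,
with a long tail). Cases with missing or reversed therapy/event dates are
excluded and counted, which is why n = 70 of 82 event cases enter the fit.

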