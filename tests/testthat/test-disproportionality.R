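test_that("contingency cells match a hand-counted six-case example", {
  drugs <- c("x", "x", "y", "y", "y", "x")
  events <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  cs <- build_case_set(flat_bundle(drugs, events))
  tab <- contingency_table(cs, "x")
  expect_equal(tab[c("a", "b", "c", "d")],
               list(a = 2L, b = 1L, c = 1L, d = 2L))
  # drug absent from the case set
  ten <- build_case_set(flat_bundle(rep("y", 10),
                                    c(rep(TRUE, 4), rep(FALSE, 6))))
  tz <- contingency_table(ten, "zzz")
  expect_equal(tz[c("a", "b", "c", "d")],
               list(a = 0L, b = 0L, c = 4L, d = 6L))
})

test_that("cells equal an independent naive count and conserve n", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    drugs <- sample(c("u", "v", "w"), n, replace = TRUE)
    events <- sample(c(TRUE, FALSE), n, replace = TRUE)
    cs <- build_case_set(flat_bundle(drugs, events))
    for (g in unique(drugs)) {
      tab <- contingency_table(cs, g)
      expect_equal(tab[c("a", "b", "c", "d")], naive_cells(drugs, events, g))
      expect_equal(tab$a + tab$b + tab$c + tab$d, n)
    }
  }
})

test_that("ror_ci reproduces the Wald formula at high precision", {
  est <- ror_ci(c(a = 5, b = 10, c = 20, d = 400))
  expect_equal(est$ror, 10.0)
  # direct evaluation of exp(ln(ad/bc) +- z sqrt(1/a+1/b+1/c+1/d))
  se <- sqrt(1 / 5 + 1 / 10 + 1 / 20 + 1 / 400)
  z <- qnorm(0.975)
  expect_equal(est$ci_low, exp(log(10) - z * se), tolerance = 1e-12)
  expect_equal(est$ci_high, exp(log(10) + z * se), tolerance = 1e-12)
  expect_equal(round(est$ci_low, 2), 3.12)
  expect_equal(round(est$ci_high, 2), 32.02)
})

test_that("uniform tables give ROR 1 with log-symmetric bounds", {
  for (k in c(1, 4, 17)) {
    est <- ror_ci(c(a = k, b = k, c = k, d = k))
    expect_equal(est$ror, 1.0)
    expect_equal(log(est$ci_low), -log(est$ci_high), tolerance = 1e-12)
    # Wald identity: the point estimate is the geometric CI midpoint
    expect_equal(recover_ror_from_ci(est$ci_low, est$ci_high), est$ror,
                 tolerance = 1e-12)
  }
})

test_that("zero cells are non-estimable, not corrected", {
  est <- ror_ci(c(a = 0, b = 5, c = 5, d = 5))
  expect_false(est$estimable)
  expect_true(is.na(est$ror))
  expect_false(signal_flag(0, est$ci_low))
})

test_that("row swap inverts the ROR and swaps the CI bounds", {
  est <- ror_ci(c(a = 7, b = 3, c = 11, d = 190))
  swp <- ror_ci(c(a = 11, b = 190, c = 7, d = 3))
  expect_equal(swp$ror, 1 / est$ror, tolerance = 1e-12)
  expect_equal(swp$ci_low, 1 / est$ci_high, tolerance = 1e-12)
  expect_equal(swp$ci_high, 1 / est$ci_low, tolerance = 1e-12)
})

test_that("signal rule: a >= 3 and lower bound above one", {
  expect_true(signal_flag(3, 1.01))
  expect_false(signal_flag(2, 50))
  expect_false(signal_flag(1000, 0.99))
  expect_false(signal_flag(3, NA))
})

test_that("increasing a with b,c,d fixed never unsets a signal", {
  b <- 10; c_ <- 40; d <- 900
  flagged <- FALSE
  for (a in 1:60) {
    est <- ror_ci(c(a = a, b = b, c = c_, d = d))
    f <- signal_flag(a, est$ci_low)
    if (flagged) expect_true(f, info = paste("a =", a))
    flagged <- flagged || f
  }
  expect_true(flagged)
})

test_that("Wald interval covers a known odds ratio at nominal rate", {
  set.seed(97)
  omega <- 3; n <- 2000
  p0 <- 0.10                      # event rate without drug
  p1 <- omega * p0 / (1 - p0 + omega * p0)  # odds(p1)/odds(p0) = omega
  reps <- 2000
  n_drug <- rbinom(reps, n, 0.3)
  a <- rbinom(reps, n_drug, p1)
  b <- n_drug - a
  c_ <- rbinom(reps, n - n_drug, p0)
  d <- n - n_drug - c_
  cover <- mapply(function(a, b, c_, d) {
    if (min(a, b, c_, d) == 0) return(NA)
    est <- ror_ci(c(a = a, b = b, c = c_, d = d))
    est$ci_low <= omega && omega <= est$ci_high
  }, a, b, c_, d)
  expect_equal(mean(cover, na.rm = TRUE), 0.95, tolerance = 0.02 / 0.95)
})

test_that("screening ranks by case count with lexicographic ties", {
  g <- generate_faers(synthetic_spec(n_cases = 3000, seed = 5))
  cs <- build_case_set(g$bundle)
  sig <- screen_signals(cs)
  expect_true(all(diff(sig$a) <= 0))
  ties <- split(sig$drug, sig$a)
  for (grp in ties) expect_equal(grp, sort(grp))
  expect_true(all(sig$a >= 3))
  # top-k larger than the list returns the whole list
  expect_equal(nrow(screen_signals(cs, top_k = 10000)), nrow(sig))
  # empty case set screens to an empty table
  empty <- build_case_set(flat_bundle(character(0), logical(0)))
  expect_equal(nrow(screen_signals(empty)), 0L)
})

test_that("planted high-ROR drug is flagged; null drugs mostly are not", {
  spec <- synthetic_spec(
    n_cases = 8000,
    drugs = data.frame(name = "signaldrug", p_assign = 0.05, p_event = 0.30,
                       alpha = 100, beta = 0.7, severity = 0.2),
    seed = 61)
  g <- generate_faers(spec)
  sig <- screen_signals(build_case_set(g$bundle))
  expect_true(sig[drug == "signaldrug", is_signal])
  null_rows <- sig[drug != "signaldrug"]
  expect_lt(mean(null_rows$is_signal), 0.1)
})

test_that("point estimates are recoverable from published Wald intervals", {
  expect_equal(recover_ror_from_ci(22.91, 25.37), 24.11, tolerance = 0.05 / 24.11)
  expect_equal(recover_ror_from_ci(83.38, 100.32), 91.46, tolerance = 0.05 / 91.46)
  expect_equal(recover_ror_from_ci(7, 7), 7)
  expect_error(recover_ror_from_ci(-1, 2), "positive")
  expect_error(recover_ror_from_ci(3, 2), "exceed")
})
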