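library(data.table)

# Minimal bundle constructor for hand-built test inputs; missing tables
# default to valid empty ones.
tiny_bundle <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL,
                        outc = NULL) {
  empty <- list(
    demo = data.table(primaryid = character(0), caseid = character(0),
                      fda_dt = character(0), event_dt = character(0),
                      age = character(0), age_cod = character(0),
                      sex = character(0), occp_cod = character(0),
                      reporter_country = character(0)),
    drug = data.table(primaryid = character(0), drug_seq = character(0),
                      role_cod = character(0), drugname = character(0)),
    reac = data.table(primaryid = character(0), pt = character(0)),
    ther = data.table(primaryid = character(0), dsg_drug_seq = character(0),
                      start_dt = character(0)),
    outc = data.table(primaryid = character(0), outc_cod = character(0)))
  fill <- function(tab, given) {
    if (is.null(given)) return(empty[[tab]])
    g <- as.data.table(given)
    for (col in setdiff(names(empty[[tab]]), names(g))) g[, (col) := ""]
    g[, names(empty[[tab]]), with = FALSE]
  }
  structure(list(demo = fill("demo", demo), drug = fill("drug", drug),
                 reac = fill("reac", reac), ther = fill("ther", ther),
                 outc = fill("outc", outc), quarter_label = "test",
                 parse_report = NULL),
            class = "quarter_bundle")
}

# One-PS-drug-per-case bundle from parallel vectors: the simplest shape for
# counting oracles.
flat_bundle <- function(drugs, events, caseid = NULL) {
  n <- length(drugs)
  pid <- as.character(5000 + seq_len(n))
  if (is.null(caseid)) caseid <- as.character(seq_len(n))
  tiny_bundle(
    demo = data.table(primaryid = pid, caseid = caseid,
                      fda_dt = "20200101"),
    drug = data.table(primaryid = pid, drug_seq = "1", role_cod = "PS",
                      drugname = drugs),
    reac = data.table(primaryid = pid,
                      pt = ifelse(events, "Hyponatraemia", "Nausea")))
}

# Independent naive contingency counter: explicit per-case loop, no joins.
naive_cells <- function(drugs, events, target) {
  a <- b <- c_ <- d <- 0L
  for (i in seq_along(drugs)) {
    if (drugs[i] == target) {
      if (events[i]) a <- a + 1L else b <- b + 1L
    } else {
      if (events[i]) c_ <- c_ + 1L else d <- d + 1L
    }
  }
  list(a = a, b = b, c = c_, d = d)
}

# 2-D grid-search Weibull oracle: iteratively zoomed grid over
# (alpha, beta), no profile shortcut.
grid_weibull_2d <- function(t, rounds = 5) {
  ll <- function(a, b) length(t) * log(b) - length(t) * b * log(a) +
    (b - 1) * sum(log(t)) - sum((t / a)^b)
  a_rng <- c(min(t) / 2, max(t) * 2)
  b_rng <- c(0.05, 20)
  best <- c(alpha = NA_real_, beta = NA_real_, loglik = -Inf)
  for (r in seq_len(rounds)) {
    as <- exp(seq(log(a_rng[1]), log(a_rng[2]), length.out = 61))
    bs <- exp(seq(log(b_rng[1]), log(b_rng[2]), length.out = 61))
    m <- outer(as, bs, Vectorize(ll))
    idx <- arrayInd(which.max(m), dim(m))
    best <- c(alpha = as[idx[1]], beta = bs[idx[2]], loglik = max(m))
    ia <- c(max(1, idx[1] - 1), min(61, idx[1] + 1))
    ib <- c(max(1, idx[2] - 1), min(61, idx[2] + 1))
    a_rng <- as[ia]; b_rng <- bs[ib]
  }
  best
}

# Profile-likelihood grid oracle over the shape only (scale profiled out
# in closed form).
grid_weibull <- function(t, beta_grid = seq(0.05, 20, by = 0.005)) {
  ll <- function(a, b) length(t) * log(b) - length(t) * b * log(a) +
    (b - 1) * sum(log(t)) - sum((t / a)^b)
  best <- c(alpha = NA_real_, beta = NA_real_, loglik = -Inf)
  for (b in beta_grid) {
    a <- mean(t^b)^(1 / b)  # profile scale is exact; grid only over shape
    v <- ll(a, b)
    if (v > best["loglik"]) best <- c(alpha = a, beta = b, loglik = v)
  }
  best
}
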