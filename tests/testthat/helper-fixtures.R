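# Fixtures built in code, and independent textbook oracles used to check the
# package's own computations.

# quick single-outcome trial
make_trial <- function(id, year, a, b, n, endpoint = "overall survival",
                       p = 0.01, measure = "HAZARD_RATIO", effect = 0.5,
                       favored = "A", update_years = integer(),
                       extra_outcomes = list()) {
  trial_comparison(
    trial_id = id, pub_year = year, regimen_a = a, regimen_b = b,
    n_total = n, update_years = update_years,
    outcomes = c(list(outcome_record(endpoint, p, measure, effect,
                                     is_primary = TRUE,
                                     favored_arm = favored)),
                 extra_outcomes))
}

# random small trial set over a handful of regimens (valid by construction)
random_trials <- function(n_trials, n_regimens = 5, years = 2000:2015) {
  regs <- paste0("X", seq_len(n_regimens))
  lapply(seq_len(n_trials), function(i) {
    ab <- sample(regs, 2)
    cls <- sample(c("overall survival", "progression-free survival",
                    "overall response rate"), 1)
    make_trial(sprintf("RT%03d", i), sample(years, 1), ab[1], ab[2],
               n = sample(50:800, 1), endpoint = cls,
               p = stats::runif(1, 1e-5, 0.2),
               effect = exp(stats::rnorm(1, 0, 0.5)),
               favored = sample(c("A", "B"), 1))
  })
}

# --- independent oracles -------------------------------------------------

# brute-force vertex valuation: flat list of (vertex, signed contribution)
# recomputed from first principles, never via evaluate_network
oracle_vertex_values <- function(trials, eval_year, half_life = 10,
                                 rv_tab = default_rv_table()) {
  pairs <- list()
  for (tr in trials) {
    if (tr$pub_year > eval_year) next
    tr <- resolve_endpoints(list(tr), rv_tab)[[1]]
    oc <- select_outcome(tr)
    if (oc$effect_measure == "NONINFERIORITY" || oc$favored_arm == "NONE") {
      pairs[[length(pairs) + 1]] <- list(v = tr$regimen_a, c = 0)
      pairs[[length(pairs) + 1]] <- list(v = tr$regimen_b, c = 0)
      next
    }
    ref <- max(c(tr$pub_year, tr$update_years[tr$update_years <= eval_year]))
    mag <- min(-log10(max(oc$p_value, 1e-3)), 3) * oc$rv *
      max(oc$effect_value, 1 / oc$effect_value) * log10(tr$n_total) *
      2^(-(eval_year - ref) / half_life)
    win <- if (oc$favored_arm == "A") tr$regimen_a else tr$regimen_b
    los <- if (oc$favored_arm == "A") tr$regimen_b else tr$regimen_a
    pairs[[length(pairs) + 1]] <- list(v = win, c = mag)
    pairs[[length(pairs) + 1]] <- list(v = los, c = -mag)
  }
  vs <- vapply(pairs, function(p) p$v, character(1))
  cs <- vapply(pairs, function(p) p$c, numeric(1))
  out <- vapply(split(cs, vs), sum, numeric(1))
  out[sort(names(out))]
}

# textbook Pearson r with Fisher-z CI and t-test P
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, ci_low = ci[1], ci_high = ci[2], p = p)
}
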