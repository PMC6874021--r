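test_that("CSV reader returns validated comparisons and resolves endpoints", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,pub_year,update_years,regimen_a,regimen_b,n_total,endpoint,p_value,effect_measure,effect_value,is_primary,favored_arm",
    "T1,2010,,A,B,100,overall survival,0.04,HAZARD_RATIO,0.6,TRUE,A"),
    path)
  trials <- read_trials(path)
  expect_length(trials, 1)
  tr <- trials[[1]]
  expect_s3_class(tr, "trial_comparison")
  expect_equal(tr$regimen_a, "A")
  expect_equal(tr$n_total, 100L)
  expect_length(tr$outcomes, 1)
  expect_equal(tr$outcomes[[1]]$endpoint_class, "STRONG")
  expect_equal(tr$outcomes[[1]]$rv, 1.0)
})

test_that("reader rejects invalid P values and unknown endpoints by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- "trial_id,pub_year,update_years,regimen_a,regimen_b,n_total,endpoint,p_value,effect_measure,effect_value,is_primary,favored_arm"
  writeLines(c(header,
               "T1,2010,,A,B,100,overall survival,-0.1,HAZARD_RATIO,0.6,TRUE,A"),
             path)
  expect_error(read_trials(path), "T1")
  writeLines(c(header,
               "T1,2010,,A,B,100,MMR,0.04,HAZARD_RATIO,0.6,TRUE,A"),
             path)
  expect_error(read_trials(path), "MMR")
  writeLines("trial_id,pub_year", path)
  expect_error(read_trials(path), "missing required column")
})

test_that("outcome and trial invariants are enforced at construction", {
  expect_error(outcome_record("os", 0, "HAZARD_RATIO", 0.5), "p_value")
  expect_error(outcome_record("os", 1.2, "HAZARD_RATIO", 0.5), "p_value")
  expect_error(outcome_record("os", 0.05, "HAZARD_RATIO", -1), "effect_value")
  # a draw with a non-unit effect is rejected, not silently zeroed
  expect_error(outcome_record("os", 0.5, "HAZARD_RATIO", 0.8,
                              favored_arm = "NONE"), "NONE")
  expect_silent(outcome_record("os", 0.5, "HAZARD_RATIO", 1,
                               favored_arm = "NONE"))
  expect_silent(outcome_record("os", 0.5, "NONINFERIORITY", 0.9,
                               favored_arm = "NONE"))
  expect_error(trial_comparison("T", 2000, "A", "A", 100,
                                list(outcome_record("os", .05,
                                                    "HAZARD_RATIO", 0.5,
                                                    favored_arm = "A"))),
               "must differ")
  expect_error(make_trial("T", 2000, "A", "B", 1), "n_total")
  expect_error(make_trial("T", 2000, "A", "B", 100,
                          update_years = 1999), "update_years")
  expect_error(trial_comparison("T", 2000, "A", "B", 100, list(
    outcome_record("os", .05, "HAZARD_RATIO", 0.5, is_primary = FALSE,
                   favored_arm = "A"))), "primary")
})

test_that("round-trip through CSV and JSON preserves records", {
  set.seed(11)
  trials <- random_trials(8)
  trials[[1]] <- make_trial("RT001", 2001, "X1", "X2", 120,
                            update_years = c(2005, 2009),
                            extra_outcomes = list(
                              outcome_record("overall survival", 0.08,
                                             "HAZARD_RATIO", 0.7,
                                             is_primary = FALSE,
                                             favored_arm = "A")))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_trials(trials, path)
    back <- read_trials(path)
    expect_equal(trials_to_df(back), trials_to_df(trials), tolerance = 1e-12)
    expect_equal(back[[1]]$update_years, c(2005L, 2009L))
  }
})

test_that("multi-arm expansion yields one comparison per pair with additive n", {
  oc <- function() list(outcome_record("overall survival", .01,
                                       "HAZARD_RATIO", 0.5,
                                       favored_arm = "A"))
  out <- expand_multiarm("T9", 2012, arms = c(A = 50, B = 50, C = 60),
                         pairs = list(c("A", "B"), c("A", "C")),
                         outcomes = list(oc(), oc()))
  expect_length(out, 2)
  expect_equal(vapply(out, function(t) t$n_total, integer(1)), c(100L, 110L))
  expect_error(expand_multiarm("T9", 2012, arms = c(A = 50, B = 50),
                               pairs = list(c("A", "D")),
                               outcomes = list(oc())),
               "unknown arm")
  # two arms, one pair: identical to direct construction
  single <- expand_multiarm("T9", 2012, arms = c(A = 50, B = 50),
                            pairs = list(c("A", "B")),
                            outcomes = list(oc()))[[1]]
  expect_equal(single$n_total, 100L)
  expect_equal(c(single$regimen_a, single$regimen_b), c("A", "B"))
  # all pairs of k arms give k(k-1)/2 comparisons
  k <- 4
  arms <- stats::setNames(rep(30, k), LETTERS[1:k])
  pairs <- utils::combn(LETTERS[1:k], 2, simplify = FALSE)
  all_out <- expand_multiarm("T10", 2012, arms, pairs,
                             outcomes = replicate(length(pairs), oc(),
                                                  simplify = FALSE))
  expect_length(all_out, k * (k - 1) / 2)
})

test_that("outcome selection follows the surrogacy and significance rules", {
  rv <- default_rv_table()
  # met weak primary is replaced by a marginal strong secondary
  tr <- trial_comparison("S1", 2010, "A", "B", 200, list(
    outcome_record("overall response rate", 0.01, "ODDS_RATIO", 2,
                   is_primary = TRUE, favored_arm = "A"),
    outcome_record("overall survival", 0.08, "HAZARD_RATIO", 0.7,
                   is_primary = FALSE, favored_arm = "A")))
  sel <- select_outcome(resolve_endpoints(list(tr), rv)[[1]])
  expect_equal(sel$endpoint, "overall survival")
  # unmet primary is kept even when a secondary is significant
  tr <- trial_comparison("S2", 2010, "A", "B", 200, list(
    outcome_record("progression-free survival", 0.20, "HAZARD_RATIO", 0.9,
                   is_primary = TRUE, favored_arm = "A"),
    outcome_record("overall response rate", 0.01, "ODDS_RATIO", 2,
                   is_primary = FALSE, favored_arm = "A")))
  sel <- select_outcome(resolve_endpoints(list(tr), rv)[[1]])
  expect_equal(sel$endpoint, "progression-free survival")
  # among several primaries the least surrogate wins
  tr <- trial_comparison("S3", 2010, "A", "B", 200, list(
    outcome_record("overall response rate", 0.01, "ODDS_RATIO", 2,
                   is_primary = TRUE, favored_arm = "A"),
    outcome_record("overall survival", 0.03, "HAZARD_RATIO", 0.7,
                   is_primary = TRUE, favored_arm = "A")))
  sel <- select_outcome(resolve_endpoints(list(tr), rv)[[1]])
  expect_equal(sel$endpoint, "overall survival")
  # a secondary that is NOT strictly less surrogate never substitutes
  tr <- trial_comparison("S4", 2010, "A", "B", 200, list(
    outcome_record("progression-free survival", 0.01, "HAZARD_RATIO", 0.6,
                   is_primary = TRUE, favored_arm = "A"),
    outcome_record("event-free survival", 0.005, "HAZARD_RATIO", 0.5,
                   is_primary = FALSE, favored_arm = "A")))
  sel <- select_outcome(resolve_endpoints(list(tr), rv)[[1]])
  expect_equal(sel$endpoint, "progression-free survival")
})

test_that("outcome selection is deterministic and returns a trial member", {
  set.seed(42)
  for (i in 1:25) {
    tr <- random_trials(1)[[1]]
    tr <- resolve_endpoints(list(tr))[[1]]
    s1 <- select_outcome(tr)
    s2 <- select_outcome(tr)
    expect_identical(s1, s2)
    expect_true(any(vapply(tr$outcomes, identical, logical(1), s1)))
  }
})

test_that("rv tables validate, look up, and rescale with the cap", {
  expect_error(rv_table(c("a", "a"), "STRONG"), "exactly one")
  expect_error(rv_table("a", "BOGUS"), "unknown endpoint class")
  tab <- default_rv_table()
  expect_equal(rv_lookup(tab, "Overall Survival")$rv, 1.0)
  expect_error(rv_lookup(tab, "nonesuch"), "nonesuch")
  up <- scale_rv(tab, 0.20)
  expect_equal(max(up$rv), 1.0)  # strong class capped at its defining max
  expect_equal(up$rv[up$class == "WEAK"][1], 0.7 * 1.2)
  dn <- scale_rv(tab, -0.10)
  expect_equal(dn$rv[dn$class == "STRONG"][1], 0.9)
  expect_error(scale_rv(tab, -1), "greater than -100%")
})
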