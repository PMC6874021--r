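# Synthetic RCT comparison streams with controllable comparator-selection
# (straw-man) structure, so the whole pipeline -- including the bias
# diagnostic and its amelioration -- is testable with no external data.

#' Scenario configuration for the synthetic trial generator
#'
#' The generated stream emulates a multi-decade treatment landscape: new
#' regimens debut over time, trials preferentially pick the currently
#' most-studied regimen as comparator (the straw-man mechanism), the newer
#' arm usually wins, and endpoint surrogacy degrades over calendar time.
#'
#' @param n_regimens number of distinct regimens introduced over the span.
#' @param start_year,end_year calendar span (inclusive).
#' @param trials_per_year trials generated per calendar year.
#' @param strawman_intensity probability that a trial uses the currently
#'   most-studied regimen as comparator (otherwise uniform choice).
#' @param newcomer_win_prob probability that the more recently introduced arm
#'   is favored.
#' @param endpoint_drift per-decade probability mass shifted from strong
#'   toward surrogate endpoints.
#' @param adoption_prob probability that a regimen which significantly beats
#'   the current standard of care is adopted as the new standard (guideline
#'   stickiness: standards persist for about a decade at the default even
#'   while repeatedly beaten, which is the essence of the straw-man
#'   mechanism).
#' @param effect_meanlog,effect_sdlog log-scale location and spread of the
#'   generated effect-ratio magnitudes.
#' @param n_meanlog,n_sdlog log-scale location and spread of per-trial
#'   patient totals at `start_year` (floored at 20).
#' @param n_growth_per_decade multiplicative growth of the patient-total
#'   location per decade of calendar time, emulating the secular growth of
#'   trial sizes.
#' @param seed integer seed; generation is strictly reproducible given it.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_regimens = 20,
                            start_year = 1990, end_year = 2020,
                            trials_per_year = 2,
                            strawman_intensity = 0.8,
                            newcomer_win_prob = 0.8,
                            endpoint_drift = 0.4,
                            adoption_prob = 0.1,
                            effect_meanlog = log(1.5), effect_sdlog = 0.25,
                            n_meanlog = log(150), n_sdlog = 0.4,
                            n_growth_per_decade = 2,
                            seed = 1L) {
  probs <- c(strawman_intensity, newcomer_win_prob, endpoint_drift,
             adoption_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("strawman_intensity, newcomer_win_prob and endpoint_drift must lie ",
         "in [0, 1]")
  }
  stopifnot(n_regimens >= 2, end_year > start_year, trials_per_year >= 1,
            n_growth_per_decade > 0, is.finite(seed))
  structure(list(n_regimens = as.integer(n_regimens),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 trials_per_year = as.integer(trials_per_year),
                 strawman_intensity = strawman_intensity,
                 newcomer_win_prob = newcomer_win_prob,
                 endpoint_drift = endpoint_drift,
                 adoption_prob = adoption_prob,
                 effect_meanlog = effect_meanlog,
                 effect_sdlog = effect_sdlog,
                 n_meanlog = n_meanlog, n_sdlog = n_sdlog,
                 n_growth_per_decade = n_growth_per_decade,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Endpoint class by calendar drift: the probability mass on the strong
# endpoint decays linearly with decades elapsed, the remainder split evenly
# between intermediate and weak surrogates.
.draw_endpoint_class <- function(year, start_year, drift) {
  level <- min(1, drift * (year - start_year) / 10)
  p_strong <- 1 - level
  sample(c("STRONG", "INTERMEDIATE", "WEAK"), 1,
         prob = c(p_strong, level / 2, level / 2))
}

.endpoint_for_class <- c(STRONG = "overall survival",
                         INTERMEDIATE = "progression-free survival",
                         WEAK = "overall response rate")

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.generate_stream <- function(config, strawman_intensity, win_prob) {
  .with_seed(config$seed, {
    span <- config$start_year:config$end_year
    n_trials <- config$trials_per_year * length(span)
    regimens <- sprintf("R%02d", seq_len(config$n_regimens))
    debut_year <- c(config$start_year, config$start_year,
                    if (config$n_regimens > 2)
                      round(seq(config$start_year + 1, config$end_year,
                                length.out = config$n_regimens - 2)))
    names(debut_year) <- regimens
    introduced <- regimens[1:2]
    pending <- regimens[-(1:2)]
    standard <- regimens[1]  # current standard of care

    trials <- vector("list", n_trials)
    k <- 0L
    for (yr in span) {
      for (j in seq_len(config$trials_per_year)) {
        k <- k + 1L
        # experimental arm: a debutant scheduled by this year if one is
        # waiting, else a regimen introduced within the preceding decade
        # (experimental arms are recent entrants, not revivals)
        if (length(pending) && debut_year[pending[1]] <= yr) {
          exper <- pending[1]
          pending <- pending[-1]
          introduced <- c(introduced, exper)
        } else {
          recent <- introduced[debut_year[introduced] >= yr - 10]
          if (length(recent) == 0) recent <- introduced
          exper <- if (length(recent) == 1) recent else sample(recent, 1)
        }
        others <- setdiff(introduced, exper)
        if (stats::runif(1) < strawman_intensity && standard != exper) {
          # straw-man mechanism: trial against the current standard of care
          comp <- standard
        } else {
          comp <- if (length(others) == 1) others else sample(others, 1)
        }

        meanlog_t <- config$n_meanlog + log(config$n_growth_per_decade) *
          (yr - config$start_year) / 10
        n_total <- max(20, round(stats::rlnorm(1, meanlog_t,
                                               config$n_sdlog)))
        newer <- if (debut_year[exper] >= debut_year[comp]) exper else comp
        older <- if (newer == exper) comp else exper
        winner <- if (stats::runif(1) < win_prob) newer else older

        cls <- .draw_endpoint_class(yr, config$start_year,
                                    config$endpoint_drift)
        se <- 2 / sqrt(n_total)
        lam <- abs(stats::rnorm(1, config$effect_meanlog,
                                config$effect_sdlog))
        lam_obs <- abs(lam + stats::rnorm(1, 0, se))
        p <- min(max(2 * stats::pnorm(-lam_obs / se), 1e-12), 0.999)
        measure <- if (cls == "WEAK") "ODDS_RATIO" else "HAZARD_RATIO"
        effect <- if (measure == "HAZARD_RATIO") exp(-lam_obs) else
          exp(lam_obs)

        primary <- outcome_record(endpoint =
                                    unname(.endpoint_for_class[cls]),
                                  p_value = p, effect_measure = measure,
                                  effect_value = effect, is_primary = TRUE,
                                  favored_arm = if (winner == exper) "A"
                                  else "B")
        outcomes <- list(primary)
        # occasionally a surrogate-primary trial also reports an overall
        # survival secondary, exercising the endpoint selection rule
        if (cls != "STRONG" && stats::runif(1) < 0.2) {
          lam2 <- abs(lam_obs / 2 + stats::rnorm(1, 0, se))
          p2 <- min(max(2 * stats::pnorm(-lam2 / se), 1e-12), 0.999)
          outcomes <- c(outcomes, list(
            outcome_record(endpoint = "overall survival", p_value = p2,
                           effect_measure = "HAZARD_RATIO",
                           effect_value = exp(-lam2), is_primary = FALSE,
                           favored_arm = if (winner == exper) "A" else "B")))
        }

        trials[[k]] <- trial_comparison(
          trial_id = sprintf("T%04d", k), pub_year = yr,
          regimen_a = exper, regimen_b = comp, n_total = n_total,
          outcomes = outcomes)
        # standard-of-care succession: a regimen that significantly beats
        # the current standard is occasionally adopted as the new standard;
        # guideline stickiness keeps reigns at about a decade
        if (standard %in% c(exper, comp) && winner != standard &&
            p <= 0.05 && stats::runif(1) < config$adoption_prob) {
          standard <- winner
        }
      }
    }
    trials
  })
}

#' Generate a trial stream with straw-man structure
#'
#' @param config a [scenario_config()].
#' @return list of `trial_comparison`s,
#'   `trials_per_year * (end_year - start_year + 1)` long.
#' @export
generate_strawman <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  .generate_stream(config, config$strawman_intensity,
                   config$newcomer_win_prob)
}

#' Generate a bias-free (null) trial stream
#'
#' The negative control for the value-versus-size diagnostic: identical
#' machinery with both ingredients of the straw-man bias neutralized — the
#' comparator is drawn uniformly from the existing regimens (straw-man
#' intensity forced to zero) and neither arm enjoys a systematic win
#' advantage (the newer arm wins with probability one half). Without the
#' second neutralization older regimens would still be both the largest and
#' the systematically beaten vertices, and the diagnostic would stay
#' negative under any comparator scheme.
#'
#' @param config a [scenario_config()].
#' @return list of `trial_comparison`s.
#' @export
generate_null <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  .generate_stream(config, 0, 0.5)
}
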