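# Vertex valuation: for each regimen vertex, the sum over incident trial
# edges of
#   min(-log10 P, 3) x RV x (+/-)E x log10(N) x 2^(-age / half_life)
# with the positive share going to the favored arm and the negative share to
# the other. Values are signed, unitless, and deliberately unnormalized: the
# magnitude carries the weight of evidence.

#' Algorithm configuration
#'
#' Collects every tunable of the valuation and propagation pipeline.
#'
#' @param half_life_years half-life of the exponential aging decay, in years.
#' @param p_truncation P values below this are truncated before taking the
#'   negative log10 (default .001).
#' @param sig_weight_cap maximum significance weight (default 3; with the
#'   default truncation the two are equivalent).
#' @param propagation_fraction fraction of a node's newly incurred value
#'   change passed to its single-generation neighbours, in [0, 1].
#' @param refresh_enabled if TRUE, each edge through which value is passed has
#'   its effective age reduced by one half-life.
#' @param split_rule how a transfer is divided among several targets:
#'   `"EQUAL"` shares, or `"PROPORTIONAL"` to the magnitude of the qualifying
#'   prior edge's contribution.
#' @param epsilon half-width of the near-zero "insufficient evidence" band
#'   used when interpreting ranked values.
#' @param p_met,p_marginal thresholds of the endpoint selection rule, see
#'   [select_outcome()].
#' @param rv_table the [rv_table()] used to resolve endpoints.
#' @return an object of class `valuation_config`.
#' @export
valuation_config <- function(half_life_years = 10,
                             p_truncation = 0.001,
                             sig_weight_cap = 3,
                             propagation_fraction = 0.5,
                             refresh_enabled = TRUE,
                             split_rule = c("EQUAL", "PROPORTIONAL"),
                             epsilon = 0.5,
                             p_met = 0.05,
                             p_marginal = 0.10,
                             rv_table = default_rv_table()) {
  split_rule <- match.arg(split_rule)
  stopifnot(half_life_years > 0, p_truncation > 0, p_truncation < 1,
            sig_weight_cap > 0, epsilon >= 0,
            inherits(rv_table, "rv_table"))
  if (!is.finite(propagation_fraction) || propagation_fraction < 0 ||
      propagation_fraction > 1) {
    stop("propagation_fraction must lie in [0, 1]")
  }
  structure(list(half_life_years = half_life_years,
                 p_truncation = p_truncation,
                 sig_weight_cap = sig_weight_cap,
                 propagation_fraction = propagation_fraction,
                 refresh_enabled = isTRUE(refresh_enabled),
                 split_rule = split_rule,
                 epsilon = epsilon,
                 p_met = p_met,
                 p_marginal = p_marginal,
                 rv_table = rv_table),
            class = "valuation_config")
}

#' Read a configuration from a YAML file
#'
#' Recognized keys: `half_life_years`, `p_truncation`, `sig_weight_cap`,
#' `propagation_fraction`, `refresh_enabled`, `split_rule`, `epsilon`,
#' `p_met`, `p_marginal`, and `rv_overrides` (a mapping endpoint name ->
#' class, merged over the default RV table).
#'
#' @param path YAML file path.
#' @return a [valuation_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  tab <- default_rv_table()
  if (!is.null(y$rv_overrides)) {
    ov <- rv_table(names(y$rv_overrides), unlist(y$rv_overrides))
    keep <- !(tolower(tab$endpoint) %in% tolower(ov$endpoint))
    tab <- structure(rbind(tab[keep, ], ov),
                     class = c("rv_table", "data.frame"))
  }
  y$rv_overrides <- NULL
  do.call(valuation_config, c(y, list(rv_table = tab)))
}

#' Significance weight of a P value
#'
#' The negative log10 of the P value, truncated so that very small P values
#' do not dominate: P below `p_truncation` counts as `p_truncation`, and the
#' weight never exceeds `cap` (defaults make any P < .001 score exactly 3).
#'
#' @param p numeric vector of P values in (0, 1].
#' @param cap maximum weight.
#' @param p_truncation truncation floor for P.
#' @return weights in [0, cap].
#' @export
significance_weight <- function(p, cap = 3, p_truncation = 10^(-cap)) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]")
  }
  pmin(-log10(pmax(p, p_truncation)), cap)
}

#' Signed effect-size coefficient
#'
#' A reported ratio-scale effect is folded to its side >= 1: a hazard ratio
#' of 0.5 and one of 2 both yield a coefficient of 2. The caller assigns +E
#' to the favored (winning) arm and -E to the other.
#'
#' @param effect_value positive ratio-scale effect size(s).
#' @return coefficient(s) >= 1.
#' @export
effect_coefficient <- function(effect_value) {
  if (any(!is.finite(effect_value)) || any(effect_value <= 0)) {
    stop("effect_value must be positive")
  }
  pmax(effect_value, 1 / effect_value)
}

#' Exponential aging coefficient
#'
#' Evidence decays with a configurable half-life: `2^(-(eval_year -
#' reference_year)/half_life)`. The reference year is the most recent of the
#' publication year and any interim update year not after the evaluation
#' year.
#'
#' @param reference_year publication (or latest update) year.
#' @param eval_year evaluation year, >= `reference_year`.
#' @param half_life half-life in years, > 0.
#' @return coefficient(s) in (0, 1].
#' @export
aging_coefficient <- function(reference_year, eval_year, half_life = 10) {
  stopifnot(half_life > 0)
  age <- eval_year - reference_year
  if (any(age < 0)) stop("eval_year must not precede reference_year")
  2^(-age / half_life)
}

.reference_year <- function(trial, eval_year) {
  yrs <- c(trial$pub_year, trial$update_years[trial$update_years <= eval_year])
  max(yrs)
}

#' Value one trial edge at an evaluation year
#'
#' Selects the outcome per [select_outcome()], computes the five factors of
#' the valuation product, and identifies winner and loser from the favored
#' arm. A noninferiority outcome, or a draw (no favored arm), contributes
#' zero.
#'
#' @param trial a `trial_comparison` with resolved endpoints (or resolvable
#'   via `config$rv_table`).
#' @param eval_year evaluation year, >= the trial's publication year.
#' @param config a [valuation_config()].
#' @return one-row data.frame with columns `trial_id`, `year`, `regimen_a`,
#'   `regimen_b`, `winner`, `loser` (NA for a draw), `endpoint`,
#'   `endpoint_class`, `sig_weight`, `rv`, `e_magnitude`, `log_n`,
#'   `effective_age`, `aging`, and `contribution` (the non-negative magnitude;
#'   the winner receives `+contribution`, the loser `-contribution`).
#' @export
edge_contribution <- function(trial, eval_year, config = valuation_config()) {
  if (trial$pub_year > eval_year) {
    stop("trial ", trial$trial_id, " published after eval_year")
  }
  if (trial$n_total < 2) stop("trial ", trial$trial_id, ": n_total < 2")
  oc <- select_outcome(resolve_endpoints(list(trial), config$rv_table)[[1]],
                       p_met = config$p_met, p_marginal = config$p_marginal)
  ref <- .reference_year(trial, eval_year)
  age <- eval_year - ref
  aging <- aging_coefficient(ref, eval_year, config$half_life_years)
  sw <- significance_weight(oc$p_value, cap = config$sig_weight_cap,
                            p_truncation = config$p_truncation)
  em <- effect_coefficient(oc$effect_value)
  ln <- log10(trial$n_total)

  draw <- oc$effect_measure == "NONINFERIORITY" || oc$favored_arm == "NONE"
  winner <- loser <- NA_character_
  contribution <- 0
  if (!draw) {
    winner <- if (oc$favored_arm == "A") trial$regimen_a else trial$regimen_b
    loser <- if (oc$favored_arm == "A") trial$regimen_b else trial$regimen_a
    contribution <- sw * oc$rv * em * ln * aging
  }
  data.frame(trial_id = trial$trial_id, year = trial$pub_year,
             regimen_a = trial$regimen_a, regimen_b = trial$regimen_b,
             winner = winner, loser = loser,
             endpoint = oc$endpoint, endpoint_class = oc$endpoint_class,
             sig_weight = sw, rv = oc$rv, e_magnitude = em, log_n = ln,
             effective_age = age, aging = aging,
             contribution = contribution, stringsAsFactors = FALSE)
}

# Signed vertex sums of the edge decomposition plus vertex-level adjustments.
.vertex_values <- function(edges, regimens, adjustments = NULL) {
  v <- stats::setNames(numeric(length(regimens)), regimens)
  live <- !is.na(edges$winner)
  if (any(live)) {
    w <- tapply(edges$contribution[live], edges$winner[live], sum)
    l <- tapply(edges$contribution[live], edges$loser[live], sum)
    v[names(w)] <- v[names(w)] + w
    v[names(l)] <- v[names(l)] - l
  }
  if (!is.null(adjustments)) v[names(adjustments)] <- v[names(adjustments)] +
      adjustments
  v
}

.vertex_sizes <- function(trials, regimens) {
  s <- stats::setNames(numeric(length(regimens)), regimens)
  for (tr in trials) {
    s[tr$regimen_a] <- s[tr$regimen_a] + tr$n_total
    s[tr$regimen_b] <- s[tr$regimen_b] + tr$n_total
  }
  s
}

.new_network_state <- function(eval_year, trials, edges, adjustments = NULL,
                               trace = NULL) {
  regimens <- sort(unique(c(edges$regimen_a, edges$regimen_b)))
  if (is.null(adjustments)) {
    adjustments <- stats::setNames(numeric(length(regimens)), regimens)
  }
  values <- .vertex_values(edges, regimens, adjustments)
  sizes <- .vertex_sizes(trials, regimens)
  structure(list(eval_year = eval_year,
                 vertices = data.frame(regimen = regimens,
                                       value = unname(values[regimens]),
                                       size = unname(sizes[regimens]),
                                       stringsAsFactors = FALSE),
                 edges = edges,
                 adjustments = adjustments,
                 trace = trace),
            class = "regimen_network")
}

#' Value a trial network at an evaluation year (no propagation)
#'
#' Includes every trial published by `eval_year`; each vertex's value is the
#' sum of its incident signed edge contributions and its size is the total
#' number of patients studied in its comparisons.
#'
#' @param trials list of `trial_comparison`s.
#' @param eval_year evaluation year.
#' @param config a [valuation_config()].
#' @return an object of class `regimen_network` with elements `eval_year`,
#'   `vertices` (regimen, value, size), `edges` (one row per comparison, see
#'   [edge_contribution()]), `adjustments` (vertex-level propagation deltas,
#'   all zero here), and `trace`.
#' @export
evaluate_network <- function(trials, eval_year,
                             config = valuation_config()) {
  eligible <- Filter(function(tr) tr$pub_year <= eval_year, trials)
  if (length(eligible) == 0) {
    stop("no trials published by ", eval_year)
  }
  edges <- do.call(rbind, lapply(eligible, edge_contribution,
                                 eval_year = eval_year, config = config))
  .new_network_state(eval_year, eligible, edges)
}

#' Vertex and connection counts of a network
#'
#' @param state a `regimen_network`.
#' @return list with `n_regimens` and `n_connections`.
#' @export
network_summary <- function(state) {
  stopifnot(inherits(state, "regimen_network"))
  list(n_regimens = nrow(state$vertices), n_connections = nrow(state$edges))
}

#' @export
print.regimen_network <- function(x, ...) {
  cat(sprintf("Regimen evidence network at %d: %d regimens, %d comparisons\n",
              x$eval_year, nrow(x$vertices), nrow(x$edges)))
  ord <- order(-x$vertices$value, x$vertices$regimen)
  print(x$vertices[ord, ], row.names = FALSE)
  invisible(x)
}
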