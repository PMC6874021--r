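# Domain types for pairwise RCT comparisons and their readers/validators.

.effect_measures <- c("HAZARD_RATIO", "ODDS_RATIO", "MEDIAN_RATIO",
                      "POINT_ESTIMATE_RATIO", "NONINFERIORITY")
.favored_arms <- c("A", "B", "NONE")

#' Construct one outcome of a pairwise comparison
#'
#' An outcome couples an endpoint (resolved to a surrogacy class and relative
#' value through an [rv_table()]) with the reported P value, the effect
#' measure and its value on the ratio scale, a primary/secondary flag, and the
#' favored arm.
#'
#' `favored_arm = "NONE"` (a draw) is only accepted for a truly neutral result
#' (`effect_value = 1`) or for a noninferiority outcome; a non-unit effect
#' with no favored arm is rejected at construction rather than silently
#' zeroed.
#'
#' @param endpoint endpoint name (e.g. "overall survival").
#' @param p_value reported P value, in (0, 1].
#' @param effect_measure one of `HAZARD_RATIO`, `ODDS_RATIO`, `MEDIAN_RATIO`,
#'   `POINT_ESTIMATE_RATIO`, `NONINFERIORITY`.
#' @param effect_value positive effect size on the ratio scale.
#' @param is_primary logical; was this a trial-defined primary endpoint?
#' @param favored_arm `"A"`, `"B"`, or `"NONE"`.
#' @param endpoint_class,rv optional pre-resolved surrogacy class and weight;
#'   normally filled in from an RV table by [read_trials()] or
#'   [resolve_endpoints()].
#' @return an object of class `outcome_record`.
#' @export
outcome_record <- function(endpoint, p_value, effect_measure, effect_value,
                           is_primary = TRUE, favored_arm = "NONE",
                           endpoint_class = NULL, rv = NULL) {
  p_value <- as.numeric(p_value)
  effect_value <- as.numeric(effect_value)
  if (!is.finite(p_value) || p_value <= 0 || p_value > 1) {
    stop("p_value must lie in (0, 1], got ", format(p_value))
  }
  if (!is.finite(effect_value) || effect_value <= 0) {
    stop("effect_value must be positive, got ", format(effect_value))
  }
  effect_measure <- match.arg(effect_measure, .effect_measures)
  favored_arm <- match.arg(favored_arm, .favored_arms)
  if (favored_arm == "NONE" && effect_value != 1 &&
      effect_measure != "NONINFERIORITY") {
    stop("favored_arm = NONE requires effect_value = 1 or a noninferiority ",
         "outcome (endpoint '", endpoint, "')")
  }
  if (!is.null(endpoint_class)) surrogacy_rank(endpoint_class)
  structure(list(endpoint = as.character(endpoint),
                 endpoint_class = endpoint_class,
                 rv = rv,
                 p_value = p_value,
                 effect_measure = effect_measure,
                 effect_value = effect_value,
                 is_primary = isTRUE(is_primary),
                 favored_arm = favored_arm),
            class = "outcome_record")
}

#' Construct a dated two-regimen comparison
#'
#' @param trial_id trial identifier.
#' @param pub_year calendar year of publication.
#' @param regimen_a,regimen_b the two distinct regimen identifiers.
#' @param n_total total patients in the pairwise comparison (>= 2).
#' @param outcomes non-empty list of [outcome_record()]s, at least one of
#'   which is primary.
#' @param update_years calendar years of interim updates (each >= `pub_year`);
#'   used only to refresh the aging reference year.
#' @return an object of class `trial_comparison`.
#' @export
trial_comparison <- function(trial_id, pub_year, regimen_a, regimen_b,
                             n_total, outcomes, update_years = integer()) {
  trial_id <- as.character(trial_id)
  pub_year <- as.integer(pub_year)
  n_total <- as.integer(n_total)
  update_years <- as.integer(update_years)
  if (identical(as.character(regimen_a), as.character(regimen_b))) {
    stop("trial ", trial_id, ": regimen_a and regimen_b must differ")
  }
  if (is.na(n_total) || n_total < 2) {
    stop("trial ", trial_id, ": n_total must be a patient count >= 2")
  }
  if (inherits(outcomes, "outcome_record")) outcomes <- list(outcomes)
  if (length(outcomes) == 0 ||
      !all(vapply(outcomes, inherits, logical(1), "outcome_record"))) {
    stop("trial ", trial_id, ": outcomes must be a non-empty list of ",
         "outcome_record objects")
  }
  if (!any(vapply(outcomes, function(o) o$is_primary, logical(1)))) {
    stop("trial ", trial_id, ": at least one outcome must be primary")
  }
  if (length(update_years) && any(update_years < pub_year)) {
    stop("trial ", trial_id, ": update_years must all be >= pub_year")
  }
  structure(list(trial_id = trial_id,
                 pub_year = pub_year,
                 update_years = sort(update_years),
                 regimen_a = as.character(regimen_a),
                 regimen_b = as.character(regimen_b),
                 n_total = n_total,
                 outcomes = outcomes),
            class = "trial_comparison")
}

#' Resolve endpoint classes and weights against an RV table
#'
#' @param trials list of `trial_comparison`s.
#' @param rv_table an [rv_table()].
#' @return the trials with every outcome's `endpoint_class` and `rv` filled.
#' @export
resolve_endpoints <- function(trials, rv_table = default_rv_table()) {
  lapply(trials, function(tr) {
    tr$outcomes <- lapply(tr$outcomes, function(o) {
      hit <- rv_lookup(rv_table, o$endpoint)
      o$endpoint_class <- hit$class
      o$rv <- hit$rv
      o
    })
    tr
  })
}

.trial_columns <- c("trial_id", "pub_year", "update_years", "regimen_a",
                    "regimen_b", "n_total", "endpoint", "p_value",
                    "effect_measure", "effect_value", "is_primary",
                    "favored_arm")

#' Read pairwise trial comparisons from CSV or JSON
#'
#' The CSV dialect is UTF-8 with a header row and one outcome per row, trial
#' fields repeated across the rows of a multi-outcome trial; `update_years`
#' is a semicolon-separated list (may be empty). The JSON form is an array of
#' trial objects each holding a nested `outcomes` array. Endpoint classes are
#' resolved through `rv_table`; an endpoint absent from the table is an
#' error naming the endpoint.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @param rv_table the [rv_table()] used to resolve endpoints.
#' @return list of validated `trial_comparison` objects.
#' @export
read_trials <- function(path, format = c("auto", "csv", "json"),
                        rv_table = default_rv_table()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  trials <- if (format == "csv") .read_trials_csv(path) else
    .read_trials_json(path)
  resolve_endpoints(trials, rv_table)
}

.parse_update_years <- function(x) {
  if (is.null(x) || length(x) == 0) return(integer())
  x <- as.character(x)[1]
  if (is.na(x) || !nzchar(trimws(x))) return(integer())
  as.integer(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
}

.read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(.trial_columns, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no trial rows in ", path)
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    rows <- df[df$trial_id == id, , drop = FALSE]
    outcomes <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      tryCatch(
        outcome_record(endpoint = r$endpoint,
                       p_value = as.numeric(r$p_value),
                       effect_measure = r$effect_measure,
                       effect_value = as.numeric(r$effect_value),
                       is_primary = tolower(r$is_primary) %in%
                         c("true", "t", "1", "yes"),
                       favored_arm = toupper(r$favored_arm)),
        error = function(e) stop("trial ", id, ": ", conditionMessage(e),
                                 call. = FALSE))
    })
    trial_comparison(trial_id = id,
                     pub_year = as.integer(rows$pub_year[1]),
                     update_years = .parse_update_years(rows$update_years[1]),
                     regimen_a = rows$regimen_a[1],
                     regimen_b = rows$regimen_b[1],
                     n_total = as.integer(rows$n_total[1]),
                     outcomes = outcomes)
  })
}

.read_trials_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(tr) {
    need <- c("trial_id", "pub_year", "regimen_a", "regimen_b", "n_total",
              "outcomes")
    missing <- setdiff(need, names(tr))
    if (length(missing)) {
      stop("missing required field(s): ", paste(missing, collapse = ", "))
    }
    outcomes <- lapply(tr$outcomes, function(o) {
      tryCatch(
        outcome_record(endpoint = o$endpoint,
                       p_value = o$p_value,
                       effect_measure = o$effect_measure,
                       effect_value = o$effect_value,
                       is_primary = isTRUE(o$is_primary),
                       favored_arm = toupper(o$favored_arm)),
        error = function(e) stop("trial ", tr$trial_id, ": ",
                                 conditionMessage(e), call. = FALSE))
    })
    trial_comparison(trial_id = tr$trial_id, pub_year = tr$pub_year,
                     update_years = unlist(tr$update_years),
                     regimen_a = tr$regimen_a, regimen_b = tr$regimen_b,
                     n_total = tr$n_total, outcomes = outcomes)
  })
}

#' Flatten trials to the one-outcome-per-row tabular form
#'
#' @param trials list of `trial_comparison`s.
#' @return a data.frame in the documented CSV column order.
#' @export
trials_to_df <- function(trials) {
  rows <- lapply(trials, function(tr) {
    do.call(rbind, lapply(tr$outcomes, function(o) {
      data.frame(trial_id = tr$trial_id, pub_year = tr$pub_year,
                 update_years = paste(tr$update_years, collapse = ";"),
                 regimen_a = tr$regimen_a, regimen_b = tr$regimen_b,
                 n_total = tr$n_total, endpoint = o$endpoint,
                 p_value = o$p_value, effect_measure = o$effect_measure,
                 effect_value = o$effect_value, is_primary = o$is_primary,
                 favored_arm = o$favored_arm, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Write trials to CSV or JSON
#'
#' Inverse of [read_trials()]: re-reading the written file yields identical
#' records.
#'
#' @param trials list of `trial_comparison`s.
#' @param path output path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @export
write_trials <- function(trials, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(trials_to_df(trials), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    objs <- lapply(trials, function(tr) {
      list(trial_id = tr$trial_id, pub_year = tr$pub_year,
           update_years = as.list(tr$update_years),
           regimen_a = tr$regimen_a, regimen_b = tr$regimen_b,
           n_total = tr$n_total,
           outcomes = lapply(tr$outcomes, function(o) {
             list(endpoint = o$endpoint, p_value = o$p_value,
                  effect_measure = o$effect_measure,
                  effect_value = o$effect_value,
                  is_primary = o$is_primary, favored_arm = o$favored_arm)
           }))
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Expand a multi-arm trial into pairwise comparisons
#'
#' The valuation operates on pairwise comparisons only, so a k-arm trial is
#' entered as its reported pairwise contrasts. Each reported pair becomes one
#' `trial_comparison` whose `n_total` is the sum of its two arms' patient
#' counts.
#'
#' @param trial_id,pub_year,update_years shared trial metadata.
#' @param arms named integer vector of per-arm patient counts, >= 2 arms.
#' @param pairs list of length-2 character vectors naming the compared arms.
#' @param outcomes list parallel to `pairs`; each element a list of
#'   [outcome_record()]s for that pair (favored_arm "A" refers to the first
#'   member of the pair).
#' @return list of `trial_comparison` objects, one per reported pair.
#' @export
expand_multiarm <- function(trial_id, pub_year, arms, pairs, outcomes,
                            update_years = integer()) {
  stopifnot(length(arms) >= 2, !is.null(names(arms)),
            length(pairs) == length(outcomes))
  lapply(seq_along(pairs), function(i) {
    pr <- as.character(pairs[[i]])
    if (length(pr) != 2) stop("each pair must name exactly two arms")
    unknown <- setdiff(pr, names(arms))
    if (length(unknown)) {
      stop("pair references unknown arm(s): ", paste(unknown, collapse = ", "))
    }
    trial_comparison(trial_id = sprintf("%s/%s-vs-%s", trial_id, pr[1], pr[2]),
                     pub_year = pub_year, update_years = update_years,
                     regimen_a = pr[1], regimen_b = pr[2],
                     n_total = sum(arms[pr]),
                     outcomes = outcomes[[i]])
  })
}

#' Select the outcome a comparison is valued on
#'
#' One outcome per comparison enters the valuation, chosen by surrogacy:
#' among the primary endpoints the least-surrogate one is taken (ties broken
#' by lowest P value, then input order). If that primary is met (P <=
#' `p_met`) and a strictly less-surrogate secondary endpoint reaches at least
#' marginal significance (P <= `p_marginal`), the secondary replaces it. If
#' the primary is not met, the primary is used regardless of the secondaries.
#'
#' @param trial a `trial_comparison` with resolved endpoint classes.
#' @param p_met significance threshold defining a met primary (default .05).
#' @param p_marginal marginal-significance threshold admitting a
#'   less-surrogate secondary (default .10).
#' @return the selected `outcome_record` (always a member of
#'   `trial$outcomes`).
#' @export
select_outcome <- function(trial, p_met = 0.05, p_marginal = 0.10) {
  oc <- trial$outcomes
  cls <- vapply(oc, function(o) {
    if (is.null(o$endpoint_class)) {
      stop("trial ", trial$trial_id,
           ": endpoint classes unresolved; call resolve_endpoints() first")
    }
    o$endpoint_class
  }, character(1))
  rank <- surrogacy_rank(cls)
  p <- vapply(oc, function(o) o$p_value, numeric(1))
  primary <- vapply(oc, function(o) o$is_primary, logical(1))
  if (!any(primary)) stop("trial ", trial$trial_id, ": no primary outcome")

  prim_idx <- which(primary)
  prim_idx <- prim_idx[order(rank[prim_idx], p[prim_idx], prim_idx)]
  chosen <- prim_idx[1]

  if (p[chosen] <= p_met) {
    sec_idx <- which(!primary & rank < rank[chosen] & p <= p_marginal)
    if (length(sec_idx)) {
      sec_idx <- sec_idx[order(rank[sec_idx], p[sec_idx], sec_idx)]
      chosen <- sec_idx[1]
    }
  }
  oc[[chosen]]
}
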