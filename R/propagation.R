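# Single-generation value propagation with aging refresh.
#
# When new evidence makes a node lose value, part of that loss is passed to
# the regimens it had previously beaten (and symmetrically, part of a gain is
# passed to the regimens it had previously lost to). The edges through which
# value is passed also have their effective age reduced by one half-life,
# restoring relevance to the older result. Transfers are recorded as
# vertex-level adjustments so the signed edge decomposition stays auditable.

#' Find the single-generation propagation targets of a node
#'
#' @param node regimen id at which a value change occurred.
#' @param event_year year of the new evidence; only edges from strictly
#'   earlier years qualify.
#' @param edges edge table of a `regimen_network`.
#' @param direction `"LOSS"` (node lost value; targets are the losers of
#'   earlier edges the node won) or `"GAIN"` (targets are the winners of
#'   earlier edges the node lost).
#' @return data.frame with columns `target` and `edge_index` (row index into
#'   `edges`); zero rows when nothing qualifies.
#' @export
find_propagation_targets <- function(node, event_year, edges,
                                     direction = c("LOSS", "GAIN")) {
  direction <- match.arg(direction)
  prior <- edges$year < event_year & !is.na(edges$winner)
  qual <- if (direction == "LOSS") prior & edges$winner == node else
    prior & edges$loser == node
  qual[is.na(qual)] <- FALSE
  idx <- which(qual)
  target <- if (direction == "LOSS") edges$loser[idx] else edges$winner[idx]
  data.frame(target = target, edge_index = idx, stringsAsFactors = FALSE)
}

#' Refresh the aging of an edge by one half-life
#'
#' Reduces the edge's effective age by `half_life` years (floored at zero),
#' then recomputes its aging coefficient and contribution magnitude. With the
#' exponential decay used here the aging coefficient at most doubles, capped
#' at 1.
#'
#' @param edge one row of an edge table.
#' @param half_life half-life in years.
#' @return the refreshed edge row.
#' @export
refresh_edge <- function(edge, half_life) {
  stopifnot(nrow(edge) == 1, half_life > 0)
  edge$effective_age <- max(0, edge$effective_age - half_life)
  edge$aging <- 2^(-edge$effective_age / half_life)
  if (!is.na(edge$winner)) {
    edge$contribution <- edge$sig_weight * edge$rv * edge$e_magnitude *
      edge$log_n * edge$aging
  }
  edge
}

#' Apply one propagation event to a network state
#'
#' A fraction of the node's value change is transferred to the targets
#' (split equally or in proportion to the magnitude of each qualifying prior
#' edge's contribution); the node's own change shrinks by the amount passed
#' on. With refresh enabled, each qualifying prior edge's effective age is
#' reduced by one half-life and its contribution recomputed.
#'
#' @param state a `regimen_network`.
#' @param event list with `node`, `delta` (signed value change), `year`, and
#'   `source_trial`.
#' @param targets result of [find_propagation_targets()].
#' @param config a [valuation_config()].
#' @return the updated `regimen_network`.
#' @export
propagate_event <- function(state, event, targets,
                            config = valuation_config()) {
  frac <- config$propagation_fraction
  if (!is.finite(frac) || frac < 0 || frac > 1) {
    stop("propagation_fraction must lie in [0, 1]")
  }
  if (nrow(targets) == 0 || frac == 0 || event$delta == 0) return(state)

  transfer <- frac * event$delta
  shares <- if (config$split_rule == "PROPORTIONAL") {
    mag <- abs(state$edges$contribution[targets$edge_index])
    if (sum(mag) > 0) transfer * mag / sum(mag) else
      rep(transfer / nrow(targets), nrow(targets))
  } else {
    rep(transfer / nrow(targets), nrow(targets))
  }

  adj <- state$adjustments
  for (i in seq_len(nrow(targets))) {
    adj[targets$target[i]] <- adj[targets$target[i]] + shares[i]
  }
  adj[event$node] <- adj[event$node] - transfer
  state$adjustments <- adj

  n_refreshed <- 0L
  if (config$refresh_enabled) {
    for (idx in unique(targets$edge_index)) {
      state$edges[idx, ] <- refresh_edge(state$edges[idx, , drop = FALSE],
                                         config$half_life_years)
      n_refreshed <- n_refreshed + 1L
    }
  }

  state$vertices$value <- unname(
    .vertex_values(state$edges, state$vertices$regimen,
                   state$adjustments)[state$vertices$regimen])
  ev <- data.frame(year = event$year, node = event$node, delta = event$delta,
                   n_targets = nrow(targets), transferred = transfer,
                   n_refreshed = n_refreshed, stringsAsFactors = FALSE)
  ev$targets <- I(list(stats::setNames(shares, targets$target)))
  state$trace <- rbind(state$trace, ev)
  state
}

#' Value a trial network with propagation and refresh
#'
#' Replays publication years in ascending order. At each year, every node's
#' value change attributable to that year's new edges (valued at
#' `eval_year`) becomes a propagation event, processed through
#' [find_propagation_targets()] and [propagate_event()]. Within a year,
#' events are ordered by the earliest contributing trial id, then node id.
#' A `propagation_fraction` of zero disables propagation entirely and the
#' result is identical to [evaluate_network()].
#'
#' @inheritParams evaluate_network
#' @return a `regimen_network`; its `trace` element logs each propagation
#'   event (year, node, delta, targets and amounts, refreshed edge count).
#' @export
evaluate_with_propagation <- function(trials, eval_year,
                                      config = valuation_config()) {
  state <- evaluate_network(trials, eval_year, config)
  if (config$propagation_fraction == 0) return(state)

  for (yr in sort(unique(state$edges$year))) {
    new_idx <- which(state$edges$year == yr & !is.na(state$edges$winner) &
                       state$edges$contribution != 0)
    if (length(new_idx) == 0) next
    new_edges <- state$edges[new_idx, , drop = FALSE]
    nodes <- unique(c(new_edges$winner, new_edges$loser))
    deltas <- .vertex_values(new_edges, nodes)

    first_trial <- vapply(nodes, function(nd) {
      min(new_edges$trial_id[new_edges$winner == nd |
                               new_edges$loser == nd])
    }, character(1))
    for (nd in nodes[order(first_trial, nodes)]) {
      delta <- deltas[[nd]]
      if (delta == 0) next
      direction <- if (delta < 0) "LOSS" else "GAIN"
      targets <- find_propagation_targets(nd, yr, state$edges, direction)
      event <- list(node = nd, delta = delta, year = yr,
                    source_trial = first_trial[[nd]])
      state <- propagate_event(state, event, targets, config)
    }
  }
  state
}

#' Propagation event log of a network state
#'
#' @param state a `regimen_network` produced by
#'   [evaluate_with_propagation()].
#' @return data.frame of events (zero rows if none occurred).
#' @export
propagation_trace <- function(state) {
  stopifnot(inherits(state, "regimen_network"))
  if (is.null(state$trace)) {
    data.frame(year = integer(), node = character(), delta = numeric(),
               n_targets = integer(), transferred = numeric(),
               n_refreshed = integer())
  } else {
    state$trace
  }
}
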