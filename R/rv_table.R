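# Relative-value (RV) tables: map endpoint names to a surrogacy class and a
# unitless weight used in the vertex valuation formula.

.rv_classes <- c("STRONG", "INTERMEDIATE", "WEAK")
.rv_class_weights <- c(STRONG = 1.0, INTERMEDIATE = 0.8, WEAK = 0.7)

#' Surrogacy rank of an endpoint class
#'
#' Lower rank means less surrogate (closer to the definitive clinical
#' endpoint): STRONG (1) < INTERMEDIATE (2) < WEAK (3).
#'
#' @param class character vector of endpoint classes.
#' @return integer vector of ranks.
#' @export
surrogacy_rank <- function(class) {
  r <- match(class, .rv_classes)
  if (anyNA(r)) {
    stop("unknown endpoint class: ",
         paste(unique(class[is.na(r)]), collapse = ", "))
  }
  r
}

#' Construct a relative-value table
#'
#' An RV table maps each endpoint name appearing in a trial set to exactly one
#' surrogacy class (`STRONG`, `INTERMEDIATE`, or `WEAK`) and a strictly
#' positive weight in (0, 1]. The default weights are 1.0 for strong, 0.8 for
#' intermediate, and 0.7 for weak endpoints.
#'
#' @param endpoint character vector of endpoint names.
#' @param class character vector of surrogacy classes, recycled if length 1.
#' @param rv optional numeric weights; defaults to the class weights.
#' @return a data.frame of class `rv_table` with columns `endpoint`, `class`,
#'   `rv`.
#' @export
rv_table <- function(endpoint, class, rv = NULL) {
  stopifnot(is.character(endpoint), length(endpoint) >= 1)
  class <- rep_len(as.character(class), length(endpoint))
  surrogacy_rank(class)  # validates
  if (is.null(rv)) rv <- unname(.rv_class_weights[class])
  rv <- rep_len(as.numeric(rv), length(endpoint))
  if (any(!is.finite(rv)) || any(rv <= 0)) {
    stop("rv weights must be strictly positive")
  }
  if (anyDuplicated(endpoint)) {
    stop("each endpoint name must map to exactly one class: duplicated ",
         paste(unique(endpoint[duplicated(endpoint)]), collapse = ", "))
  }
  structure(data.frame(endpoint = endpoint, class = class, rv = rv,
                       stringsAsFactors = FALSE),
            class = c("rv_table", "data.frame"))
}

#' Default relative-value table
#'
#' Ships the surrogacy assignments used throughout: overall survival is the
#' strong (least surrogate) endpoint; progression-free and event-free survival
#' are intermediate surrogates; response rates and molecular/cytogenetic
#' response markers are weak surrogates. Fully overridable: supply your own
#' [rv_table()] or per-class weights via `class_weights`.
#'
#' @param class_weights named numeric vector giving the weight for each of
#'   STRONG, INTERMEDIATE, WEAK.
#' @return an `rv_table`.
#' @export
default_rv_table <- function(class_weights = .rv_class_weights) {
  stopifnot(all(.rv_classes %in% names(class_weights)))
  ep <- c(
    "overall survival"              = "STRONG",
    "progression-free survival"     = "INTERMEDIATE",
    "event-free survival"           = "INTERMEDIATE",
    "time to progression"           = "INTERMEDIATE",
    "overall response rate"         = "WEAK",
    "complete response rate"        = "WEAK",
    "major molecular response"      = "WEAK",
    "complete cytogenetic response" = "WEAK",
    "complete hematologic response" = "WEAK"
  )
  rv_table(names(ep), unname(ep),
           rv = unname(class_weights[unname(ep)]))
}

#' Look up the class and weight of an endpoint
#'
#' @param table an `rv_table`.
#' @param endpoint endpoint name (exact, case-insensitive match).
#' @return list with elements `class` and `rv`.
#' @export
rv_lookup <- function(table, endpoint) {
  stopifnot(inherits(table, "rv_table"), length(endpoint) == 1)
  i <- match(tolower(endpoint), tolower(table$endpoint))
  if (is.na(i)) {
    stop("endpoint '", endpoint, "' has no relative-value table entry")
  }
  list(class = table$class[i], rv = table$rv[i])
}

#' Uniformly rescale the weights of an RV table
#'
#' Multiplies every weight by `1 + delta` for the sensitivity analysis of the
#' rankings. Weights are capped at 1 (RV is a relative weight whose defining
#' maximum is the strong class at 1.0) and must remain positive.
#'
#' @param table an `rv_table`.
#' @param delta signed fraction, must be > -1 (e.g. 0.05 for +5%).
#' @param cap upper bound applied after scaling.
#' @return the rescaled `rv_table`.
#' @export
scale_rv <- function(table, delta, cap = 1.0) {
  stopifnot(inherits(table, "rv_table"))
  if (!is.finite(delta) || delta <= -1) {
    stop("rv perturbation must be a finite fraction greater than -100%")
  }
  table$rv <- pmin(table$rv * (1 + delta), cap)
  table
}
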