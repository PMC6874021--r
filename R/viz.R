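# Network visualization: divergent color by value, area by patients studied,
# transparency by evidence age, edge color by endpoint class, plus GraphML
# export. All operations are pure with respect to the network state.

.edge_class_colors <- c(STRONG = "#1A9641",        # green
                        INTERMEDIATE = "#FF7F00",  # orange
                        WEAK = "#2C7BB6")          # blue, weak surrogates

#' Convert a network state to an igraph object
#'
#' Vertex attributes: `value`, `size` (patients), `interpretation`. Edge
#' attributes: `trial_id`, `year`, `endpoint`, `endpoint_class`,
#' `contribution` (signed toward the edge head: each edge points loser ->
#' winner; draws keep their a -> b orientation with contribution 0),
#' `effective_age`.
#'
#' @param state a `regimen_network`.
#' @param epsilon near-zero band for the interpretation attribute.
#' @return an igraph graph.
#' @export
as_regimen_graph <- function(state, epsilon = 0.5) {
  stopifnot(inherits(state, "regimen_network"))
  e <- state$edges
  from <- ifelse(is.na(e$winner), e$regimen_a, e$loser)
  to <- ifelse(is.na(e$winner), e$regimen_b, e$winner)
  ranked <- rank_regimens(state, epsilon = epsilon)
  vtx <- ranked[match(state$vertices$regimen, ranked$regimen), ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, trial_id = e$trial_id, year = e$year,
               endpoint = e$endpoint, endpoint_class = e$endpoint_class,
               contribution = e$contribution,
               effective_age = e$effective_age, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = vtx$regimen, value = vtx$value,
                          size = vtx$size,
                          interpretation = vtx$interpretation,
                          stringsAsFactors = FALSE))
  g
}

.divergent_color <- function(values, palette = c("#B2182B", "#F7F7F7",
                                                 "#2166AC")) {
  maxabs <- max(abs(values))
  t <- if (maxabs == 0) rep(0.5, length(values)) else
    (values / maxabs + 1) / 2
  ramp <- grDevices::colorRamp(palette)
  rgb <- ramp(t)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Resolve the visual channels of a network
#'
#' Vertex color follows a divergent scale symmetric about zero (negative
#' pole red, positive pole blue, white at exactly zero) with extremes at
#' +/- max|value|; vertex area is proportional to patients studied; vertex
#' opacity decreases linearly with the age of its newest incident evidence
#' (1.0 at age 0 down to 0.25 at three half-lives or more). Edge color is
#' categorical by endpoint class (weak surrogates blue) and edge width is
#' proportional to the contribution magnitude.
#'
#' @param state a `regimen_network`.
#' @param half_life half-life used for the age-to-opacity mapping, years.
#' @param palette length-3 vector: negative pole, midpoint, positive pole.
#' @param max_radius plot radius (in igraph size units) of the largest
#'   vertex.
#' @return an igraph graph with `color`, `radius`, `alpha` vertex attributes
#'   and `color`, `width` edge attributes resolved.
#' @export
assign_visual_channels <- function(state, half_life = 10,
                                   palette = c("#B2182B", "#F7F7F7",
                                               "#2166AC"),
                                   max_radius = 25) {
  g <- as_regimen_graph(state)
  val <- igraph::V(g)$value
  igraph::V(g)$color <- .divergent_color(val, palette)

  sz <- igraph::V(g)$size
  igraph::V(g)$radius <- max_radius * sqrt(sz / max(sz))  # area ~ patients

  # newest incident evidence dominates visibility
  min_age <- vapply(igraph::V(g)$name, function(nm) {
    inc <- state$edges$regimen_a == nm | state$edges$regimen_b == nm
    min(state$edges$effective_age[inc])
  }, numeric(1))
  igraph::V(g)$alpha <- 1 - 0.75 * pmin(min_age / (3 * half_life), 1)

  igraph::E(g)$color <- unname(.edge_class_colors[igraph::E(g)$endpoint_class])
  cmax <- max(abs(igraph::E(g)$contribution), 1e-12)
  igraph::E(g)$width <- 0.5 + 4 * abs(igraph::E(g)$contribution) / cmax
  g
}

#' Deterministic force-directed layout
#'
#' @param g a styled igraph graph.
#' @param seed integer seed; the same graph and seed always give the same
#'   coordinates.
#' @return the graph with a `layout` graph attribute (n x 2 matrix).
#' @export
layout_network <- function(g, seed = 42) {
  coords <- if (igraph::vcount(g) == 1) {
    matrix(0, nrow = 1, ncol = 2)
  } else {
    .with_seed(seed, igraph::layout_with_fr(g))
  }
  igraph::graph_attr(g, "layout") <- coords
  g
}

#' Render a regimen network to SVG or PNG
#'
#' Draws the styled, positioned network with a legend (value color bar
#' endpoints, size key, endpoint-class key) and the evaluation year stamped
#' in the title.
#'
#' @param state a `regimen_network`.
#' @param path output file path ending in `.svg` or `.png`.
#' @param fmt output format; inferred from the extension by default.
#' @param seed layout seed.
#' @param width,height device size in inches.
#' @param half_life half-life for the opacity channel, years.
#' @return the path, invisibly.
#' @export
render_network <- function(state, path, fmt = c("auto", "svg", "png"),
                           seed = 42, width = 8, height = 8,
                           half_life = 10) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  }
  g <- layout_network(assign_visual_channels(state, half_life = half_life),
                      seed = seed)
  vcol <- mapply(grDevices::adjustcolor, igraph::V(g)$color,
                 alpha.f = igraph::V(g)$alpha)
  if (fmt == "svg") grDevices::svg(path, width = width, height = height) else
    grDevices::png(path, width = width * 100, height = height * 100)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 1))
  igraph::plot.igraph(
    g, layout = igraph::graph_attr(g, "layout"),
    vertex.size = igraph::V(g)$radius, vertex.color = vcol,
    vertex.label = igraph::V(g)$name, vertex.label.cex = 0.7,
    vertex.label.color = "black",
    edge.color = igraph::E(g)$color, edge.width = igraph::E(g)$width,
    edge.arrow.size = 0.4,
    main = sprintf("Regimen evidence network, %d", state$eval_year))
  maxv <- max(abs(igraph::V(g)$value))
  graphics::legend(
    "bottomleft", bty = "n", cex = 0.7,
    legend = c(sprintf("value +%.1f", maxv), "value 0",
               sprintf("value -%.1f", maxv),
               sprintf("largest vertex: %d patients",
                       max(igraph::V(g)$size)),
               "strong endpoint", "intermediate endpoint",
               "weak endpoint"),
    col = c(.divergent_color(c(maxv, 0, -maxv)),
            "gray40", unname(.edge_class_colors)),
    pch = c(19, 19, 19, 19, NA, NA, NA),
    lty = c(NA, NA, NA, NA, 1, 1, 1), lwd = 2)
  invisible(path)
}

#' Export a network state to GraphML
#'
#' Node attributes: `value` (double), `size` (double, patients),
#' `interpretation` (string). Edge attributes: `trial_id`, `year`,
#' `endpoint`, `endpoint_class`, `contribution`, `effective_age`. The file
#' round-trips losslessly through a generic GraphML reader.
#'
#' @param state a `regimen_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_graphml <- function(state, path) {
  g <- as_regimen_graph(state)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
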