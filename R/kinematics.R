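#' Node size class for a kinematic diagram
#'
#' Bins a behavior's relative frequency (percent of all transitions) into the
#' five ascending symbol-size classes `<1%`, `1-5%`, `5-10%`, `10-15%`,
#' `>15%`. Bins are half-open `[lo, hi)`: a boundary value belongs to the
#' upper class.
#'
#' @param freq_pct relative frequency in percent (vectorized).
#' @return Integer class 1..5.
#' @examples
#' node_size_class(c(0.47, 1, 15))
#' @export
node_size_class <- function(freq_pct) {
  if (any(freq_pct < 0)) stop("frequency percentage must be nonnegative")
  findInterval(freq_pct, c(1, 5, 10, 15)) + 1L
}

#' Edge band for a kinematic diagram
#'
#' Bins a significant Freeman-Tukey deviate into the three ascending arrow
#' classes: `[criterion, 5)` low (black), `[5, 10)` intermediate (orange),
#' `>= 10` high (red). Non-significant deviates are not drawn and raise an
#' error.
#'
#' @param deviate Freeman-Tukey deviate(s), each above `criterion`.
#' @param criterion the simultaneous significance criterion of the fit.
#' @return Character vector: `"low"`, `"intermediate"` or `"high"`.
#' @export
edge_band <- function(deviate, criterion) {
  if (any(deviate <= criterion)) {
    stop("deviate at or below the significance criterion: edge is not drawn")
  }
  c("low", "intermediate", "high")[findInterval(deviate, c(5, 10)) + 1L]
}

edge_color <- c(low = "black", intermediate = "orange", high = "red")
edge_penwidth <- c(low = 1, intermediate = 2.5, high = 4)

# Node shape by behavior category (squares for aggression, filled for
# high-intensity; circles for interactive/non-aggressive; triangles for
# non-interactive).
category_shape <- c(non_interactive = "triangle",
                    interactive_nonaggressive = "circle",
                    low_intensity_aggression = "box",
                    high_intensity_aggression = "box")

#' Build a kinematic diagram from a fit
#'
#' Nodes are the ethogram behaviors: size class encodes the behavior's
#' relative frequency (first-member row margin over total transitions, as a
#' percentage) and shape encodes its category. Edges are exactly the
#' significant transitions, banded by Freeman-Tukey deviate.
#'
#' @param fit a [qi_fit].
#' @param ethogram the [ethogram] of the fit.
#' @return List of class `kinematic_diagram` with `nodes` and `edges` data
#'   frames.
#' @export
kinematic_diagram <- function(fit, ethogram) {
  stopifnot(inherits(fit, "qi_fit"), inherits(ethogram, "ethogram"))
  if (!identical(fit$counts$labels, ethogram$code)) {
    stop("fit labels do not match ethogram codes")
  }
  freq_pct <- 100 * rowSums(fit$counts$n) / fit$counts$total
  nodes <- data.frame(code = ethogram$code,
                      category = ethogram$category,
                      frequency_pct = unname(freq_pct),
                      size_class = node_size_class(unname(freq_pct)),
                      shape = unname(category_shape[ethogram$category]),
                      filled = ethogram$category == "high_intensity_aggression",
                      stringsAsFactors = FALSE)
  sig <- significant_transitions(fit)
  edges <- data.frame(from = sig$from, to = sig$to, deviate = sig$deviate,
                      band = if (nrow(sig)) edge_band(sig$deviate, fit$criterion)
                             else character(0),
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, ethogram$code),
                       match(edges$to, ethogram$code)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "kinematic_diagram")
}

#' Export a kinematic diagram in DOT format
#'
#' Deterministic text output (nodes in ethogram order, edges in row-major
#' order): the same fit always yields byte-identical DOT, suitable for
#' rendering with any Graphviz-compatible tool.
#'
#' @param fit a [qi_fit].
#' @param ethogram the [ethogram] of the fit.
#' @param path optional output file; if `NULL` the DOT text is returned.
#' @return The DOT text as a character scalar (invisibly if written to
#'   `path`).
#' @export
export_dot <- function(fit, ethogram, path = NULL) {
  kd <- kinematic_diagram(fit, ethogram)
  node_pt <- c(10, 14, 18, 24, 30)  # symbol sizes by class
  lines <- c("digraph kinematic {",
             "  graph [overlap=false, splines=true];",
             "  node [fixedsize=true, fontname=\"Helvetica\"];")
  for (i in seq_len(nrow(kd$nodes))) {
    nd <- kd$nodes[i, ]
    sz <- node_pt[nd$size_class] / 18
    lines <- c(lines, sprintf(
      "  \"%s\" [shape=%s, width=%.3f, height=%.3f, style=%s, label=\"%s\"];",
      nd$code, nd$shape, sz, sz,
      if (nd$filled) "filled" else "solid", nd$code))
  }
  for (i in seq_len(nrow(kd$edges))) {
    ed <- kd$edges[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [color=%s, penwidth=%g];",
      ed$from, ed$to, edge_color[[ed$band]], edge_penwidth[[ed$band]]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
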