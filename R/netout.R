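# Gene-flow networks: populations are nodes, directed edges carry
# relative migration weights. Filtering applies to the normalized
# weights; the significance mask from the bootstrap test can restrict
# edges to significantly asymmetric directions.

#' Build a gene-flow network
#'
#' Keeps every off-diagonal entry of the relative migration matrix with
#' weight at or above `threshold`, intersected with an optional logical
#' edge mask (e.g. from [significant_edge_mask()]). Self-edges never
#' occur.
#'
#' @param c a `relative_migration` matrix (or plain square matrix with
#'   entries in `[0, 1]`).
#' @param threshold filter threshold in `[0, 1]`; raising it never adds
#'   edges.
#' @param mask optional logical matrix of the same shape; only `TRUE`
#'   cells become edges.
#' @return A `flow_network`: list with `nodes`, `edges` (data frame
#'   `from`, `to`, `weight`, `significant`), `graph` (igraph),
#'   `threshold`, `masked`.
#' @export
build_network <- function(c, threshold = 0, mask = NULL) {
  cm <- unclass(c)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("`c` must be a square relative migration matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single value in [0, 1]")
  nodes <- rownames(cm)
  if (is.null(nodes)) nodes <- sprintf("pop%d", seq_len(nrow(cm)))
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(cm)))
      stop("`mask` must be a logical matrix of the same shape as `c`")
  }
  keep <- !is.na(cm) & row(cm) != col(cm) & cm >= threshold
  if (!is.null(mask)) keep <- keep & mask
  ij <- which(keep, arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  edges <- data.frame(from = nodes[ij[, 1L]], to = nodes[ij[, 2L]],
                      weight = cm[ij],
                      significant = rep(if (is.null(mask)) NA else TRUE,
                                        nrow(ij)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, masked = !is.null(mask)),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("flow_network: %d populations, %d directed edges (threshold %g%s)\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              if (x$masked) ", significance-masked" else ""))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export a gene-flow network
#'
#' Writes an edge-list CSV (`from,to,weight,significant`), GraphML, or
#' DOT file. Weights are written with 4 decimal places.
#'
#' @param n a `flow_network`.
#' @param path output path.
#' @param format `"csv"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(n, path, format = c("csv", "graphml", "dot")) {
  stopifnot(inherits(n, "flow_network"))
  format <- match.arg(format)
  if (format == "csv") {
    e <- n$edges
    e$weight <- round(e$weight, 4L)
    write.csv(e, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  g <- n$graph
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- round(n$edges$weight, 4L)
  if (format == "dot" && "significant" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "significant")  # DOT has no booleans
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read an edge-list CSV written by [export_network()]
#' @param path CSV path.
#' @return Data frame with `from`, `to`, `weight`, `significant`.
#' @export
read_edge_list <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Plot a gene-flow network
#'
#' Best-effort static rendering: force-directed layout with edge width
#' and shade proportional to relative migration. The exportable edge
#' list, not the drawing, is the quantitative artifact.
#'
#' @param x a `flow_network`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.flow_network <- function(x, ...) {
  g <- x$graph
  w <- if (nrow(x$edges)) x$edges$weight else numeric()
  igraph::plot.igraph(
    g, layout = igraph::layout_with_fr(g),
    edge.width = 0.5 + 4 * w, edge.arrow.size = 0.5,
    edge.color = grDevices::gray(1 - 0.8 * w),
    vertex.color = "lightsteelblue", vertex.label.color = "black", ...)
  invisible(x)
}
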