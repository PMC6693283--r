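# Degree centrality split into inner (edges pointing into a node — "is
# regulated by"), outer (edges pointing out — "regulates") and total
# degree, computed per frame. These drive HUB-node identification, node
# sizing, and threshold hiding.

#' Per-frame degree table
#'
#' For a directed network: `inner(v)` = number of edges `u -> v` in the
#' frame, `outer(v)` = number of edges `v -> u`, `total = inner + outer`.
#' A self-loop adds 1 to inner and 1 to outer. For an undirected network the
#' split is not meaningful: `inner = outer = total =` incident edge count.
#'
#' @param net A [temporal_network()].
#' @param frame Frame label (must be in `net$frames`).
#' @return Tibble with one row per network node: `node`, `frame`, `inner`,
#'   `outer`, `total`. Isolated nodes appear with zero degrees.
#' @export
#' @examples
#' net <- temporal_network(data.frame(source = c("A", "A", "B"),
#'                                    target = c("B", "C", "C")))
#' degree_table(net, "static")
degree_table <- function(net, frame) {
  stopifnot(is_temporal_network(net))
  ed <- frame_edges(net, frame)
  node_f <- factor(net$nodes, levels = net$nodes)
  inn <- table(factor(ed$target, levels = net$nodes))
  out <- table(factor(ed$source, levels = net$nodes))
  res <- tibble::tibble(
    node = net$nodes,
    frame = frame,
    inner = as.integer(inn),
    outer = as.integer(out)
  )
  if (net$directed) {
    res$total <- res$inner + res$outer
  } else {
    # incident edge count; a self-loop is one incident edge
    inc <- as.integer(inn) + as.integer(out) -
      as.integer(table(factor(ed$source[ed$source == ed$target],
                              levels = net$nodes)))
    res$inner <- inc
    res$outer <- inc
    res$total <- inc
  }
  res
}

#' Degree table over all frames
#'
#' The exportable "node degree table": [degree_table()] stacked over every
#' frame, showing how the degree of each node changes over the series.
#'
#' @param net A [temporal_network()].
#' @return Tibble `node`, `frame`, `inner`, `outer`, `total`, ordered by
#'   frame then node.
#' @export
degree_over_time <- function(net) {
  stopifnot(is_temporal_network(net))
  purrr::map_dfr(net$frames, function(f) degree_table(net, f))
}

#' Write a degree table as TSV
#' @param degrees Output of [degree_table()] or [degree_over_time()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degree_table <- function(degrees, path) {
  readr::write_tsv(degrees, path)
  invisible(path)
}

new_subnetwork <- function(parent, nodes, edges, provenance) {
  structure(
    list(nodes = nodes, frames = unique(edges$frame) %||% character(),
         edges = edges, directed = parent$directed,
         parent_glance = glance.temporal_network(parent),
         provenance = provenance),
    class = c("subnetwork", "temporal_network")
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork:%s> %d nodes, %d edges\n",
              x$provenance, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Hide nodes below a degree threshold
#'
#' Retains the nodes whose chosen degree (total, inner or outer) in the
#' given frame is at least `threshold`, plus the frame edges both of whose
#' endpoints survive. Threshold 0 is the identity.
#'
#' @param net A [temporal_network()].
#' @param frame Frame label.
#' @param threshold Non-negative integer degree cut-off.
#' @param which Which degree to threshold on: `"total"` (default),
#'   `"inner"` or `"outer"`.
#' @return A `subnetwork` (also a [temporal_network()]) restricted to the
#'   frame, with provenance `"threshold"`.
#' @export
filter_by_degree <- function(net, frame, threshold,
                             which = c("total", "inner", "outer")) {
  stopifnot(is_temporal_network(net))
  which <- match.arg(which)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  deg <- degree_table(net, frame)
  keep <- deg$node[deg[[which]] >= threshold]
  ed <- frame_edges(net, frame)
  ed <- dplyr::filter(ed, .data$source %in% keep & .data$target %in% keep)
  new_subnetwork(net, keep, ed, "threshold")
}

#' First-degree neighbourhood of a node
#'
#' The local neighbour network around a selected node in one frame: the node
#' itself, every frame-neighbour in either direction (regulators and
#' targets), and all frame edges among the retained set.
#'
#' @param net A [temporal_network()].
#' @param node Node id (must be in `net$nodes`).
#' @param frame Frame label.
#' @return A `subnetwork` with provenance `"neighbourhood"`; the focal node
#'   is stored in `$focal`.
#' @export
first_degree_neighbourhood <- function(net, node, frame) {
  stopifnot(is_temporal_network(net))
  if (!node %in% net$nodes) {
    stop("unknown node: '", node, "'", call. = FALSE)
  }
  ed <- frame_edges(net, frame)
  nb <- unique(c(node,
                 ed$target[ed$source == node],
                 ed$source[ed$target == node]))
  keep_nodes <- net$nodes[net$nodes %in% nb]
  ed <- dplyr::filter(ed, .data$source %in% keep_nodes &
                        .data$target %in% keep_nodes)
  sub <- new_subnetwork(net, keep_nodes, ed, "neighbourhood")
  sub$focal <- node
  sub
}

#' Edges persisting between two frames
#'
#' The intersection of two frames' edge sets. Edge identity is the ordered
#' (source, target) pair; the relation label is ignored. Companion counts
#' (sizes of each frame, the intersection and both differences) are attached
#' and available via [edge_turnover()].
#'
#' @param net A [temporal_network()].
#' @param frame_a,frame_b Frame labels to compare.
#' @return Tibble of persistent edges (`source`, `target`, `relation`,
#'   `frame` of `frame_a`), with attribute `turnover` (the count tibble).
#' @export
persistent_edges <- function(net, frame_a, frame_b) {
  stopifnot(is_temporal_network(net))
  ea <- frame_edges(net, frame_a)
  eb <- frame_edges(net, frame_b)
  key <- function(e) paste(e$source, e$target, sep = "\r")
  inter <- ea[key(ea) %in% key(eb), ]
  turnover <- tibble::tibble(
    frame_a = frame_a, frame_b = frame_b,
    n_a = nrow(ea), n_b = nrow(eb),
    n_persistent = nrow(inter),
    n_lost = nrow(ea) - nrow(inter),
    n_gained = nrow(eb) - nrow(inter)
  )
  attr(inter, "turnover") <- turnover
  inter
}

#' Edge turnover counts between two frames
#'
#' @inheritParams persistent_edges
#' @return One-row tibble: `frame_a`, `frame_b`, `n_a`, `n_b`,
#'   `n_persistent`, `n_lost` (in a only), `n_gained` (in b only).
#' @export
edge_turnover <- function(net, frame_a, frame_b) {
  attr(persistent_edges(net, frame_a, frame_b), "turnover")
}
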