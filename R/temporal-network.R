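# The temporal network container: an ordered node set, an ordered frame
# vector, and one edge tibble in long format (source, target, relation,
# frame). A static network is the degenerate case with a single frame.

#' Construct a temporal network
#'
#' The central data structure of tempnet. Edges live in a long-format tibble
#' with one row per (source, target, frame); a static network has exactly one
#' frame. Duplicate edges within a frame are collapsed; self-loops are kept.
#'
#' @param edges A data frame with columns `source` and `target` (character),
#'   and optionally `relation` and `frame`. A missing `frame` column puts all
#'   edges in a single static frame.
#' @param nodes Optional character vector of node ids. Defaults to the union
#'   of edge endpoints; ids listed here but absent from `edges` become
#'   isolated nodes.
#' @param directed Logical flag, one per network. Biological regulatory
#'   networks ("A regulates B") are directed, the default.
#' @param frames Optional character vector fixing frame order. Defaults to
#'   first-appearance order in `edges`.
#' @param static_frame Label used for the single frame of a static network.
#'
#' @return A `temporal_network` object: a list with fields `nodes` (ordered
#'   character), `frames` (ordered character), `edges` (tibble with columns
#'   `source`, `target`, `relation`, `frame`) and `directed` (flag).
#' @export
#' @examples
#' net <- temporal_network(data.frame(source = c("A", "B"), target = c("B", "C")))
#' net$nodes
temporal_network <- function(edges, nodes = NULL, directed = TRUE,
                             frames = NULL, static_frame = "static") {
  edges <- tibble::as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    stop("`edges` must have columns `source` and `target`", call. = FALSE)
  }
  if (!"relation" %in% names(edges)) edges$relation <- NA_character_
  if (!"frame" %in% names(edges)) edges$frame <- static_frame
  edges <- edges %>%
    dplyr::mutate(
      source = stringr::str_trim(as.character(.data$source)),
      target = stringr::str_trim(as.character(.data$target)),
      relation = as.character(.data$relation),
      frame = as.character(.data$frame)
    ) %>%
    dplyr::select("source", "target", "relation", "frame")
  if (nrow(edges) > 0 && any(edges$source == "" | edges$target == "")) {
    stop("edge endpoints must be non-empty node ids", call. = FALSE)
  }
  # duplicate edges within a frame collapse to one (relation of first kept)
  edges <- dplyr::distinct(edges, .data$source, .data$target, .data$frame,
                           .keep_all = TRUE)

  frame_order <- frames %||% unique(edges$frame)
  if (length(frame_order) == 0) frame_order <- static_frame
  unknown <- setdiff(edges$frame, frame_order)
  if (length(unknown) > 0) {
    stop("edge frames not in declared frame order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  edges <- dplyr::arrange(edges, match(.data$frame, frame_order))

  node_order <- unique(c(nodes, edges$source, edges$target))
  node_order <- stringr::str_trim(as.character(node_order))
  node_order <- node_order[node_order != ""]

  structure(
    list(nodes = node_order, frames = as.character(frame_order),
         edges = edges, directed = isTRUE(directed)),
    class = "temporal_network"
  )
}

#' Test for a temporal network
#' @param x Object to test.
#' @return `TRUE` for objects created by [temporal_network()].
#' @export
is_temporal_network <- function(x) inherits(x, "temporal_network")

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf(
    "<temporal_network> %d nodes, %d frames, %d edges (%s)\n",
    length(x$nodes), length(x$frames), nrow(x$edges),
    if (x$directed) "directed" else "undirected"
  ))
  counts <- table(factor(x$edges$frame, levels = x$frames))
  for (f in x$frames) cat(sprintf("  frame %-12s %d edges\n", f, counts[[f]]))
  invisible(x)
}

#' Edge table of a single frame
#'
#' @param net A [temporal_network()].
#' @param frame Frame label; must be one of `net$frames`.
#' @return Tibble of the frame's edges (`source`, `target`, `relation`,
#'   `frame`).
#' @export
frame_edges <- function(net, frame) {
  stopifnot(is_temporal_network(net))
  if (!frame %in% net$frames) {
    stop("unknown frame: '", frame, "' (frames: ",
         paste(net$frames, collapse = ", "), ")", call. = FALSE)
  }
  dplyr::filter(net$edges, .data$frame == !!frame)
}

#' Tidy a temporal network into its long edge table
#'
#' @param x A [temporal_network()].
#' @param ... Unused.
#' @return The long-format edge tibble (`source`, `target`, `relation`,
#'   `frame`), one row per edge occurrence.
#' @exportS3Method generics::tidy
tidy.temporal_network <- function(x, ...) x$edges

#' One-row summary of a temporal network
#'
#' @param x A [temporal_network()].
#' @param ... Unused.
#' @return A one-row tibble: `n_nodes`, `n_frames`, `n_edges` (rows of the
#'   long table), `directed`.
#' @exportS3Method generics::glance
glance.temporal_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_frames = length(x$frames),
    n_edges = nrow(x$edges),
    directed = x$directed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

`%||%` <- function(a, b) if (is.null(a)) b else a
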