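# File I/O for all network and data dialects: two-column edge lists, 0/1
# adjacency matrices with row+column labels, Cytoscape SIF, long-format
# dynamic edge tables, and node-expression tables. Format detection is
# deterministic and total: every input maps to exactly one format, and
# anything ambiguous is UNKNOWN, never guessed silently.

NETWORK_FORMATS <- c("edge_list", "adjacency_matrix", "sif",
                     "dynamic_edge_list", "unknown")

# Delimiter sniffing: try tab, comma, semicolon, then any whitespace; the
# first candidate giving a consistent column count (> 1 where possible) wins.
split_lines <- function(lines, delimiter) {
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) return(NULL)
  pat <- switch(delimiter, tab = "\t", comma = ",", semicolon = ";",
                whitespace = "\\s+")
  rows <- lapply(lines, function(l) {
    toks <- stringr::str_split(stringr::str_trim(l), pat)[[1]]
    stringr::str_trim(toks)
  })
  rows
}

sniff_raw_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  for (delim in c("tab", "comma", "semicolon", "whitespace")) {
    rows <- split_lines(lines, delim)
    widths <- lengths(rows)
    body_ok <- length(unique(widths[-1])) <= 1
    # a labelled adjacency matrix header is one cell short of the body
    header_ok <- widths[1] %in% c(widths[min(2, length(widths))],
                                  widths[min(2, length(widths))] - 1)
    if (body_ok && header_ok && (max(widths) > 1 || delim == "whitespace")) {
      return(list(rows = rows, delimiter = delim, path = path))
    }
  }
  # no delimiter yields consistent column counts: report the first offender
  rows <- split_lines(lines, "whitespace")
  widths <- lengths(rows)
  bad <- which(widths != widths[1])[1]
  stop(sprintf("ragged rows in %s: line %d has %d columns, expected %d",
               path, bad, widths[bad], widths[1]), call. = FALSE)
}

is_binary_chr <- function(x) all(x %in% c("0", "1"))

#' Detect the format of a raw network table
#'
#' Classifies a parsed text table as one of `edge_list`,
#' `adjacency_matrix`, `sif`, `dynamic_edge_list` or `unknown`:
#' * two columns throughout, not a 0/1 grid -> `edge_list`;
#' * a square grid of 0/1 cells with row and column labels -> `adjacency_matrix`;
#' * three columns where the file extension is `.sif` or the middle column
#'   repeats over a small token set while flanking columns look like ids ->
#'   `sif` (tokens read as source, relation, target);
#' * three or more columns whose third column repeats over a small label set
#'   (or matches declared frame labels) -> `dynamic_edge_list`;
#' * anything else -> `unknown`.
#'
#' @param raw A raw table from an internal sniffer, or a list of character
#'   token vectors (one per row).
#' @param path Optional file path; a `.sif` extension is decisive for
#'   three-column files.
#' @param frame_labels Optional declared frame labels that identify the
#'   third column of a dynamic edge table.
#' @return A single string, one of
#'   `c("edge_list", "adjacency_matrix", "sif", "dynamic_edge_list", "unknown")`.
#' @export
#' @examples
#' detect_format(list(c("A", "B"), c("B", "C")))
detect_format <- function(raw, path = NULL, frame_labels = NULL) {
  rows <- if (is.list(raw) && !is.null(raw$rows)) raw$rows else raw
  path <- path %||% (if (is.list(raw)) raw$path else NULL)
  if (length(rows) == 0) stop("empty table", call. = FALSE)
  widths <- lengths(rows)

  if (is_adjacency_rows(rows)) return("adjacency_matrix")

  if (all(widths == 2)) return("edge_list")

  if (all(widths == 3)) {
    if (!is.null(path) && grepl("\\.sif$", path, ignore.case = TRUE)) {
      return("sif")
    }
    third <- vapply(rows, `[`, "", 3)
    mid <- vapply(rows, `[`, "", 2)
    if (!is.null(frame_labels) && all(third %in% frame_labels)) {
      return("dynamic_edge_list")
    }
    # relation heuristic: few distinct middle tokens that never appear as an
    # endpoint anywhere in the file
    endpoints <- unique(c(vapply(rows, `[`, "", 1), third))
    mid_small <- length(unique(mid)) <= max(1, ceiling(length(rows) / 3))
    if (mid_small && !any(unique(mid) %in% endpoints)) return("sif")
    third_small <- length(unique(third)) <= max(1, ceiling(length(rows) / 2))
    if (third_small) return("dynamic_edge_list")
    return("unknown")
  }

  if (all(widths >= 3) && length(unique(widths)) == 1) {
    third <- vapply(rows, `[`, "", 3)
    if (!is.null(frame_labels)) {
      if (all(third %in% frame_labels)) return("dynamic_edge_list")
    } else if (length(unique(third)) <= max(1, ceiling(length(rows) / 2))) {
      return("dynamic_edge_list")
    }
  }
  "unknown"
}

# square 0/1 grid with row+column labels ("" or a corner token allowed at
# the top-left); bare unlabelled grids are not accepted (cannot be told from
# node ids that merely look numeric)
is_adjacency_rows <- function(rows) {
  if (length(rows) < 2) return(FALSE)
  widths <- lengths(rows)
  n <- length(rows) - 1          # body rows
  header <- rows[[1]]
  body <- rows[-1]
  if (!all(lengths(body) == lengths(body)[1])) return(FALSE)
  body_w <- lengths(body)[1]
  if (body_w != n + 1) return(FALSE)              # label + n cells
  if (!(widths[1] %in% c(n, n + 1))) return(FALSE) # header: n labels (+corner)
  cells <- unlist(lapply(body, function(r) r[-1]))
  is_binary_chr(cells)
}

#' Read a static network file
#'
#' Reads a two-column edge list, a labelled 0/1 adjacency matrix or a
#' Cytoscape SIF file into a single-frame [temporal_network()]. The format is
#' auto-detected unless given. The node set is the union of edge endpoints
#' (for an adjacency matrix, the row/column labels, so isolated nodes are
#' kept); duplicate edges collapse; edge and node counts are logged.
#'
#' @param path Path to the network file (`.txt`, `.csv`, `.tsv`, `.sif`;
#'   tab, comma, semicolon or whitespace separated).
#' @param format One of `"auto"` (default), `"edge_list"`,
#'   `"adjacency_matrix"`, `"sif"`.
#' @param directed Directedness flag for the whole network (default
#'   `TRUE`).
#' @param static_frame Frame label given to the single frame.
#' @param quiet Suppress the count log line.
#' @return A single-frame [temporal_network()].
#' @export
read_network <- function(path, format = "auto", directed = TRUE,
                         static_frame = "static", quiet = TRUE) {
  raw <- sniff_raw_table(path)
  if (identical(format, "auto")) format <- detect_format(raw)
  if (format == "unknown") {
    stop("unsupported or unrecognized network format in ", path, call. = FALSE)
  }
  if (format == "dynamic_edge_list") {
    return(read_dynamic_edges(path, directed = directed, quiet = quiet))
  }
  rows <- raw$rows
  net <- switch(format,
    edge_list = {
      if (!all(lengths(rows) == 2)) {
        stop("edge list rows must have exactly 2 columns", call. = FALSE)
      }
      temporal_network(
        tibble::tibble(source = vapply(rows, `[`, "", 1),
                       target = vapply(rows, `[`, "", 2)),
        directed = directed, static_frame = static_frame
      )
    },
    sif = {
      if (!all(lengths(rows) == 3)) {
        stop("SIF rows must have exactly 3 tokens", call. = FALSE)
      }
      temporal_network(
        tibble::tibble(source = vapply(rows, `[`, "", 1),
                       relation = vapply(rows, `[`, "", 2),
                       target = vapply(rows, `[`, "", 3)),
        directed = directed, static_frame = static_frame
      )
    },
    adjacency_matrix = read_adjacency_rows(rows, directed, static_frame),
    stop("unsupported format: ", format, call. = FALSE)
  )
  if (!quiet) {
    message(sprintf("read %s: %d nodes, %d edges [%s]", path,
                    length(net$nodes), nrow(net$edges), format))
  }
  net
}

read_adjacency_rows <- function(rows, directed, static_frame) {
  header <- rows[[1]]
  body <- rows[-1]
  n <- length(body)
  col_labels <- if (length(header) == n + 1) header[-1] else header
  row_labels <- vapply(body, `[`, "", 1)
  cells <- t(vapply(body, function(r) r[-1], character(n)))
  if (n == 1) cells <- matrix(body[[1]][-1], nrow = 1)
  if (!is_binary_chr(cells)) {
    bad <- cells[!cells %in% c("0", "1")][1]
    stop("adjacency matrix cell outside {0,1}: '", bad, "'", call. = FALSE)
  }
  idx <- which(cells == "1", arr.ind = TRUE)
  edges <- tibble::tibble(source = row_labels[idx[, 1]],
                          target = col_labels[idx[, 2]])
  temporal_network(edges, nodes = unique(c(row_labels, col_labels)),
                   directed = directed, static_frame = static_frame)
}

#' Read a dynamic edge interaction file
#'
#' Long-format table with one interaction per row and at least three
#' columns: source, target and frame label (a fourth column, if present, is
#' taken as the relation). The result is a multi-frame
#' [temporal_network()] whose per-frame edge sets drive edge-rewiring
#' animation. Frame order is first-appearance order unless `frames` is given.
#'
#' @param path Path to the dynamic edge file (CSV/TSV).
#' @param directed Directedness flag.
#' @param frames Optional frame label order overriding first appearance.
#' @param quiet Suppress the count log line.
#' @return A [temporal_network()] with one frame per distinct label.
#' @export
read_dynamic_edges <- function(path, directed = TRUE, frames = NULL,
                               quiet = TRUE) {
  raw <- sniff_raw_table(path)
  rows <- raw$rows
  if (any(lengths(rows) < 3)) {
    stop("dynamic edge file needs >= 3 columns (source, target, frame); ",
         path, " has a row with ", min(lengths(rows)), call. = FALSE)
  }
  edges <- tibble::tibble(
    source = vapply(rows, `[`, "", 1),
    target = vapply(rows, `[`, "", 2),
    frame = vapply(rows, `[`, "", 3),
    relation = vapply(rows, function(r) if (length(r) >= 4) r[4] else NA_character_, "")
  )
  net <- temporal_network(edges, directed = directed, frames = frames)
  if (!quiet) {
    message(sprintf("read %s: %d nodes, %d frames, %d edges", path,
                    length(net$nodes), length(net$frames), nrow(net$edges)))
  }
  net
}

#' Read a node-expression series
#'
#' First column: node ids. Header row: ordered frame labels (time, dose, or
#' dose-over-time such as `T8_D5000`). Remaining cells: expression values in
#' any user unit (intensity, log fold change, ...). Empty cells are recorded
#' as missing, not zero, and render in neutral grey downstream.
#'
#' @param path Path to the expression table (CSV/TSV, header required).
#' @return An `expression_series`: a tibble with column `node` plus one
#'   numeric column per frame, carrying attribute `frames` (ordered labels).
#' @export
read_expression <- function(path) {
  raw <- sniff_raw_table(path)
  rows <- raw$rows
  if (length(rows) < 2) stop("expression file needs a header and data rows",
                             call. = FALSE)
  header <- rows[[1]]
  body <- rows[-1]
  if (!all(lengths(body) == length(header))) {
    stop("expression rows must match header width", call. = FALSE)
  }
  frames <- header[-1]
  nodes <- vapply(body, `[`, "", 1)
  if (anyDuplicated(nodes)) {
    stop("duplicated node id in expression file: ",
         nodes[duplicated(nodes)][1], call. = FALSE)
  }
  vals <- lapply(seq_along(frames), function(j) {
    cells <- vapply(body, `[`, "", j + 1)
    out <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & nzchar(cells) & cells != "NA" & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric expression cell at row %d, column '%s': '%s'",
                   bad[1] + 1, frames[j], cells[bad[1]]), call. = FALSE)
    }
    out
  })
  expr <- tibble::tibble(node = nodes)
  for (j in seq_along(frames)) expr[[frames[j]]] <- vals[[j]]
  new_expression_series(expr, frames)
}

new_expression_series <- function(tbl, frames) {
  structure(tbl, frames = as.character(frames),
            class = c("expression_series", class(tibble::as_tibble(tbl))))
}

#' Build an expression series from a tibble
#'
#' @param tbl Data frame with a `node` column and one numeric column per
#'   frame.
#' @param frames Frame order; defaults to column order.
#' @return An `expression_series`.
#' @export
expression_series <- function(tbl, frames = NULL) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot("node" %in% names(tbl))
  if (anyDuplicated(tbl$node)) stop("duplicated node id", call. = FALSE)
  frames <- frames %||% setdiff(names(tbl), "node")
  new_expression_series(tbl[c("node", frames)], frames)
}

#' Frame labels of an expression series or temporal network
#' @param x An `expression_series` or [temporal_network()].
#' @return Character vector of ordered frame labels.
#' @export
frame_labels <- function(x) {
  if (is_temporal_network(x)) x$frames else attr(x, "frames")
}

#' Long (tidy) form of an expression series
#' @param x An `expression_series`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `frame`, `value`; `frame` keeps the
#'   series order as a factor.
#' @exportS3Method generics::tidy
tidy.expression_series <- function(x, ...) {
  frames <- attr(x, "frames")
  tibble::as_tibble(x) %>%
    tidyr::pivot_longer(-"node", names_to = "frame", values_to = "value") %>%
    dplyr::mutate(frame = factor(.data$frame, levels = frames)) %>%
    dplyr::arrange(.data$node, .data$frame)
}

#' Write a temporal network to disk
#'
#' Round-trip contract: reading the written file reproduces the node set
#' (minus isolated nodes for formats that cannot carry them) and the
#' per-frame edge sets exactly. Multi-frame networks can only be written to
#' the static formats if a `frame` is selected.
#'
#' @param net A [temporal_network()].
#' @param path Output path.
#' @param format One of `"edge_list"`, `"sif"`, `"dynamic_edge_list"`.
#' @param frame Frame to export for static formats (required when `net` has
#'   more than one frame).
#' @param default_relation Relation token for SIF rows lacking one.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "sif",
                                                "dynamic_edge_list"),
                          frame = NULL, default_relation = "interacts") {
  stopifnot(is_temporal_network(net))
  format <- match.arg(format)
  if (format %in% c("edge_list", "sif")) {
    if (length(net$frames) > 1 && is.null(frame)) {
      stop("multi-frame network: select a `frame` to write a static ",
           format, call. = FALSE)
    }
    ed <- frame_edges(net, frame %||% net$frames[1])
    lines <- switch(format,
      edge_list = paste(ed$source, ed$target, sep = "\t"),
      sif = paste(ed$source,
                  dplyr::coalesce(ed$relation, default_relation),
                  ed$target, sep = "\t")
    )
  } else {
    ed <- net$edges
    lines <- paste(ed$source, ed$target, ed$frame, sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write an expression series
#' @param expr An `expression_series`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(tibble::as_tibble(expr), path)
  invisible(path)
}
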