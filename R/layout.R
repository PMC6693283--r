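# Deterministic force-directed layout. A Fruchterman–Reingold-style spring
# model: attraction d^2/k along edges, repulsion k^2/d between all pairs,
# with a linearly cooling displacement cap. For an isolated connected pair
# the forces balance exactly at distance k, so `natural_length` is the
# equilibrium edge length before normalization. Final coordinates are
# min-max normalized to [0, 1] per axis (a degenerate axis maps to 0.5).

#' Force-directed 2D layout
#'
#' Computes one (x, y) position per network node for a chosen frame, by
#' iterating spring forces: attraction between connected nodes, repulsion
#' between every pair, with a cooling schedule. Deterministic: initial
#' positions are drawn from `seed` in canonical (sorted) node order, so the
#' same inputs and seed always give bitwise-identical positions and
#' reordering the node list does not change the result.
#'
#' @param net A [temporal_network()].
#' @param frame Frame whose edge set drives attraction; defaults to the
#'   first frame.
#' @param iterations Number of force iterations (default 300).
#' @param seed Integer seed for the initial placement.
#' @param natural_length Natural spring length `k` in pre-normalization
#'   units (default 0.3); an isolated connected pair equilibrates at this
#'   distance.
#' @param temperature Initial displacement cap (default `natural_length`),
#'   cooled linearly to ~0.
#' @return A layout tibble: `node`, `x`, `y`, with x and y in [0, 1].
#' @export
layout_force <- function(net, frame = NULL, iterations = 300, seed = 1,
                         natural_length = 0.3, temperature = NULL) {
  stopifnot(is_temporal_network(net))
  if (length(net$nodes) == 0) stop("empty node set", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  frame <- frame %||% net$frames[1]
  ed <- frame_edges(net, frame)
  ed <- ed[ed$source != ed$target, ]          # self-loops exert no force

  nodes <- sort(net$nodes)                    # canonical order for seeding
  n <- length(nodes)
  k <- natural_length
  temp0 <- temperature %||% k

  pos <- matrix(with_preserved_seed(seed, stats::runif(2 * n)),
                ncol = 2)                     # row i = node i, sorted order
  if (n == 1) {
    return(tibble::tibble(node = net$nodes, x = 0.5, y = 0.5))
  }

  src <- match(ed$source, nodes)
  tgt <- match(ed$target, nodes)

  for (it in seq_len(iterations)) {
    # repulsion: k^2 / d, all pairs
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    rep_f <- k^2 / d
    diag(rep_f) <- 0
    disp_x <- rowSums(dx / d * rep_f)
    disp_y <- rowSums(dy / d * rep_f)
    # attraction: d^2 / k along each edge
    if (length(src) > 0) {
      ex <- pos[src, 1] - pos[tgt, 1]
      ey <- pos[src, 2] - pos[tgt, 2]
      edist <- sqrt(ex^2 + ey^2)
      edist[edist < 1e-9] <- 1e-9
      att <- edist^2 / k
      fx <- ex / edist * att
      fy <- ey / edist * att
      disp_x <- disp_x - vec_accumulate(src, fx, n) + vec_accumulate(tgt, fx, n)
      disp_y <- disp_y - vec_accumulate(src, fy, n) + vec_accumulate(tgt, fy, n)
    }
    dl <- sqrt(disp_x^2 + disp_y^2)
    dl[dl < 1e-9] <- 1e-9
    temp <- temp0 * (1 - (it - 1) / iterations)
    step <- pmin(dl, temp)
    pos[, 1] <- pos[, 1] + disp_x / dl * step
    pos[, 2] <- pos[, 2] + disp_y / dl * step
  }

  out <- tibble::tibble(node = nodes,
                        x_raw = pos[, 1], y_raw = pos[, 2])
  out <- out[match(net$nodes, out$node), ]
  res <- tibble::tibble(
    node = out$node,
    x = normalize01(out$x_raw),
    y = normalize01(out$y_raw)
  )
  attr(res, "raw") <- tibble::tibble(node = out$node, x = out$x_raw,
                                     y = out$y_raw)
  res
}

vec_accumulate <- function(idx, val, n) {
  out <- numeric(n)
  acc <- tapply(val, idx, sum)
  out[as.integer(names(acc))] <- acc
  out
}

normalize01 <- function(v) {
  r <- range(v)
  if (diff(r) < 1e-12) return(rep(0.5, length(v)))
  (v - r[1]) / diff(r)
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% (.Machine$integer.max - 1)))
  expr
}

#' Extend a 2D layout to 3D
#'
#' Adds a z coordinate from the normalized x and y positions:
#' \deqn{z = 0.8\, y \sin(\pi y) + 0.8\, x \sin(\pi x)}
#' so the network sheet folds into a smooth dome (z = 0 on the unit-square
#' corners and edges midline, maximum 0.8 at the centre). x and y are
#' unchanged.
#'
#' @param pos A layout tibble from [layout_force()] with `x`, `y` in
#'   [0, 1].
#' @return The layout tibble with an added `z` column.
#' @export
#' @examples
#' extend_to_3d(tibble::tibble(node = "A", x = 0.5, y = 0.5))$z  # 0.8
extend_to_3d <- function(pos) {
  stopifnot(all(c("x", "y") %in% names(pos)))
  if (any(pos$x < 0 | pos$x > 1 | pos$y < 0 | pos$y > 1, na.rm = TRUE)) {
    stop("extend_to_3d() requires x and y normalized to [0, 1]",
         call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(pos),
                z = z_formula(.data$x, .data$y))
}

z_formula <- function(x, y) {
  0.8 * y * sin(y * pi) + 0.8 * x * sin(x * pi)
}

#' Write a layout as TSV
#' @param pos Layout tibble (`node`, `x`, `y`[, `z`]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(pos, path) {
  readr::write_tsv(tibble::as_tibble(pos), path)
  invisible(path)
}
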