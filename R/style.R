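# Expression -> colour and degree -> node size mapping. The colour domain
# is [-M, +M] with M = max |value| over the WHOLE series (all frames
# jointly), so that a dark red (strong downregulation) is exactly as far
# from neutral as a bright green/blue (strong upregulation), and colours are
# comparable across every frame of an animation.

NEUTRAL_RGB <- c(30L, 30L, 30L)   # near-black midpoint of the dark->bright ramp
MISSING_HEX <- "#808080"          # missing expression: neutral grey

#' Build a symmetric colour scale from an expression series
#'
#' The scale domain is `[-M, +M]` where `M` is the maximum absolute value
#' over all nodes and frames of the series; 0 maps to a near-black neutral,
#' `-M` to full red and `+M` to full green (or blue), linearly per RGB
#' channel. An all-zero series gives a degenerate scale under which every
#' value renders neutral.
#'
#' @param expr An `expression_series` (see [read_expression()]), or a
#'   numeric vector of values.
#' @param palette `"red_green"` (default) or `"red_blue"`.
#' @return A `colour_scale` object with fields `max_abs`, `domain`,
#'   `palette`.
#' @export
#' @examples
#' sc <- build_colour_scale(c(-1.2, 0.1, 3))
#' sc$domain  # -3 3
build_colour_scale <- function(expr, palette = c("red_green", "red_blue")) {
  palette <- match.arg(palette)
  vals <- if (is.numeric(expr)) expr else {
    unlist(tibble::as_tibble(expr)[frame_labels(expr)], use.names = FALSE)
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    stop("cannot build a colour scale from an all-missing series",
         call. = FALSE)
  }
  m <- max(abs(vals))
  structure(list(max_abs = m, domain = c(-m, m), palette = palette),
            class = "colour_scale")
}

#' @export
print.colour_scale <- function(x, ...) {
  cat(sprintf("<colour_scale %s> domain [%g, %g], neutral #%02x%02x%02x\n",
              x$palette, x$domain[1], x$domain[2],
              NEUTRAL_RGB[1], NEUTRAL_RGB[2], NEUTRAL_RGB[3]))
  invisible(x)
}

#' Map expression values to colours
#'
#' Linear interpolation per RGB channel: `-M` -> full red `(255,0,0)`,
#' `0` -> the neutral near-black midpoint, `+M` -> full green `(0,255,0)`
#' (or blue `(0,0,255)` for the red_blue palette). Values outside the
#' domain clamp to the endpoints; missing values map to neutral grey
#' `#808080`, distinct from the 0-value colour. Total function — never
#' errors on a value.
#'
#' @param scale A `colour_scale` from [build_colour_scale()].
#' @param v Numeric vector of expression values (NAs allowed).
#' @return Character vector of hex colours (`#rrggbb`), one per value.
#' @export
value_to_colour <- function(scale, v) {
  stopifnot(inherits(scale, "colour_scale"))
  rgb_mat <- value_to_rgb(scale, v)
  grDevices::rgb(rgb_mat[, 1], rgb_mat[, 2], rgb_mat[, 3],
                 maxColorValue = 255)
}

#' Map expression values to RGB triples
#'
#' @inheritParams value_to_colour
#' @return Integer matrix with one row per value and columns `r`, `g`, `b`
#'   in 0..255.
#' @export
value_to_rgb <- function(scale, v) {
  stopifnot(inherits(scale, "colour_scale"))
  m <- scale$max_abs
  pos_end <- if (scale$palette == "red_green") c(0, 255, 0) else c(0, 0, 255)
  neg_end <- c(255, 0, 0)
  out <- matrix(NA_integer_, nrow = length(v), ncol = 3,
                dimnames = list(NULL, c("r", "g", "b")))
  for (i in seq_along(v)) {
    x <- v[i]
    if (is.na(x)) {
      out[i, ] <- c(128L, 128L, 128L)
    } else if (m == 0) {
      out[i, ] <- NEUTRAL_RGB
    } else {
      t <- min(abs(x) / m, 1)                 # clamp outside the domain
      endpoint <- if (x < 0) neg_end else pos_end
      out[i, ] <- as.integer(round(NEUTRAL_RGB + t * (endpoint - NEUTRAL_RGB)))
    }
  }
  out
}

#' Node size rule
#'
#' @param mode `"fixed"`, or scale the radius by `"by_total"`,
#'   `"by_inner"` or `"by_outer"` degree.
#' @param min_radius,max_radius Radius range in display units (pixels of
#'   the rendered frame).
#' @return A `size_rule` object.
#' @export
size_rule <- function(mode = c("fixed", "by_total", "by_inner", "by_outer"),
                      min_radius = 4, max_radius = 16) {
  mode <- match.arg(mode)
  stopifnot(min_radius <= max_radius)
  structure(list(mode = mode, min_radius = min_radius,
                 max_radius = max_radius),
            class = "size_rule")
}

#' Map degrees to node radii
#'
#' Linear map from `[0, max_degree]` to `[min_radius, max_radius]`; the
#' fixed mode returns `min_radius` for every node. Radius is monotone
#' non-decreasing in the degree.
#'
#' @param rule A [size_rule()].
#' @param degree Non-negative integer vector of degrees.
#' @param max_degree Upper end of the degree domain; defaults to
#'   `max(degree)`. Pass the maximum over all frames to keep radii
#'   comparable across an animation.
#' @return Numeric vector of radii.
#' @export
degree_to_radius <- function(rule, degree, max_degree = NULL) {
  stopifnot(inherits(rule, "size_rule"))
  if (any(degree < 0)) stop("degrees must be non-negative", call. = FALSE)
  if (rule$mode == "fixed") return(rep(rule$min_radius, length(degree)))
  max_degree <- max_degree %||% max(degree, 0)
  if (max_degree == 0) return(rep(rule$min_radius, length(degree)))
  t <- pmin(degree / max_degree, 1)
  rule$min_radius + t * (rule$max_radius - rule$min_radius)
}

degree_column <- function(mode) {
  switch(mode, by_total = "total", by_inner = "inner", by_outer = "outer",
         fixed = NULL)
}
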