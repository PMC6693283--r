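# Frame-by-frame animation assembly and export. A frame bundles the node
# positions (fixed across frames by default, so the eye tracks colour and
# wiring changes, not node movement), per-frame node colours from the
# global expression colour scale, per-frame radii from the degree table,
# and the frame's active edge set.

#' Assemble an animation
#'
#' Builds one animation frame per series frame. Three modes fall out of the
#' inputs: node animation (static network + multi-frame expression:
#' constant edges, changing colours), edge animation (dynamic edges, no
#' expression: changing edges, uniform colour) and the combined mode (both
#' dynamic). Frame labels of a multi-frame network and a multi-frame
#' expression series must be reconcilable: identical, or mapped via
#' `frame_map`.
#'
#' @param net A [temporal_network()].
#' @param expr Optional `expression_series`; nodes without a value in a
#'   frame render neutral grey.
#' @param layout Optional layout tibble from [layout_force()]; computed
#'   with defaults when omitted. Positions are held fixed across frames
#'   unless `relayout_per_frame`.
#' @param scale Optional `colour_scale`; built from `expr` (over all
#'   frames jointly) when omitted.
#' @param rule A [size_rule()]; degree-based modes size nodes by their
#'   per-frame degree against the all-frame maximum.
#' @param frame_map Optional named character vector mapping expression
#'   frame labels to network frame labels.
#' @param uniform_colour Node colour when no expression is given.
#' @param drop_absent Drop nodes with no incident edge in a frame instead
#'   of drawing them greyed.
#' @param relayout_per_frame Recompute the layout for every frame from that
#'   frame's edges (same seed) instead of holding positions fixed.
#' @param seed Layout seed when `layout` is omitted.
#' @return An `animation`: list of `frames` (each with `frame`, `positions`,
#'   `colours`, `radii`, `edges`, `degrees`) plus a `cursor` starting at 1.
#' @export
build_animation <- function(net, expr = NULL, layout = NULL, scale = NULL,
                            rule = size_rule(), frame_map = NULL,
                            uniform_colour = "#4682B4",
                            drop_absent = FALSE,
                            relayout_per_frame = FALSE, seed = 1) {
  stopifnot(is_temporal_network(net))
  net_frames <- net$frames
  expr_frames <- if (!is.null(expr)) frame_labels(expr) else NULL

  if (!is.null(expr_frames) && !is.null(frame_map)) {
    expr_frames_mapped <- unname(frame_map[expr_frames])
  } else {
    expr_frames_mapped <- expr_frames
  }

  if (is.null(expr_frames)) {
    frames <- net_frames
  } else if (length(net_frames) == 1) {
    frames <- expr_frames                       # static net, animated colours
  } else {
    if (!setequal(expr_frames_mapped, net_frames)) {
      stop("irreconcilable frame labels.\n  network:    ",
           paste(net_frames, collapse = ", "), "\n  expression: ",
           paste(expr_frames, collapse = ", "), call. = FALSE)
    }
    frames <- net_frames
  }

  if (is.null(scale) && !is.null(expr)) scale <- build_colour_scale(expr)
  if (is.null(layout)) layout <- layout_force(net, seed = seed)

  deg_all <- degree_over_time(net)
  deg_col <- degree_column(rule$mode)
  max_deg <- if (!is.null(deg_col)) max(deg_all[[deg_col]], 0) else 0

  expr_tbl <- if (!is.null(expr)) tibble::as_tibble(expr) else NULL

  frame_objs <- lapply(frames, function(f) {
    net_f <- if (f %in% net_frames) f else net_frames[1]
    ed <- frame_edges(net, net_f)
    deg <- degree_table(net, net_f)

    nodes <- net$nodes
    active <- unique(c(ed$source, ed$target))
    if (drop_absent) nodes <- nodes[nodes %in% active]

    if (!is.null(expr_tbl)) {
      expr_f <- if (!is.null(frame_map)) {
        names(frame_map)[match(f, frame_map)] %||% f
      } else f
      vals <- expr_tbl[[expr_f]][match(nodes, expr_tbl$node)]
      cols <- value_to_colour(scale, vals)
    } else {
      cols <- rep(uniform_colour, length(nodes))
      cols[!nodes %in% active] <- MISSING_HEX    # greyed, still drawn
    }

    radii <- if (is.null(deg_col)) {
      rep(rule$min_radius, length(nodes))
    } else {
      degree_to_radius(rule, deg[[deg_col]][match(nodes, deg$node)], max_deg)
    }

    list(frame = f,
         positions = layout[match(nodes, layout$node), , drop = FALSE],
         colours = stats::setNames(cols, nodes),
         radii = stats::setNames(radii, nodes),
         edges = ed,
         degrees = deg[deg$node %in% nodes, ])
  })

  structure(list(frames = frame_objs, cursor = 1L, directed = net$directed,
                 scale = scale),
            class = "animation")
}

#' @export
print.animation <- function(x, ...) {
  cat(sprintf("<animation> %d frames (%s), cursor at %d\n",
              length(x$frames),
              paste(vapply(x$frames, `[[`, "", "frame"), collapse = ", "),
              x$cursor))
  invisible(x)
}

#' Step an animation forward or backward
#'
#' Moves the cursor one frame, clamped at the ends (stepping forward past
#' the last frame stays on the last frame).
#'
#' @param anim An `animation`.
#' @param direction `"forward"` or `"backward"`.
#' @return The animation with the cursor moved; read the current frame
#'   with [anim_current()].
#' @export
anim_step <- function(anim, direction = c("forward", "backward")) {
  stopifnot(inherits(anim, "animation"), length(anim$frames) > 0)
  direction <- match.arg(direction)
  delta <- if (direction == "forward") 1L else -1L
  anim$cursor <- min(max(anim$cursor + delta, 1L), length(anim$frames))
  anim
}

#' Current frame of an animation
#' @param anim An `animation`.
#' @return The frame under the cursor.
#' @export
anim_current <- function(anim) {
  stopifnot(inherits(anim, "animation"))
  anim$frames[[anim$cursor]]
}

# ---- rendering -----------------------------------------------------------

render_frame_device <- function(frame, directed, width, height, title) {
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(-0.05, 1.05), ylim = c(-0.05, 1.05),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = title, cex.main = 0.9)
  pos <- frame$positions
  ed <- frame$edges
  if (nrow(ed) > 0) {
    i <- match(ed$source, pos$node); j <- match(ed$target, pos$node)
    ok <- !is.na(i) & !is.na(j)
    if (any(ok)) {
      graphics::segments(pos$x[i[ok]], pos$y[i[ok]],
                         pos$x[j[ok]], pos$y[j[ok]],
                         col = "grey60", lwd = 0.8)
      if (directed) {
        graphics::arrows(pos$x[i[ok]], pos$y[i[ok]],
                         pos$x[j[ok]], pos$y[j[ok]],
                         length = 0.05, angle = 18, col = "grey60",
                         lwd = 0.5)
      }
    }
  }
  cex <- frame$radii[pos$node] / 4
  graphics::points(pos$x, pos$y, pch = 21,
                   bg = frame$colours[pos$node],
                   col = "grey30", cex = pmax(cex, 0.6))
  if (length(pos$node) <= 60) {
    graphics::text(pos$x, pos$y, pos$node, pos = 3, cex = 0.55,
                   offset = 0.35)
  }
}

render_frame_png <- function(frame, directed, path, width, height) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  render_frame_device(frame, directed, width, height, frame$frame)
  invisible(path)
}

# hand-written single-frame SVG: deterministic text artefact
render_frame_svg <- function(frame, directed, path, width, height) {
  pos <- frame$positions
  sx <- function(x) round(20 + x * (width - 40), 2)
  sy <- function(y) round(height - 20 - y * (height - 40), 2)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    sprintf('<rect width="%d" height="%d" fill="white"/>', width, height),
    sprintf('<text x="10" y="14" font-size="12" font-family="sans-serif">%s</text>',
            frame$frame))
  ed <- frame$edges
  if (nrow(ed) > 0) {
    i <- match(ed$source, pos$node); j <- match(ed$target, pos$node)
    ok <- which(!is.na(i) & !is.na(j))
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="1"/>',
      sx(pos$x[i[ok]]), sy(pos$y[i[ok]]), sx(pos$x[j[ok]]), sy(pos$y[j[ok]])))
  }
  lines <- c(lines, sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333"/>',
    sx(pos$x), sy(pos$y), round(unname(frame$radii[pos$node]), 2),
    unname(frame$colours[pos$node])))
  lines <- c(lines, sprintf(
    '<text x="%s" y="%s" font-size="9" font-family="sans-serif" text-anchor="middle">%s</text>',
    sx(pos$x), sy(pos$y) - unname(frame$radii[pos$node]) - 2, pos$node))
  lines <- c(lines, "</svg>")
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- export --------------------------------------------------------------

#' Export an animation
#'
#' Formats: `gif` (animated, configurable frame duration), `png_sequence`
#' (files `frame_001.png` ... in a directory), `html` (one self-contained
#' page embedding the frame data with forward/backward step controls,
#' opening on frame 1) and `svg` (the current cursor frame as a
#' single vector image). Every format carries exactly as many frames as
#' the animation.
#'
#' @param anim An `animation`.
#' @param path Output file (`gif`, `html`, `svg`) or directory
#'   (`png_sequence`).
#' @param format One of `"gif"`, `"png_sequence"`, `"html"`, `"svg"`.
#' @param delay_ms Frame duration in milliseconds for GIF (default 1000).
#' @param width,height Pixel dimensions of rendered frames.
#' @return `path`, invisibly. For `png_sequence`, the vector of written
#'   files.
#' @export
export_animation <- function(anim, path,
                             format = c("gif", "png_sequence", "html", "svg"),
                             delay_ms = 1000, width = 480, height = 480) {
  stopifnot(inherits(anim, "animation"))
  format <- match.arg(format)
  n <- length(anim$frames)
  switch(format,
    gif = {
      imgs <- vector("list", n)
      for (i in seq_len(n)) {
        tmp <- tempfile(fileext = ".png")
        render_frame_png(anim$frames[[i]], anim$directed, tmp, width, height)
        imgs[[i]] <- png::readPNG(tmp)
        unlink(tmp)
      }
      write_gif(imgs, path, delay_cs = max(1L, round(delay_ms / 10)))
      invisible(path)
    },
    png_sequence = {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      files <- file.path(path, sprintf("frame_%03d.png", seq_len(n)))
      for (i in seq_len(n)) {
        render_frame_png(anim$frames[[i]], anim$directed, files[i],
                         width, height)
      }
      invisible(files)
    },
    html = {
      export_animation_html(anim, path, delay_ms, width, height)
      invisible(path)
    },
    svg = {
      render_frame_svg(anim_current(anim), anim$directed, path, width,
                       height)
      invisible(path)
    }
  )
}

animation_frame_json <- function(anim) {
  frames <- lapply(anim$frames, function(fr) {
    pos <- fr$positions
    list(
      frame = fr$frame,
      nodes = lapply(seq_len(nrow(pos)), function(i) {
        nd <- pos$node[i]
        list(id = nd, x = pos$x[i], y = pos$y[i],
             colour = unname(fr$colours[nd]),
             r = unname(fr$radii[nd]))
      }),
      edges = lapply(seq_len(nrow(fr$edges)), function(i) {
        list(source = fr$edges$source[i], target = fr$edges$target[i])
      })
    )
  })
  jsonlite::toJSON(frames, auto_unbox = TRUE, digits = 6)
}

export_animation_html <- function(anim, path, delay_ms, width, height) {
  json <- animation_frame_json(anim)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>network animation</title></head>",
    "<body>",
    sprintf("<canvas id=\"cv\" width=\"%d\" height=\"%d\" style=\"border:1px solid #ccc\"></canvas>", width, height),
    "<div>",
    "<button id=\"back\">&#9664; back</button>",
    "<span id=\"label\"></span>",
    "<button id=\"fwd\">forward &#9654;</button>",
    "</div>",
    "<script>",
    paste0("var frames = ", json, ";"),
    sprintf("var W = %d, H = %d, cur = 0;", width, height),
    "var ctx = document.getElementById('cv').getContext('2d');",
    "function sx(x){return 20 + x*(W-40);} function sy(y){return H-20 - y*(H-40);}",
    "function draw(){",
    "  var f = frames[cur];",
    "  ctx.clearRect(0,0,W,H);",
    "  var pos = {};",
    "  f.nodes.forEach(function(n){pos[n.id] = n;});",
    "  ctx.strokeStyle = '#999';",
    "  f.edges.forEach(function(e){",
    "    var a = pos[e.source], b = pos[e.target];",
    "    if(!a || !b) return;",
    "    ctx.beginPath(); ctx.moveTo(sx(a.x), sy(a.y)); ctx.lineTo(sx(b.x), sy(b.y)); ctx.stroke();",
    "  });",
    "  f.nodes.forEach(function(n){",
    "    ctx.beginPath(); ctx.fillStyle = n.colour;",
    "    ctx.arc(sx(n.x), sy(n.y), n.r, 0, 2*Math.PI); ctx.fill();",
    "  });",
    "  document.getElementById('label').textContent = ' frame ' + (cur+1) + '/' + frames.length + ': ' + f.frame + ' ';",
    "}",
    "document.getElementById('fwd').onclick = function(){cur = Math.min(cur+1, frames.length-1); draw();};",
    "document.getElementById('back').onclick = function(){cur = Math.max(cur-1, 0); draw();};",
    "draw();",
    "</script>",
    "</body></html>"
  )
  readr::write_lines(html, path)
  invisible(path)
}

# ---- line graph ----------------------------------------------------------

#' Expression line graph for a node selection
#'
#' The static companion of the animation: one line per selected node over
#' the ordered frames (x axis = frame labels such as `T2_D200`), typically
#' for a first-degree neighbourhood. Writes the figure and, alongside it,
#' the underlying tidy table (`node`, `frame`, `value`) as TSV.
#'
#' @param expr An `expression_series`.
#' @param node_ids Nodes to plot; ids missing from the series are warned
#'   about and skipped. All-unknown is an error.
#' @param path Output figure path (`.png` or `.svg`); the tidy table goes
#'   to the same path with extension `.tsv`. `NULL` skips writing.
#' @param width,height Figure size in pixels.
#' @return Invisibly, a list with `plot` (ggplot), `data` (tidy tibble) and
#'   `paths` (written files).
#' @export
line_graph <- function(expr, node_ids, path = NULL, width = 640,
                       height = 480) {
  known <- intersect(node_ids, expr$node)
  unknown <- setdiff(node_ids, expr$node)
  if (length(unknown) > 0) {
    warning("skipping nodes absent from the expression series: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(known) == 0) {
    stop("none of the requested nodes are in the expression series",
         call. = FALSE)
  }
  tidy_tbl <- tidy.expression_series(expr) %>%
    dplyr::filter(.data$node %in% known)
  p <- ggplot2::ggplot(tidy_tbl,
                       ggplot2::aes(x = .data$frame, y = .data$value,
                                    colour = .data$node,
                                    group = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "frame", y = "expression", colour = "node") +
    ggplot2::theme_minimal()
  paths <- character()
  if (!is.null(path)) {
    dev <- if (grepl("\\.svg$", path)) grDevices::svg else {
      function(filename, width, height) {
        grDevices::png(filename, width = width * 96, height = height * 96,
                       res = 96, type = "cairo")
      }
    }
    dev(path, width = width / 96, height = height / 96)
    print(p)
    grDevices::dev.off()
    tsv <- sub("\\.[a-zA-Z]+$", ".tsv", path)
    readr::write_tsv(tidy_tbl %>%
                       dplyr::mutate(frame = as.character(.data$frame)), tsv)
    paths <- c(path, tsv)
  }
  invisible(list(plot = p, data = tidy_tbl, paths = paths))
}

# ---- autoplot ------------------------------------------------------------

#' Plot a single network frame
#'
#' ggplot2 rendering of one frame: edges as segments, nodes coloured by
#' expression (if given) and sized by degree.
#'
#' @param object A [temporal_network()].
#' @param frame Frame to draw; defaults to the first.
#' @param layout Optional layout tibble; computed when omitted.
#' @param expr Optional `expression_series` for node colours.
#' @param rule A [size_rule()].
#' @param seed Layout seed when `layout` is omitted.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.temporal_network <- function(object, frame = NULL, layout = NULL,
                                      expr = NULL, rule = size_rule(),
                                      seed = 1, ...) {
  anim <- build_animation(object, expr = expr, layout = layout, rule = rule,
                          seed = seed)
  anim_labels <- vapply(anim$frames, `[[`, "", "frame")
  frame <- frame %||% anim_labels[1]
  if (!frame %in% anim_labels) {
    stop("unknown frame: '", frame, "' (frames: ",
         paste(anim_labels, collapse = ", "), ")", call. = FALSE)
  }
  fr <- anim$frames[[match(frame, anim_labels)]]
  pos <- fr$positions
  ed <- fr$edges
  seg <- tibble::tibble(
    x = pos$x[match(ed$source, pos$node)],
    y = pos$y[match(ed$source, pos$node)],
    xend = pos$x[match(ed$target, pos$node)],
    yend = pos$y[match(ed$target, pos$node)]
  )
  nodes <- tibble::tibble(node = pos$node, x = pos$x, y = pos$y,
                          colour = unname(fr$colours[pos$node]),
                          r = unname(fr$radii[pos$node]))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$r),
                        colour = nodes$colour) +
    ggplot2::scale_size_identity() +
    ggplot2::labs(title = frame) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
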