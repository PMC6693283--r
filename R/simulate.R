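# Synthetic temporal-network fixtures. The generator emulates the shape of
# real exposure studies: a focal hub gene whose interaction count grows
# over the exposure frames and partially persists after a washout frame
# (with a split into regulators and targets), a background of randomly
# rewiring edges, planted node-expression trajectories (a strong
# downregulation at a middle frame, a strong upregulation), and miniature
# annotation tables. Every planted quantity is recorded in a ground-truth
# list/JSON so analysis pipelines can be checked for exact recovery.

#' Fixture specification
#'
#' Defaults encode the package's reference study conditions: four frames
#' (three exposure days and a washout), a hub connected to 10 neighbours on
#' day 1 (inner 7, outer 3) growing to 71 interactions by day 3 (inner 49,
#' outer 22) and keeping exactly 50 of them (inner 35, outer 15) after
#' washout, on a background of 120 genes with slowly rewiring random edges.
#'
#' @param n_nodes Number of background genes (hub excluded).
#' @param frames Ordered frame labels.
#' @param hub_node Focal hub id.
#' @param hub_inner,hub_outer Per-frame counts of edges into / out of the
#'   hub.
#' @param retain_inner,retain_outer Per-frame number of the previous
#'   frame's hub edges kept (first element `NA`); the remainder are new
#'   partners, so persistence counts between consecutive frames are exactly
#'   `retain_inner + retain_outer`.
#' @param edge_p Background edge density on frame 1.
#' @param edge_birth,edge_death Per-frame background edge birth/death
#'   probabilities.
#' @param planted_expression Named list: node id -> numeric trajectory of
#'   length `length(frames)`. Planted values are written exactly; all other
#'   nodes get noise clamped inside the planted extremes, so the series
#'   maximum absolute value is the planted one.
#' @param noise_sd Standard deviation of background expression noise
#'   (clamped to [-1, 1]).
#' @param seed Seed governing all randomness of the fixture.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_nodes = 120,
                         frames = c("day1", "day2", "day3", "washout"),
                         hub_node = "HUB1",
                         hub_inner = c(7, 28, 49, 35),
                         hub_outer = c(3, 12, 22, 15),
                         retain_inner = c(NA, 7, 28, 35),
                         retain_outer = c(NA, 3, 12, 15),
                         edge_p = 0.02, edge_birth = 0.01,
                         edge_death = 0.2,
                         planted_expression = list(
                           DOWN1 = c(0.1, -1.2, -0.4, -0.1),
                           UP1 = c(-0.2, 0.5, 1.8, 0.6)
                         ),
                         noise_sd = 0.4, seed = 1) {
  nf <- length(frames)
  stopifnot(length(hub_inner) == nf, length(hub_outer) == nf,
            length(retain_inner) == nf, length(retain_outer) == nf)
  if (any(c(edge_p, edge_birth, edge_death) < 0) ||
      any(c(edge_p, edge_birth, edge_death) > 1)) {
    stop("edge probabilities must be in [0, 1]", call. = FALSE)
  }
  for (nm in names(planted_expression)) {
    if (length(planted_expression[[nm]]) != nf) {
      stop("planted trajectory for ", nm, " must have one value per frame",
           call. = FALSE)
    }
  }
  ri <- retain_inner[-1]; ro <- retain_outer[-1]
  if (any(ri > hub_inner[-nf] | ri > hub_inner[-1], na.rm = TRUE) ||
      any(ro > hub_outer[-nf] | ro > hub_outer[-1], na.rm = TRUE)) {
    stop("retain counts cannot exceed the hub counts of either frame",
         call. = FALSE)
  }
  # every frame needs enough distinct partners; new partners are never
  # recycled, so the total draw must fit in the background node pool
  need <- sum(hub_inner - c(0, retain_inner[-1])) +
    sum(hub_outer - c(0, retain_outer[-1]))
  if (need > n_nodes) {
    stop(sprintf("hub needs %d distinct partners but only %d nodes exist",
                 need, n_nodes), call. = FALSE)
  }
  structure(list(n_nodes = n_nodes, frames = frames, hub_node = hub_node,
                 hub_inner = hub_inner, hub_outer = hub_outer,
                 retain_inner = retain_inner, retain_outer = retain_outer,
                 edge_p = edge_p, edge_birth = edge_birth,
                 edge_death = edge_death,
                 planted_expression = planted_expression,
                 noise_sd = noise_sd, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic temporal network, expression series and truth
#'
#' @param spec A [fixture_spec()].
#' @return List with `net` (a [temporal_network()]), `expr` (an
#'   `expression_series`), `store` (a miniature `annotation_store`) and
#'   `truth` (planted quantities: hub degree trajectory, per-transition
#'   persistence counts, planted trajectories, expression max-abs).
#' @export
simulate_temporal_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, simulate_impl(spec))
}

simulate_impl <- function(spec) {
  nf <- length(spec$frames)
  genes <- sprintf("G%03d", seq_len(spec$n_nodes))
  hub <- spec$hub_node
  planted_nodes <- names(spec$planted_expression)
  # planted expression nodes ride on background gene ids
  stopifnot(length(planted_nodes) <= spec$n_nodes)
  id_map <- stats::setNames(genes[seq_along(planted_nodes)], planted_nodes)

  # --- hub edge schedule -------------------------------------------------
  pool <- sample(genes)                    # draw order for new partners
  take <- local({
    i <- 0L
    function(k) {
      if (k == 0) return(character())
      out <- pool[(i + 1):(i + k)]
      i <<- i + k
      out
    }
  })
  in_sets <- out_sets <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (f == 1) {
      in_sets[[f]] <- take(spec$hub_inner[1])
      out_sets[[f]] <- take(spec$hub_outer[1])
    } else {
      keep_in <- sample(in_sets[[f - 1]], spec$retain_inner[f])
      keep_out <- sample(out_sets[[f - 1]], spec$retain_outer[f])
      in_sets[[f]] <- c(keep_in, take(spec$hub_inner[f] -
                                        spec$retain_inner[f]))
      out_sets[[f]] <- c(keep_out, take(spec$hub_outer[f] -
                                          spec$retain_outer[f]))
    }
  }
  hub_edges <- purrr::map_dfr(seq_len(nf), function(f) {
    tibble::tibble(
      source = c(in_sets[[f]], rep(hub, length(out_sets[[f]]))),
      target = c(rep(hub, length(in_sets[[f]])), out_sets[[f]]),
      frame = spec$frames[f]
    )
  })

  # --- background edges (hub excluded), birth/death process --------------
  bg_pairs <- expand.grid(source = genes, target = genes,
                          stringsAsFactors = FALSE)
  bg_pairs <- bg_pairs[bg_pairs$source != bg_pairs$target, ]
  alive <- stats::runif(nrow(bg_pairs)) < spec$edge_p
  bg_edges <- list()
  for (f in seq_len(nf)) {
    if (f > 1) {
      die <- stats::runif(nrow(bg_pairs)) < spec$edge_death
      born <- stats::runif(nrow(bg_pairs)) < spec$edge_birth
      alive <- (alive & !die) | (!alive & born)
    }
    bg_edges[[f]] <- tibble::tibble(source = bg_pairs$source[alive],
                                    target = bg_pairs$target[alive],
                                    frame = spec$frames[f])
  }
  edges <- dplyr::bind_rows(hub_edges, dplyr::bind_rows(bg_edges))
  net <- temporal_network(edges, nodes = c(hub, genes), directed = TRUE,
                          frames = spec$frames)

  # --- expression --------------------------------------------------------
  planted_abs <- if (length(spec$planted_expression) > 0) {
    max(abs(unlist(spec$planted_expression)))
  } else 1
  all_nodes <- c(hub, genes)
  mat <- matrix(pmax(pmin(stats::rnorm(length(all_nodes) * nf, 0,
                                       spec$noise_sd), 1), -1),
                nrow = length(all_nodes))
  mat <- round(mat, 4)
  rownames(mat) <- all_nodes
  for (nm in planted_nodes) {
    mat[id_map[[nm]], ] <- spec$planted_expression[[nm]]
  }
  expr_tbl <- tibble::as_tibble(as.data.frame(mat))
  names(expr_tbl) <- spec$frames
  expr <- expression_series(dplyr::bind_cols(tibble::tibble(node = all_nodes),
                                             expr_tbl), spec$frames)

  # --- annotations -------------------------------------------------------
  pathways <- sprintf("Pathway_%02d", 1:12)
  diseases <- sprintf("Disease_%02d", 1:5)
  n_pw <- stats::rbinom(length(all_nodes), 3, 0.5)
  pw_rows <- purrr::map_dfr(seq_along(all_nodes), function(i) {
    if (n_pw[i] == 0) return(NULL)
    tibble::tibble(symbol = all_nodes[i],
                   pathway = sample(pathways, n_pw[i]))
  })
  ds_rows <- purrr::map_dfr(seq_along(all_nodes), function(i) {
    if (stats::runif(1) < 0.2) {
      tibble::tibble(symbol = all_nodes[i], disease = sample(diseases, 1))
    } else NULL
  })
  info <- tibble::tibble(
    symbol = all_nodes,
    entrez = as.character(seq_along(all_nodes) + 1000L),
    synonyms = paste0(all_nodes, "_ALT"),
    gene_type = "protein-coding"
  )
  store <- annotation_store("Homo sapiens", gene_info = info,
                            gene_pathways = pw_rows,
                            gene_diseases = ds_rows)

  truth <- list(
    seed = spec$seed,
    hub_node = hub,
    frames = spec$frames,
    hub_inner = spec$hub_inner,
    hub_outer = spec$hub_outer,
    hub_total = spec$hub_inner + spec$hub_outer,
    hub_persistent = spec$retain_inner + spec$retain_outer,  # vs previous frame
    planted_expression = stats::setNames(
      spec$planted_expression,
      unname(id_map[planted_nodes])),
    expression_max_abs = if (length(planted_nodes) > 0) planted_abs else
      max(abs(mat))
  )
  list(net = net, expr = expr, store = store, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Materializes [simulate_temporal_network()] in the exact dialects the
#' readers consume: a static edge list and SIF file (frame 1), the
#' long-format dynamic edge table, the expression table, the three
#' annotation TSVs and a `ground_truth.json` with every planted quantity.
#' Byte-identical across runs for the same spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths, with the
#'   generated objects in attribute `"objects"`.
#' @export
simulate_fixture <- function(spec, dir) {
  sim <- simulate_temporal_network(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    edge_list = file.path(dir, "network_edgelist.tsv"),
    sif = file.path(dir, "network.sif"),
    dynamic_edges = file.path(dir, "dynamic_edges.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gene_info = file.path(dir, "gene_info.tsv"),
    gene_pathway = file.path(dir, "gene_pathway.tsv"),
    gene_disease = file.path(dir, "gene_disease.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_network(sim$net, paths[["edge_list"]], "edge_list",
                frame = sim$net$frames[1])
  write_network(sim$net, paths[["sif"]], "sif", frame = sim$net$frames[1])
  write_network(sim$net, paths[["dynamic_edges"]], "dynamic_edge_list")
  write_expression(sim$expr, paths[["expression"]])
  readr::write_tsv(sim$store$gene_info, paths[["gene_info"]],
                   col_names = FALSE)
  readr::write_lines(paste(sim$store$gene_pathways$symbol,
                           sim$store$gene_pathways$pathway, sep = "\t"),
                     paths[["gene_pathway"]])
  readr::write_lines(paste(sim$store$gene_diseases$symbol,
                           sim$store$gene_diseases$disease, sep = "\t"),
                     paths[["gene_disease"]])
  jsonlite::write_json(sim$truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- paths
  attr(out, "objects") <- sim
  invisible(out)
}
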