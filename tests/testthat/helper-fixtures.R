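# Test fixtures built in code, plus independent brute-force oracles that
# stay deliberately naive (straight loops over edge rows).

# Erdos-Renyi style random digraph as a single-frame temporal network
random_digraph <- function(n, p, seed, directed = TRUE) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  temporal_network(pairs[keep, ], nodes = ids, directed = directed)
}

# random multi-frame network: independent random edge sets per frame
random_temporal_net <- function(n, p, frames, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  edges <- do.call(rbind, lapply(frames, function(f) {
    pairs <- expand.grid(source = ids, target = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < p, ]
    if (nrow(pairs) == 0) pairs <- data.frame(source = ids[1],
                                              target = ids[2])
    pairs$frame <- f
    pairs
  }))
  temporal_network(edges, nodes = ids, frames = frames)
}

# O(V*E) edge-scan degree oracle, independent of degree_table()
oracle_degrees <- function(net, frame) {
  ed <- net$edges[net$edges$frame == frame, ]
  out <- data.frame(node = net$nodes, inner = 0L, outer = 0L)
  for (v in seq_along(net$nodes)) {
    id <- net$nodes[v]
    for (e in seq_len(nrow(ed))) {
      if (ed$target[e] == id) out$inner[v] <- out$inner[v] + 1L
      if (ed$source[e] == id) out$outer[v] <- out$outer[v] + 1L
    }
  }
  out$total <- out$inner + out$outer
  out
}

sniff_rows <- function(path) tempnet:::sniff_raw_table(path)

# small edge-list network used across files
tri_net <- function() {
  temporal_network(data.frame(source = c("A", "A", "B"),
                              target = c("B", "C", "C")))
}

# tiny annotation store: g1 -> P1; g2 -> P1, P2
tiny_store <- function() {
  annotation_store(
    "Homo sapiens",
    gene_info = data.frame(symbol = c("g1", "g2"),
                           entrez = c("11", "22"),
                           synonyms = c("G1A|G1B", "G2A"),
                           gene_type = "protein-coding"),
    gene_pathways = data.frame(symbol = c("g1", "g2", "g2"),
                               pathway = c("P1", "P1", "P2")),
    gene_diseases = data.frame(symbol = "g1", disease = "D1")
  )
}

expr_3frame <- function() {
  expression_series(data.frame(
    node = c("A", "B", "C"),
    T2 = c(0.1, -0.5, 0.3),
    T8 = c(-1.2, 0.2, 0.4),
    T24 = c(-0.4, 0.9, -0.1)
  ))
}
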