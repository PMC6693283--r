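test_that("degree decomposition follows the in/out definition", {
  net <- tri_net()  # A->B, A->C, B->C
  deg <- degree_table(net, "static")
  g <- function(n, col) deg[[col]][deg$node == n]
  expect_equal(g("C", "inner"), 2)
  expect_equal(g("C", "outer"), 0)
  expect_equal(g("C", "total"), 2)
  expect_equal(g("A", "outer"), 2)
  expect_equal(g("A", "inner"), 0)
  expect_equal(g("B", "total"), 2)
})

test_that("a self-loop adds one inner and one outer degree", {
  net <- temporal_network(data.frame(source = c("A", "A"),
                                     target = c("A", "B")))
  deg <- degree_table(net, "static")
  a <- deg[deg$node == "A", ]
  expect_equal(a$inner, 1)
  expect_equal(a$outer, 2)
  expect_equal(a$total, 3)
})

test_that("an empty frame yields all-zero degrees", {
  net <- temporal_network(data.frame(source = "A", target = "B",
                                     frame = "f1"),
                          nodes = c("A", "B", "C"),
                          frames = c("f1", "f2"))
  # f2 declared but holds no edges
  deg <- degree_table(net, "f2")
  expect_true(all(deg$total == 0))
  expect_error(degree_table(net, "nope"), "unknown frame")
})

test_that("undirected degrees collapse to incident edge counts", {
  net <- temporal_network(data.frame(source = c("A", "B", "C"),
                                     target = c("B", "C", "C")),
                          directed = FALSE)
  deg <- degree_table(net, "static")
  expect_equal(deg$inner, deg$outer)
  expect_equal(deg$inner, deg$total)
  expect_equal(deg$total[deg$node == "B"], 2)
  expect_equal(deg$total[deg$node == "C"], 2)  # self-loop = one incident edge
})

test_that("degrees agree with the edge-scan oracle on random digraphs", {
  for (seed in 1:20) {
    net <- random_digraph(30, 0.2, seed)
    deg <- degree_table(net, "static")
    orc <- oracle_degrees(net, "static")
    expect_equal(deg$inner, orc$inner, info = paste("seed", seed))
    expect_equal(deg$outer, orc$outer, info = paste("seed", seed))
    expect_equal(deg$total, orc$total, info = paste("seed", seed))
    # directed degree identity and handshake
    expect_equal(deg$total, deg$inner + deg$outer)
    expect_equal(sum(deg$inner), nrow(net$edges))
    expect_equal(sum(deg$outer), nrow(net$edges))
  }
})

test_that("degree_over_time tracks per-frame changes", {
  net <- temporal_network(
    data.frame(source = "A", target = "B", frame = "f2"),
    nodes = c("A", "B"), frames = c("f1", "f2"))
  dot <- degree_over_time(net)
  a <- dot[dot$node == "A", ]
  expect_equal(a$total[a$frame == "f1"], 0)
  expect_equal(a$total[a$frame == "f2"], 1)

  stat <- tri_net()
  expect_equal(degree_over_time(stat), degree_table(stat, "static"))
})

test_that("a planted hub's degree grows monotonically with its spokes", {
  frames <- c("f1", "f2", "f3")
  spokes <- c(2, 5, 9)
  edges <- do.call(rbind, lapply(seq_along(frames), function(i) {
    data.frame(source = "HUB", target = sprintf("s%02d", 1:spokes[i]),
               frame = frames[i])
  }))
  net <- temporal_network(edges, frames = frames)
  hub <- dplyr::filter(degree_over_time(net), node == "HUB")
  expect_equal(hub$total, spokes)
  expect_true(all(diff(hub$total) > 0))
})

test_that("filter_by_degree applies the threshold rule", {
  net <- tri_net()
  expect_setequal(filter_by_degree(net, "static", 0)$nodes, net$nodes)

  # every node has total degree 2 here, so the threshold keeps them all
  expect_setequal(filter_by_degree(net, "static", 2, "total")$nodes,
                  c("A", "B", "C"))
  # on inner degree only C (regulated by A and B) survives; no edge has
  # both endpoints retained
  sub <- filter_by_degree(net, "static", 2, "inner")
  expect_identical(sub$nodes, "C")
  expect_equal(nrow(sub$edges), 0)
  # on outer degree only A (regulates B and C) survives
  expect_identical(filter_by_degree(net, "static", 2, "outer")$nodes, "A")

  expect_equal(length(filter_by_degree(net, "static", 99)$nodes), 0)
  expect_error(filter_by_degree(net, "static", -1), "non-negative")
})

test_that("raising the threshold never adds nodes", {
  net <- random_digraph(25, 0.15, seed = 11)
  prev <- filter_by_degree(net, "static", 0)$nodes
  for (th in 1:6) {
    cur <- filter_by_degree(net, "static", th)$nodes
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("first-degree neighbourhoods keep both directions", {
  net <- temporal_network(data.frame(source = c("A", "B", "C"),
                                     target = c("B", "C", "D")))
  nb <- first_degree_neighbourhood(net, "B", "static")
  expect_setequal(nb$nodes, c("A", "B", "C"))
  expect_equal(nrow(nb$edges), 2)   # A->B and B->C; C->D excluded
  expect_identical(nb$focal, "B")

  iso <- temporal_network(data.frame(source = "X", target = "Y"),
                          nodes = c("X", "Y", "Z"))
  solo <- first_degree_neighbourhood(iso, "Z", "static")
  expect_identical(solo$nodes, "Z")
  expect_equal(nrow(solo$edges), 0)

  expect_error(first_degree_neighbourhood(net, "NOPE", "static"),
               "unknown node")
})

test_that("neighbourhoods contain the focus and only parent edges", {
  for (seed in 1:10) {
    net <- random_digraph(20, 0.15, seed)
    v <- sample(net$nodes, 1)
    nb <- first_degree_neighbourhood(net, v, "static")
    expect_true(v %in% nb$nodes)
    parent_keys <- paste(net$edges$source, net$edges$target)
    expect_true(all(paste(nb$edges$source, nb$edges$target) %in% parent_keys))
    expect_true(all(nb$edges$source %in% nb$nodes))
    expect_true(all(nb$edges$target %in% nb$nodes))
  }
})

test_that("persistent_edges is the frame intersection", {
  net <- temporal_network(
    data.frame(source = c("A", "B", "B", "C"),
               target = c("B", "C", "C", "D"),
               frame = c("f1", "f1", "f2", "f2")),
    frames = c("f1", "f2"))
  pe <- persistent_edges(net, "f1", "f2")
  expect_equal(nrow(pe), 1)
  expect_equal(pe$source, "B")
  expect_equal(pe$target, "C")
  tv <- edge_turnover(net, "f1", "f2")
  expect_equal(tv$n_a, 2)
  expect_equal(tv$n_b, 2)
  expect_equal(tv$n_persistent, 1)
  expect_equal(tv$n_lost, 1)
  expect_equal(tv$n_gained, 1)

  # idempotence: a frame against itself is itself
  self <- persistent_edges(net, "f1", "f1")
  expect_equal(nrow(self), 2)
})

test_that("degree tables export as the standard TSV", {
  net <- tri_net()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_degree_table(degree_over_time(net), p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_identical(names(back), c("node", "frame", "inner", "outer", "total"))
  expect_equal(nrow(back), 3)
})

test_that("tidy and glance expose the network as tables", {
  net <- random_temporal_net(8, 0.2, c("f1", "f2"), seed = 5)
  td <- generics::tidy(net)
  expect_identical(names(td), c("source", "target", "relation", "frame"))
  gl <- generics::glance(net)
  expect_equal(gl$n_nodes, length(net$nodes))
  expect_equal(gl$n_edges, nrow(net$edges))
  expect_true(gl$directed)
})
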