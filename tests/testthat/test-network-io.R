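test_that("detect_format classifies the canonical dialects", {
  expect_identical(detect_format(list(c("A", "B"), c("B", "C"))),
                   "edge_list")
  expect_identical(
    detect_format(list(c("", "A", "B"), c("A", "0", "1"), c("B", "1", "0"))),
    "adjacency_matrix")
  expect_identical(
    detect_format(list(c("A", "pp", "B"), c("B", "pd", "C")),
                  path = "net.sif"),
    "sif")
  expect_identical(
    detect_format(list(c("A", "B", "day1"), c("A", "C", "day1"),
                       c("B", "C", "day2"), c("C", "D", "day2")),
                  frame_labels = c("day1", "day2")),
    "dynamic_edge_list")
  # three id-like columns with many distinct tokens everywhere: ambiguous
  expect_identical(
    detect_format(list(c("A", "B", "C"), c("D", "E", "F"),
                       c("G", "H", "I"), c("J", "K", "L"))),
    "unknown")
  expect_error(detect_format(list()), "empty")
})

test_that("detection is deterministic and total over random token tables", {
  set.seed(42)
  for (i in 1:50) {
    ncol <- sample(1:5, 1)
    nrow_ <- sample(1:8, 1)
    rows <- replicate(nrow_, replicate(ncol, paste0(
      sample(letters, 3), collapse = "")), simplify = FALSE)
    rows <- lapply(seq_len(nrow_), function(i) {
      vapply(1:ncol, function(j) paste0(sample(letters, 3), collapse = ""), "")
    })
    f1 <- detect_format(rows)
    f2 <- detect_format(rows)
    expect_identical(f1, f2)
    expect_true(f1 %in% c("edge_list", "adjacency_matrix", "sif",
                          "dynamic_edge_list", "unknown"))
  }
})

test_that("read_network parses edge lists, collapsing duplicates", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A\tB", "A\tB", "B\tC"), p)
  net <- read_network(p)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2)
  expect_true(net$directed)
})

test_that("read_network parses delimiters other than tab", {
  for (d in c(",", ";", " ")) {
    p <- withr::local_tempfile(fileext = ".txt")
    writeLines(paste0("A", d, "B"), p)
    net <- read_network(p)
    expect_setequal(net$nodes, c("A", "B"))
  }
})

test_that("read_network parses labelled adjacency matrices", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\tA\tB", "A\t0\t0", "B\t0\t0"), p)
  net <- read_network(p)
  expect_setequal(net$nodes, c("A", "B"))   # labels survive with zero edges
  expect_equal(nrow(net$edges), 0)

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\tA\tB", "A\t0\t2", "B\t1\t0"), p2)
  expect_error(read_network(p2, format = "adjacency_matrix"),
               "outside \\{0,1\\}")
})

test_that("read_network parses SIF with relations", {
  p <- withr::local_tempfile(fileext = ".sif")
  writeLines("A\tinteracts\tB", p)
  net <- read_network(p)
  expect_equal(net$edges$relation, "interacts")
  expect_equal(net$edges$source, "A")
  expect_equal(net$edges$target, "B")
})

test_that("unreadable and malformed inputs produce named errors", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), p)
  expect_error(read_network(p), "empty")

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A\tB", "A\tB\tC\tD\tE", "B"), p2)
  expect_error(read_network(p2), "line")
})

test_that("read_expression parses node-by-frame tables", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tT2\tT8\tT24", "TLR4\t0.1\t-1.2\t-0.4"), p)
  expr <- read_expression(p)
  expect_identical(frame_labels(expr), c("T2", "T8", "T24"))
  expect_equal(unlist(expr[expr$node == "TLR4", c("T2", "T8", "T24")],
                      use.names = FALSE),
               c(0.1, -1.2, -0.4))
})

test_that("read_expression handles single frames, missing and bad cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,T2", "A,1.5", "B,NA"), p)
  expr <- read_expression(p)
  expect_identical(frame_labels(expr), "T2")
  expect_true(is.na(expr$T2[expr$node == "B"]))   # missing, not zero

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,T2", "A,1.5", "A,2.0"), p2)
  expect_error(read_expression(p2), "duplicated node id")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,T2,T8", "A,1.5,x"), p3)
  expect_error(read_expression(p3), "row 2.*T8")
})

test_that("read_dynamic_edges builds per-frame edge sets", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tday1", "A\tB\tday2", "B\tC\tday2"), p)
  net <- read_dynamic_edges(p)
  expect_identical(net$frames, c("day1", "day2"))
  expect_equal(nrow(frame_edges(net, "day1")), 1)
  expect_equal(nrow(frame_edges(net, "day2")), 2)
  expect_setequal(net$nodes, c("A", "B", "C"))
})

test_that("dynamic edge frame order follows config, not appearance", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tday1", "B\tC\tday3", "C\tD\tday2"), p)
  net <- read_dynamic_edges(p, frames = c("day1", "day2", "day3"))
  expect_identical(net$frames, c("day1", "day2", "day3"))
})

test_that("a one-frame dynamic file equals read_network on columns 1-2", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tday1", "B\tC\tday1"), p)
  dyn <- read_dynamic_edges(p)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), p2)
  stat <- read_network(p2)
  expect_setequal(dyn$nodes, stat$nodes)
  expect_equal(dyn$edges[c("source", "target")],
               stat$edges[c("source", "target")])
})

test_that("write-then-read round-trips preserve node and edge sets", {
  net <- random_temporal_net(12, 0.12, c("day1", "day2"), seed = 7)
  edge_key <- function(n) sort(paste(n$edges$source, n$edges$target,
                                     n$edges$frame))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, p, "dynamic_edge_list")
  back <- read_dynamic_edges(p)
  expect_setequal(back$nodes, unique(c(net$edges$source, net$edges$target)))
  expect_identical(edge_key(back), edge_key(net))

  one <- random_digraph(8, 0.25, seed = 8)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(one, p2, "edge_list")
  back2 <- read_network(p2)
  expect_identical(sort(paste(back2$edges$source, back2$edges$target)),
                   sort(paste(one$edges$source, one$edges$target)))

  p3 <- withr::local_tempfile(fileext = ".sif")
  write_network(one, p3, "sif")
  back3 <- read_network(p3)
  expect_identical(sort(paste(back3$edges$source, back3$edges$target)),
                   sort(paste(one$edges$source, one$edges$target)))
  expect_true(all(back3$edges$relation == "interacts"))
})

test_that("multi-frame networks refuse static formats without a frame", {
  net <- random_temporal_net(6, 0.3, c("f1", "f2"), seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_network(net, p, "edge_list"), "select a `frame`")
  write_network(net, p, "edge_list", frame = "f2")
  back <- read_network(p)
  f2 <- frame_edges(net, "f2")
  expect_identical(sort(paste(back$edges$source, back$edges$target)),
                   sort(paste(f2$source, f2$target)))
})

test_that("adjacency matrix and equivalent edge list read identically", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(2:20, 1)
    m <- matrix(stats::rbinom(n * n, 1, 0.25), n, n)
    ids <- sprintf("g%02d", seq_len(n))
    pa <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(paste(c("", ids), collapse = "\t"),
                 vapply(seq_len(n), function(i) {
                   paste(c(ids[i], m[i, ]), collapse = "\t")
                 }, "")), pa)
    idx <- which(m == 1, arr.ind = TRUE)
    pe <- withr::local_tempfile(fileext = ".txt")
    writeLines(paste(ids[idx[, 1]], ids[idx[, 2]], sep = "\t"), pe)

    a <- read_network(pa)
    expect_identical(detect_format(sniff_rows(pa)), "adjacency_matrix",
                     info = paste("seed", seed))
    if (nrow(idx) > 0) {
      e <- read_network(pe)
      expect_identical(sort(paste(a$edges$source, a$edges$target)),
                       sort(paste(e$edges$source, e$edges$target)))
    } else {
      expect_equal(nrow(a$edges), 0)
    }
  }
})
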