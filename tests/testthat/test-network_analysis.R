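triangle <- function() {
  build_graph(data.frame(source_id = c("a", "b", "c"),
                         target_id = c("b", "c", "a")))
}

test_that("build_graph yields a simple graph and logs cleanup", {
  g <- triangle()
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(edge_node_ratio(g), 1.0)
  dup <- build_graph(data.frame(source_id = c("a", "b", "a"),
                                target_id = c("b", "a", "b")))
  expect_equal(igraph::ecount(dup), 1L)
  expect_warning(
    loop <- build_graph(data.frame(source_id = c("a", "a"),
                                   target_id = c("a", "b"))),
    "self-loop")
  expect_equal(igraph::ecount(loop), 1L)
})

test_that("graphs round-trip through the edge TSV writer", {
  cfg <- synth_config(seed = 4, graph = list(module_sizes = c(6L, 6L),
                                             p_within = 0.8,
                                             p_between = 0.1))
  g <- generate_interactome(cfg)$graph
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(g, path)
  back <- read_edge_tsv(path)
  key <- function(gr) sort(apply(igraph::as_edgelist(gr), 1,
                                 function(e) paste(sort(e), collapse = "~")))
  expect_equal(key(back), key(g))
})

test_that("merge is a deduplicating union and idempotent", {
  g1 <- triangle()
  g2 <- build_graph(data.frame(source_id = c("x", "y"),
                               target_id = c("y", "z")))
  m <- merge_graphs(list(g1, g2))
  expect_equal(igraph::vcount(m), 6L)
  expect_equal(igraph::ecount(m), 5L)
  same <- merge_graphs(list(g1, g1))
  expect_equal(igraph::vcount(same), 3L)
  expect_equal(igraph::ecount(same), 3L)
  # |E(merged)| <= sum of component edge counts on random graph sets
  set.seed(10)
  for (i in 1:5) {
    gs <- lapply(1:3, function(j) {
      n <- sample(4:8, 1)
      ids <- sample(letters[1:10], n)
      pairs <- t(utils::combn(ids, 2))
      keep <- runif(nrow(pairs)) < 0.4
      if (!any(keep)) keep[1] <- TRUE
      build_graph(data.frame(source_id = pairs[keep, 1],
                             target_id = pairs[keep, 2]))
    })
    m <- merge_graphs(gs)
    expect_lte(igraph::ecount(m),
               sum(vapply(gs, igraph::ecount, numeric(1))))
  }
})

test_that("edge/node ratio arithmetic matches the reported summaries", {
  expect_equal(round(edge_node_ratio(121, 390), 1), 3.2)
  expect_gt(edge_node_ratio(491, 2292), 4)
  expect_gt(edge_node_ratio(95, 293), 3.0)
  expect_gt(edge_node_ratio(91, 313), 3)
  # a tree on k nodes stays below 1
  k <- 9
  tree <- build_graph(data.frame(source_id = paste0("n", 1:(k - 1)),
                                 target_id = paste0("n", 2:k)))
  expect_equal(edge_node_ratio(tree), (k - 1) / k)
  expect_error(edge_node_ratio(0, 5), "empty graph")
})

test_that("isolated and missing input molecules are split correctly", {
  g <- triangle()
  expect_equal(isolated_and_missing(g, c("a", "b", "c")),
               list(isolated_count = 0L, missing_count = 0L,
                    isolated = character(), missing = character()))
  expect_equal(isolated_and_missing(g, c("a", "q"))$missing_count, 1L)
  # planted degree-0 inputs
  g2 <- extract_subnetwork(g, nodes = c("a", "b"),
                           augment = c("i1", "i2", "i3"))
  got <- isolated_and_missing(g2, c("a", "i1", "i2", "i3"))
  expect_equal(got$isolated_count, 3L)
  expect_error(isolated_and_missing(g, character()), "empty")
})

test_that("network scores are hypergeometric, monotone, and zero at no focus", {
  ns0 <- network_score(0, 20, 30, 600)
  expect_equal(ns0$p_right, 1)
  expect_equal(ns0$score, 0)
  scores <- vapply(0:15, function(k)
    network_score(k, 20, 30, 600)$score, numeric(1))
  expect_true(all(diff(scores) >= 0))
  # brute-force cross-check on a small universe
  ns <- network_score(4, 10, 12, 60)
  expect_equal(ns$p_right, brute_tail(4, 10, 12, 60, "right"),
               tolerance = 1e-12)
  expect_error(network_score(15, 10, 12, 60), "a <= A")
})

test_that("quant overlay colors nodes and respects the ratio boundary", {
  rec <- read_quant_tsv(c("protein_id\tratio_PH",
                          "a\t3.92", "b\t0.4", "c\tinf"))
  g <- overlay_quant(triangle(), rec)
  cls <- setNames(igraph::V(g)$ratio_class, igraph::V(g)$name)
  expect_equal(unname(cls[c("a", "b", "c")]),
               c("enriched_red", "depleted_green", "enriched_red"))
  g2 <- overlay_quant(triangle(), rec[1, , drop = FALSE])
  cls2 <- setNames(igraph::V(g2)$ratio_class, igraph::V(g2)$name)
  expect_equal(unname(cls2["b"]), "absent_white")
  # doubling ratios flips a depleted node only if it crosses 1
  rec_lo <- read_quant_tsv(c("protein_id\tratio_PH",
                             "a\t0.3", "b\t0.7", "c\t0.9"))
  rec_hi <- rec_lo; rec_hi$ratio_PH <- rec_lo$ratio_PH * 2
  rec_hi$ratio_class <- classify_record(rec_hi$ratio_PH)
  lo <- igraph::V(overlay_quant(triangle(), rec_lo))$ratio_class
  hi <- igraph::V(overlay_quant(triangle(), rec_hi))$ratio_class
  crossed <- rec_lo$ratio_PH * 2 > 1
  expect_equal(hi == "enriched_red", crossed)
  expect_equal(lo, rep("depleted_green", 3))
})

test_that("subnetwork extraction is a brute-force induced subgraph", {
  nd <- data.frame(id = letters[1:6],
                   function_labels = c("adhesion", "adhesion;transport",
                                       "transport", "adhesion", "", ""),
                   stringsAsFactors = FALSE)
  ed <- data.frame(source_id = c("a", "a", "b", "c", "d", "e"),
                   target_id = c("b", "d", "c", "d", "e", "f"))
  g <- build_graph(ed, nd)
  sub <- extract_subnetwork(g, label = "adhesion")
  expect_setequal(igraph::V(sub)$name, c("a", "b", "d"))
  keep <- c("a", "b", "d")
  brute <- ed[ed$source_id %in% keep & ed$target_id %in% keep, ]
  expect_equal(igraph::ecount(sub), nrow(brute))
  # augmentation enters without edges
  aug <- extract_subnetwork(g, label = "adhesion", augment = "zz")
  expect_equal(unname(igraph::degree(aug, "zz")), 0)
  expect_error(extract_subnetwork(g, label = "nope"), "no nodes match")
  # connected components agree with a brute-force union-find
  comp <- igraph::components(g)$no
  parent <- setNames(seq_len(nrow(nd)), nd$id)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(ed))) {
    a <- find(match(ed$source_id[r], nd$id))
    b <- find(match(ed$target_id[r], nd$id))
    if (a != b) parent[a] <- b
  }
  expect_equal(comp, length(unique(vapply(seq_along(parent), find, 1))))
})
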