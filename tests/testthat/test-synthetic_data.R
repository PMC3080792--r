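test_that("ontology generation has the stated geometry and is seeded", {
  cfg <- synth_config(seed = 9, dag_depth = 3, dag_branching = 4)
  dag <- generate_ontology(cfg)
  expect_equal(nrow(dag$terms), 1 + 4 + 16 + 64)
  # no multi-parent: a tree, every non-root has exactly one parent
  expect_equal(nrow(dag$edges), nrow(dag$terms) - 1L)
  expect_equal(anyDuplicated(dag$edges$child), 0L)
  again <- generate_ontology(cfg)
  expect_identical(write_obo(dag), write_obo(again))
  other <- generate_ontology(synth_config(seed = 10, dag_depth = 3,
                                          dag_branching = 4,
                                          multiparent_fraction = 0.5))
  expect_gt(nrow(other$edges), nrow(other$terms) - 1L)
})

test_that("universe annotation densities are honored", {
  cfg <- synth_config(seed = 3, N = 400, n = 50, dag_depth = 2,
                      dag_branching = 3, term_annotation_density = 1)
  dag <- generate_ontology(cfg)
  uni <- generate_universe(cfg, dag)
  A <- annotation_counts(uni$table, attr(dag, "leaves"))
  expect_true(all(A == cfg$N))
  # density 1 annotates everything, so the root covers the universe
  expect_equal(unname(annotation_counts(
    uni$table, dag$roots[["biological_process"]])), cfg$N)

  cfg2 <- synth_config(seed = 31, N = 2000, n = 50, dag_depth = 2,
                       dag_branching = 3, term_annotation_density = 0.1)
  uni2 <- generate_universe(cfg2, generate_ontology(cfg2))
  A2 <- annotation_counts(uni2$table,
                          attr(generate_ontology(cfg2), "leaves"))
  mu <- 0.1 * cfg2$N
  sd3 <- 3 * sqrt(cfg2$N * 0.1 * 0.9)
  expect_true(all(abs(A2 - mu) <= sd3))
})

test_that("membranome sampling is uniform at odds 1 and biased when planted", {
  cfg <- synth_config(seed = 5, N = 600, n = 200, dag_depth = 2,
                      dag_branching = 3)
  dag <- generate_ontology(cfg)
  uni <- generate_universe(cfg, dag)
  # n = N returns the whole universe
  cfg_all <- synth_config(seed = 5, N = 600, n = 600, dag_depth = 2,
                          dag_branching = 3)
  expect_equal(generate_membranome(cfg_all, uni),
               names(uni$table$assignments), ignore_attr = TRUE)
  # odds 1 everywhere: per-protein inclusion ~ Binomial(reps, n/N)
  hits <- integer(cfg$N)
  reps <- 40
  for (s in 1:reps) {
    c2 <- cfg; c2$seed <- s
    hits <- hits + (names(uni$table$assignments) %in%
                      generate_membranome(c2, uni))
  }
  p <- cfg$n / cfg$N
  expect_equal(mean(hits) / reps, p) # each draw takes exactly n of N
  expect_lt(max(abs(hits / reps - p)), 4.5 * sqrt(p * (1 - p) / reps))
  # planted odds push the realized a/n above A/N in most seeds
  planted <- attr(dag, "leaves")[1]
  wins <- 0
  for (s in 1:20) {
    c3 <- synth_config(seed = s, N = 600, n = 200, dag_depth = 2,
                       dag_branching = 3,
                       planted_terms = setNames(10, planted))
    memb <- generate_membranome(c3, uni)
    a <- sum(memb %in% names(uni$table$assignments)[vapply(
      uni$table$assignments, function(t) planted %in% t, logical(1))])
    A <- annotation_counts(uni$table, planted)
    wins <- wins + (a / c3$n > A / c3$N)
  }
  expect_gte(wins, 19)
})

test_that("quant generation obeys its closed forms and recovers parameters", {
  memb <- sprintf("P%06d", 1:300)
  cfg <- synth_config(seed = 8, N = 300, n = 300,
                      quant = list(membrane_fraction = 1,
                                   log2_enrichment_mean = 1,
                                   log2_enrichment_sd = 0, dropout_H = 0))
  q <- generate_quant(cfg, memb)
  expect_equal(unname(q$records$ratio_PH), rep(2, 300), tolerance = 1e-9)
  cfg_drop <- synth_config(seed = 8, N = 300, n = 300,
                           quant = list(dropout_H = 1))
  expect_true(all(is.infinite(
    generate_quant(cfg_drop, memb)$records$ratio_PH)))
  # planted mean log2 enrichment recovered within its standard error
  cfg2 <- synth_config(seed = 12, N = 300, n = 300,
                       quant = list(membrane_fraction = 1,
                                    log2_enrichment_mean = 1.5,
                                    log2_enrichment_sd = 0.5,
                                    dropout_H = 0))
  q2 <- generate_quant(cfg2, memb)
  est <- mean(log2(q2$records$ratio_PH))
  expect_lt(abs(est - 1.5), 4 * 0.5 / sqrt(300))
})

test_that("interactome modules follow the stochastic block structure", {
  cfg <- synth_config(seed = 2, graph = list(module_sizes = c(4L, 4L),
                                             p_within = 1, p_between = 0))
  net <- generate_interactome(cfg)
  expect_equal(igraph::ecount(net$graph), 12L)
  expect_equal(edge_node_ratio(net$graph), 1.5)
  expect_equal(igraph::components(net$graph)$no, 2L)
  # realized densities near their parameters on a bigger draw
  cfg2 <- synth_config(seed = 6, graph = list(module_sizes = c(30L, 30L),
                                              p_within = 0.4,
                                              p_between = 0.05))
  g2 <- generate_interactome(cfg2)$graph
  mod <- igraph::V(g2)$module
  el <- igraph::as_edgelist(g2)
  m1 <- mod[match(el[, 1], igraph::V(g2)$name)]
  m2 <- mod[match(el[, 2], igraph::V(g2)$name)]
  within <- sum(m1 == m2); between <- sum(m1 != m2)
  n_within <- 2 * choose(30, 2); n_between <- 30 * 30
  expect_lt(abs(within / n_within - 0.4),
            3 * sqrt(0.4 * 0.6 / n_within))
  expect_lt(abs(between / n_between - 0.05),
            3 * sqrt(0.05 * 0.95 / n_between))
  expect_warning(generate_interactome(
    synth_config(seed = 1, graph = list(p_within = 0.01,
                                        p_between = 0.5))),
    "inverted")
})

test_that("every generator is byte-deterministic under its seed", {
  cfg <- synth_config(seed = 77, N = 200, n = 40, dag_depth = 2,
                      dag_branching = 3,
                      planted_terms = c("SYN:0000004" = 3))
  one <- function() {
    dag <- generate_ontology(cfg)
    uni <- generate_universe(cfg, dag)
    memb <- generate_membranome(cfg, uni)
    q <- generate_quant(cfg, memb)
    net <- generate_interactome(cfg)
    list(obo = write_obo(dag), ann = write_annotations(uni$table),
         memb = memb, quant = q$records,
         edges = igraph::as_edgelist(net$graph))
  }
  expect_identical(one(), one())
})
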