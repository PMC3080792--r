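# a 100-protein universe over chain_dag(): L1 has 10 proteins, C1 those 10
# plus 10 more, G1 covers 50, G2 covers the other 50; every protein reaches
# the root
chain_universe <- function() {
  dag <- chain_dag()
  prot <- sprintf("u%03d", 1:100)
  rows <- c(paste0(prot[1:10], "\tL1"),
            paste0(prot[11:20], "\tC1"),
            paste0(prot[21:50], "\tG1"),
            paste0(prot[51:100], "\tG2"))
  tab <- propagate(parse_annotations(c("protein_id\tterm_id", rows), dag),
                   dag)
  list(dag = dag, table = tab, prot = prot)
}

test_that("a planted enriched leaf is terminal; its ancestors are expanded, not actual", {
  u <- chain_universe()
  # 8 of L1's 10 proteins plus 12 spread over G1-only and G2
  memb <- c(u$prot[1:8], u$prot[21:26], u$prot[51:56])
  rep <- mine(u$dag, u$table, memb)
  expect_equal(rep$actual_enriched, "L1")
  nodes <- rep$nodes
  expect_true(all(c("G1", "C1") %in% nodes$term_id[nodes$expanded]))
  expect_equal(nodes$direction[nodes$term_id == "L1"], "enriched")
  # path connectivity: every visited node chains back to a general category
  for (i in seq_len(nrow(nodes))) {
    t <- nodes$term_id[i]; guard <- 0
    while (!t %in% rep$general_categories && guard < 20) {
      t <- nodes$parent_id[match(t, nodes$term_id)]; guard <- guard + 1
    }
    expect_true(t %in% rep$general_categories)
  }
  # depth bookkeeping
  kid <- nodes[!is.na(nodes$parent_id), ]
  expect_equal(kid$depth,
               nodes$depth[match(kid$parent_id, nodes$term_id)] + 1L)
})

test_that("an enriched child under a depleted parent needs a forced descent", {
  u <- chain_universe()
  # membranome hits L1 hard but leaves the rest of G1 empty, so G1 itself
  # is depleted while its grandchild L1 is strongly enriched
  memb <- c(u$prot[1:8], u$prot[51:62])
  base <- mine(u$dag, u$table, memb)
  g1 <- base$nodes[base$nodes$term_id == "G1", ]
  expect_lt(g1$z, 0)
  expect_false(g1$expanded)
  expect_false("L1" %in% base$nodes$term_id)

  forced <- mine(u$dag, u$table, memb,
                 mining_policy(force_expand = c("G1", "C1")))
  expect_true("L1" %in% forced$actual_enriched)
  expect_equal(
    forced$nodes$expansion_reason[forced$nodes$term_id == "G1"],
    "forced_by_user")
  expect_error(mine(u$dag, u$table, memb,
                    mining_policy(force_expand = "NOPE")),
               "NOPE")
})

test_that("membranome = universe yields no actual-enriched terms", {
  u <- chain_universe()
  rep <- mine(u$dag, u$table, u$prot)
  expect_length(rep$actual_enriched, 0L)
  expect_true(all(rep$nodes$z == 0))
})

test_that("mining invariants hold on synthetic planted data", {
  cfg <- synth_config(seed = 5, N = 800, n = 120,
                      planted_terms = c("SYN:0000021" = 6))
  dag <- generate_ontology(cfg)
  uni <- generate_universe(cfg, dag)
  memb <- generate_membranome(cfg, uni)
  rep <- mine(dag, uni$table, memb)
  nodes <- rep$nodes
  # soundness: actual enriched terms are significantly enriched
  expect_true(all(nodes$direction[nodes$term_id %in% rep$actual_enriched]
                  == "enriched"))
  # terminality: no actual term has an enriched visited child
  for (t in rep$actual_enriched) {
    kids <- nodes$term_id[nodes$parent_id %in% t]
    expect_false(any(nodes$direction[nodes$term_id %in% kids] == "enriched"))
  }
  # children recorded only under expanded nodes
  expect_true(all(nodes$parent_id[!is.na(nodes$parent_id)] %in%
                    nodes$term_id[nodes$expanded]))
})

test_that("custom categories are injected, scored, and listed as general", {
  u <- chain_universe()
  # category of exactly the membranome's proteins from a 10% slice
  memb <- u$prot[1:10]
  upd <- add_custom_category("mechanotransduction", memb, u$dag, u$table)
  expect_true(upd$term_id %in%
                general_categories(upd$dag, "biological_process"))
  res <- enrich_terms(memb, upd$table, terms = upd$term_id)
  expect_gt(res$z, 2)
  # membership proportional to the universe scores ~0
  upd2 <- add_custom_category("everything", u$prot, u$dag, u$table)
  res2 <- enrich_terms(memb, upd2$table, terms = upd2$term_id)
  expect_equal(res2$z, 0)
  # error paths
  expect_error(add_custom_category("empty", character(), u$dag, u$table),
               "no known proteins")
  expect_warning(
    upd3 <- add_custom_category("partial", c(memb, "ghost"), u$dag,
                                u$table), "not in universe")
  expect_error(add_custom_category("mechanotransduction", memb,
                                   upd$dag, upd$table), "already exists")
})

test_that("a strongly concentrated custom category can exceed Z of 18", {
  # counts in the spirit of a curated membrane-function category: the
  # category holds 60 of 2000 universe proteins and 55 of them fall in a
  # 300-protein selection
  expect_gt(zscore(60, 300, 60, 2000), 18)
})

test_that("render_report is stable, depth-indented, and complete", {
  u <- chain_universe()
  memb <- c(u$prot[1:8], u$prot[21:26], u$prot[51:56])
  rep <- mine(u$dag, u$table, memb)
  tsv <- render_report(rep, "tsv")
  expect_length(tsv, nrow(rep$nodes) + 1L)
  tree <- render_report(rep, "tree")
  lead <- nchar(sub("\\S.*$", "", tree))
  expect_equal(lead, rep$nodes$depth * 2L)
  expect_identical(render_report(rep, "tsv"), tsv)
  expect_identical(render_report(rep, "json"), render_report(rep, "json"))
})
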