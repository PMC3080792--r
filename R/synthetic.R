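# stable per-generator RNG streams: stream seed = f(master seed, label) so
# adding a generator never perturbs the draws of an existing one
stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, label))
  expr
}

#' Configuration for the synthetic-data generator
#'
#' The defaults state the emulated world: a reference universe of 20000
#' annotated proteins from which a membranome of ~1800 proteins is drawn
#' (the scale of a large plasma-membrane proteome against a public
#' annotation database), a 3-level ontology with branching 4, per-leaf
#' annotation density 0.05, lognormal abundances spanning the ng/mg range
#' seen in such tables, a twofold average membrane enrichment
#' (`log2_enrichment_mean = 1`) for true membrane proteins, 10% homogenate
#' dropout producing infinite P/H ratios, and interaction modules far
#' denser inside than between (0.3 vs 0.02).
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param N,n Universe and membranome sizes.
#' @param dag_depth,dag_branching Ontology shape (depth counts levels below
#'   the root).
#' @param multiparent_fraction Fraction of non-root terms given a second
#'   parent.
#' @param term_annotation_density Per-leaf-term probability of annotating a
#'   protein.
#' @param planted_terms Named numeric vector: term id -> enrichment odds
#'   (sampling weight multiplier; odds 1 = null).
#' @param quant list: `membrane_fraction`, `log2_enrichment_mean`,
#'   `log2_enrichment_sd`, `abundance_meanlog`, `abundance_sdlog`,
#'   `dropout_H`.
#' @param graph list: `module_sizes`, `p_within`, `p_between`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, N = 20000L, n = 1800L,
                         dag_depth = 3L, dag_branching = 4L,
                         multiparent_fraction = 0,
                         term_annotation_density = 0.05,
                         planted_terms = numeric(),
                         quant = list(), graph = list()) {
  quant_def <- list(membrane_fraction = 0.5, log2_enrichment_mean = 1,
                    log2_enrichment_sd = 0.5, abundance_meanlog = log(100),
                    abundance_sdlog = 1.5, dropout_H = 0.1)
  graph_def <- list(module_sizes = c(20L, 16L, 16L),
                    p_within = 0.3, p_between = 0.02)
  quant <- utils::modifyList(quant_def, quant)
  graph <- utils::modifyList(graph_def, graph)
  stopifnot(N >= 1, n >= 1, n <= N, dag_depth >= 1, dag_branching >= 1,
            multiparent_fraction >= 0, multiparent_fraction <= 1,
            term_annotation_density >= 0, term_annotation_density <= 1,
            all(planted_terms > 0),
            quant$membrane_fraction >= 0, quant$membrane_fraction <= 1,
            quant$dropout_H >= 0, quant$dropout_H <= 1,
            graph$p_within >= 0, graph$p_within <= 1,
            graph$p_between >= 0, graph$p_between <= 1)
  structure(list(seed = as.integer(seed), N = as.integer(N),
                 n = as.integer(n), dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 multiparent_fraction = multiparent_fraction,
                 term_annotation_density = term_annotation_density,
                 planted_terms = planted_terms,
                 quant = quant, graph = graph),
            class = "synth_config")
}

#' Generate a synthetic rooted ontology DAG
#'
#' A balanced tree of the configured depth and branching under a single
#' `biological_process` root, with an optional fraction of non-root terms
#' receiving a second (`part_of`) parent from the level above. Deterministic
#' under the config seed.
#'
#' @param config A [synth_config()].
#' @return An `OntologyDAG`; leaf term ids carry attribute `"leaves"`.
#' @export
generate_ontology <- function(config) {
  with_stream(config$seed, "ontology", {
    ids <- "SYN:0000000"
    levels <- list("SYN:0000000")
    edges <- list()
    counter <- 0L
    for (d in seq_len(config$dag_depth)) {
      level <- character()
      for (parent in levels[[d]]) {
        for (b in seq_len(config$dag_branching)) {
          counter <- counter + 1L
          id <- sprintf("SYN:%07d", counter)
          level <- c(level, id)
          edges[[length(edges) + 1L]] <-
            data.frame(child = id, parent = parent, relation = "is_a")
        }
      }
      # optional extra parents from the same upper level
      if (config$multiparent_fraction > 0 && length(levels[[d]]) > 1) {
        pick <- runif(length(level)) < config$multiparent_fraction
        for (id in level[pick]) {
          p1 <- edges[[which(vapply(edges, function(e) e$child == id,
                                    logical(1)))[1]]]$parent
          cand <- setdiff(levels[[d]], p1)
          p2 <- cand[sample.int(length(cand), 1L)]
          edges[[length(edges) + 1L]] <-
            data.frame(child = id, parent = p2, relation = "part_of")
        }
      }
      levels[[d + 1L]] <- level
      ids <- c(ids, level)
    }
    terms <- data.frame(term_id = ids,
                        name = paste0("synthetic term ", ids),
                        namespace = "biological_process",
                        obsolete = FALSE, stringsAsFactors = FALSE)
    dag <- ontology_dag(terms, do.call(rbind, edges))
    attr(dag, "leaves") <- sort(levels[[config$dag_depth + 1L]])
    dag
  })
}

#' Generate a synthetic annotation universe
#'
#' Each of the `N` proteins is annotated to each leaf term independently
#' with the configured density; true-path propagation is then applied so
#' the table is enrichment-ready. Ground truth records the realized per-term
#' counts and the planted odds.
#'
#' @param config A [synth_config()].
#' @param dag DAG from [generate_ontology()].
#' @return list with the propagated `table` and a `truth` list
#'   (`A_realized`, `planted_terms`, `leaf_assignments`).
#' @export
generate_universe <- function(config, dag) {
  leaves <- attr(dag, "leaves")
  stopifnot(!is.null(leaves))
  with_stream(config$seed, "universe", {
    prot <- sprintf("P%06d", seq_len(config$N))
    hits <- lapply(leaves, function(t)
      prot[runif(config$N) < config$term_annotation_density])
    names(hits) <- leaves
    leaf_assign <- split(
      rep(names(hits), lengths(hits)),
      unlist(hits, use.names = FALSE))
    assignments <- setNames(rep(list(character()), config$N), prot)
    assignments[names(leaf_assign)] <- leaf_assign
    raw <- annotation_table(assignments, propagated = FALSE)
    table <- propagate(raw, dag)
    truth <- list(A_realized = annotation_counts(table),
                  planted_terms = config$planted_terms,
                  leaf_assignments = table$assignments)
    list(table = table, truth = truth)
  })
}

#' Draw a synthetic membranome with planted enrichment
#'
#' Weighted sampling without replacement from the universe: a protein's
#' weight is the product of the planted odds of the (propagated) terms it
#' carries, so planting odds > 1 on a term biases the membranome toward
#' that category — a well-defined non-central hypergeometric target. With
#' all odds at 1 the sample is uniform.
#'
#' @param config A [synth_config()].
#' @param universe Output of [generate_universe()].
#' @return Character vector of `n` protein ids, plus attribute `"weights"`.
#' @export
generate_membranome <- function(config, universe) {
  table <- universe$table
  if (config$n > table$N) stop("membranome size exceeds universe size")
  with_stream(config$seed, "membranome", {
    w <- vapply(table$assignments, function(ts) {
      hit <- intersect(ts, names(config$planted_terms))
      if (!length(hit)) 1 else prod(config$planted_terms[hit])
    }, numeric(1))
    sel <- sample(names(table$assignments), config$n, prob = w)
    sel <- sort(sel)
    attr(sel, "weights") <- w
    sel
  })
}

#' Generate a synthetic quantification table
#'
#' Emulates a membrane-fraction quantification table: lognormal abundances,
#' membrane-true proteins (a Bernoulli `membrane_fraction` of the
#' membranome) receive a multiplicative P-vs-H enrichment
#' `2^e, e ~ N(log2_enrichment_mean, sd)` while the rest get `e ~ N(0, sd)`;
#' homogenate dropout (`sin_H = 0`) produces infinite ratios.
#'
#' @param config A [synth_config()].
#' @param membranome Protein ids from [generate_membranome()].
#' @return list with `records` (quant data.frame as [read_quant_tsv()]
#'   returns) and `truth` (`membrane_true`, `log2_e` per protein).
#' @export
generate_quant <- function(config, membranome) {
  stopifnot(length(membranome) >= 1)
  q <- config$quant
  with_stream(config$seed, "quant", {
    m <- length(membranome)
    membrane_true <- runif(m) < q$membrane_fraction
    e <- rnorm(m, mean = ifelse(membrane_true, q$log2_enrichment_mean, 0),
               sd = q$log2_enrichment_sd)
    abundance <- rlnorm(m, q$abundance_meanlog, q$abundance_sdlog)
    sin_P <- rlnorm(m, q$abundance_meanlog, q$abundance_sdlog)
    sin_H <- sin_P / 2^e
    drop <- runif(m) < q$dropout_H
    sin_H[drop] <- 0
    records <- data.frame(
      protein_id = membranome,
      accession = paste0("ACC_", membranome),
      description = paste("synthetic protein", membranome),
      abundance_P_ng_per_mg = abundance,
      sin_P = sin_P, sin_H = sin_H,
      ratio_PH = compute_ratio(sin_P, sin_H),
      locations = ifelse(membrane_true, "plasma membrane", "cytoplasm"),
      stringsAsFactors = FALSE)
    records$ratio_class <- classify_record(records$ratio_PH)
    records$compartments <- parse_locations(records$locations)
    truth <- list(membrane_true = setNames(membrane_true, membranome),
                  log2_e = setNames(e, membranome))
    list(records = records, truth = truth)
  })
}

#' Generate a modular synthetic interactome
#'
#' Stochastic block structure: nodes are split into the configured modules;
#' node pairs within a module are connected with `p_within`, pairs across
#' modules with `p_between`. Module membership is recorded as a node
#' attribute and in the returned truth.
#'
#' @param config A [synth_config()].
#' @param node_ids Optional node names; default `M0001...` covering the
#'   module sizes.
#' @return list with `graph` (igraph) and `truth$module` (named membership
#'   vector).
#' @export
generate_interactome <- function(config, node_ids = NULL) {
  g <- config$graph
  sizes <- as.integer(g$module_sizes)
  total <- sum(sizes)
  if (is.null(node_ids)) node_ids <- sprintf("M%04d", seq_len(total))
  stopifnot(length(node_ids) == total)
  if (g$p_within < g$p_between) {
    warning("p_within < p_between: inverted module structure")
  }
  with_stream(config$seed, "interactome", {
    module <- rep(seq_along(sizes), sizes)
    pairs <- utils::combn(total, 2L)
    same <- module[pairs[1, ]] == module[pairs[2, ]]
    p <- ifelse(same, g$p_within, g$p_between)
    hit <- runif(ncol(pairs)) < p
    ed <- data.frame(source_id = node_ids[pairs[1, hit]],
                     target_id = node_ids[pairs[2, hit]],
                     stringsAsFactors = FALSE)
    nd <- data.frame(id = node_ids, molecule_class = "protein",
                     function_labels = paste0("module", module),
                     stringsAsFactors = FALSE)
    graph <- build_graph(ed, nd)
    igraph::V(graph)$module <- module[match(igraph::V(graph)$name, node_ids)]
    list(graph = graph, truth = list(module = setNames(module, node_ids)))
  })
}

#' Write a quantification table to TSV
#' @param records Quant data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_quant_tsv <- function(records, path) {
  df <- records[, setdiff(names(records), c("compartments", "ratio_class")),
                drop = FALSE]
  df$ratio_PH <- ifelse(is.infinite(df$ratio_PH), "inf",
                        as.character(df$ratio_PH))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
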