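#' Mining policy for recursive category expansion
#'
#' Controls how [mine()] descends the ontology from each general category.
#' The default rule expands every node with a positive Z-score (and always a
#' significantly enriched node); the `force_expand` list reproduces manual
#' descents into depleted branches, e.g. recovering an enriched transport
#' subcategory two levels under a moderately depleted ion-transport parent.
#'
#' @param z_threshold Significance threshold for enriched/depleted calls.
#' @param expand_z_gt Expand nodes whose `z` exceeds this value (default 0).
#' @param max_depth Maximum depth below a general category (default 10).
#' @param min_A Smallest universe category size considered well-supported;
#'   smaller categories are still reported but flagged `low_support`.
#' @param force_expand Term ids that are always expanded when visited.
#' @return A list of class `mining_policy`.
#' @export
mining_policy <- function(z_threshold = 2.0, expand_z_gt = 0,
                          max_depth = 10, min_A = 2,
                          force_expand = character()) {
  stopifnot(z_threshold > 0, max_depth >= 1, min_A >= 0)
  structure(list(z_threshold = z_threshold, expand_z_gt = expand_z_gt,
                 max_depth = max_depth, min_A = min_A,
                 force_expand = as.character(force_expand)),
            class = "mining_policy")
}

#' Inject a custom category into the ontology and universe
#'
#' Attaches a new term as a direct child of the namespace root and annotates
#' the listed universe proteins with it, so a manually curated function
#' (e.g. mechanotransduction/mechanosignaling, absent from public
#' ontologies) is scored like any other general category.
#'
#' @param name Human-readable category name (must not collide with an
#'   existing term id).
#' @param protein_ids Universe proteins carrying the category; unknown ids
#'   are dropped with a warning, an empty (post-drop) list is an error.
#' @param dag An `OntologyDAG`.
#' @param table An `AnnotationTable` over `dag`'s universe.
#' @param namespace Root to attach under (default `biological_process`).
#' @param term_id Identifier for the new term; default `CUSTOM:<slug>`.
#' @return list with the updated `dag` and `table` and the new `term_id`.
#' @export
add_custom_category <- function(name, protein_ids, dag, table,
                                namespace = "biological_process",
                                term_id = NULL) {
  stopifnot(inherits(dag, "OntologyDAG"), inherits(table, "AnnotationTable"))
  if (!namespace %in% names(dag$roots)) stop("unknown namespace: ", namespace)
  if (is.null(term_id)) {
    term_id <- paste0("CUSTOM:", gsub("[^A-Za-z0-9]+", "_", name))
  }
  if (term_id %in% dag$terms$term_id || name %in% dag$terms$name) {
    stop("category already exists: ", name)
  }
  protein_ids <- unique(as.character(protein_ids))
  unknown <- setdiff(protein_ids, names(table$assignments))
  if (length(unknown)) {
    warning("dropping ", length(unknown), " protein id(s) not in universe")
    protein_ids <- setdiff(protein_ids, unknown)
  }
  if (!length(protein_ids)) stop("custom category has no known proteins")
  root <- dag$roots[[namespace]]
  terms <- rbind(dag$terms,
                 data.frame(term_id = term_id, name = name,
                            namespace = namespace, obsolete = FALSE,
                            stringsAsFactors = FALSE))
  edges <- rbind(dag$edges,
                 data.frame(child = term_id, parent = root,
                            relation = "is_a", stringsAsFactors = FALSE))
  new_dag <- ontology_dag(terms, edges)
  assignments <- table$assignments
  for (p in protein_ids) {
    extra <- if (table$propagated) c(term_id, root) else term_id
    assignments[[p]] <- sort(unique(c(assignments[[p]], extra)))
  }
  new_table <- annotation_table(assignments, propagated = table$propagated,
                                report = table$report)
  list(dag = new_dag, table = new_table, term_id = term_id)
}

#' Recursive category-tree mining
#'
#' Starting from the general categories (direct children of the namespace
#' root), scores every visited term with [enrich_terms()] and expands a
#' node's children when its Z-score exceeds the policy's expansion rule,
#' when it is significantly enriched, or when it is on the force-expand
#' list. The report's `actual_enriched` set contains the terminal enriched
#' refinements: significantly enriched visited terms none of whose visited
#' children is itself enriched.
#'
#' Multi-parent terms are visited once per distinct path but deduplicated in
#' `actual_enriched`. Traversal order (children identifier-sorted,
#' depth-first) is deterministic.
#'
#' @param dag An `OntologyDAG`.
#' @param table A propagated `AnnotationTable`.
#' @param membranome Character vector of selected protein ids.
#' @param policy A [mining_policy()].
#' @param namespace Namespace to mine (default `biological_process`).
#' @param variance Variance convention for [zscore()].
#' @return Object of class `MiningReport`: list with `nodes` (one row per
#'   visit: `term_id`, `parent_id`, `depth`, counts, `z`, `direction`,
#'   `expanded`, `expansion_reason`, `low_support`), `actual_enriched`,
#'   `general_categories`, `namespace`, `policy`.
#' @export
mine <- function(dag, table, membranome, policy = mining_policy(),
                 namespace = "biological_process",
                 variance = c("hypergeometric", "binomial")) {
  variance <- match.arg(variance)
  stopifnot(inherits(policy, "mining_policy"))
  missing_force <- setdiff(policy$force_expand,
                           dag$terms$term_id[!dag$terms$obsolete])
  if (length(missing_force)) {
    stop("force-expand term(s) absent from DAG: ",
         paste(missing_force, collapse = ", "))
  }
  ns_terms <- dag$terms$term_id[dag$terms$namespace == namespace &
                                  !dag$terms$obsolete]
  scores <- enrich_terms(membranome, table, terms = ns_terms,
                         z_threshold = policy$z_threshold,
                         variance = variance)
  rownames(scores) <- scores$term_id
  gen <- general_categories(dag, namespace)

  rows <- list()
  visit <- function(term, parent, depth) {
    sc <- scores[term, ]
    reason <- NA_character_
    expanded <- FALSE
    if (depth < policy$max_depth) {
      if (term %in% policy$force_expand) {
        expanded <- TRUE; reason <- "forced_by_user"
      } else if (sc$direction == "enriched") {
        expanded <- TRUE; reason <- "significant_parent"
      } else if (is.finite(sc$z) && sc$z > policy$expand_z_gt) {
        expanded <- TRUE; reason <- "forced_by_policy"
      }
    }
    kids <- if (expanded) dag_children(dag, term) else character()
    kids <- kids[kids %in% ns_terms]
    rows[[length(rows) + 1L]] <<- data.frame(
      term_id = term, parent_id = parent, depth = depth,
      a = sc$a, n = sc$n, A = sc$A, N = sc$N, z = sc$z,
      p_right = sc$p_right, direction = sc$direction,
      expanded = expanded, expansion_reason = reason,
      low_support = sc$A < policy$min_A, stringsAsFactors = FALSE)
    if (expanded) for (k in kids) visit(k, term, depth + 1L)
  }
  for (g in gen) visit(g, NA_character_, 0L)
  nodes <- do.call(rbind, rows)
  rownames(nodes) <- NULL

  # terminal enriched refinement: enriched visit with no enriched visited child
  enriched_terms <- unique(nodes$term_id[nodes$direction == "enriched"])
  actual <- vapply(enriched_terms, function(t) {
    kid_rows <- nodes$parent_id %in% t
    !any(nodes$direction[kid_rows] == "enriched")
  }, logical(1))
  structure(list(nodes = nodes,
                 actual_enriched = sort(enriched_terms[actual]),
                 general_categories = gen,
                 namespace = namespace, policy = policy),
            class = "MiningReport")
}

#' @export
print.MiningReport <- function(x, ...) {
  cat("MiningReport (", x$namespace, "): ", nrow(x$nodes),
      " visits over ", length(x$general_categories),
      " general categories; ", length(x$actual_enriched),
      " actual-enriched term(s)\n", sep = "")
  invisible(x)
}

#' Render a mining report
#'
#' @param report A `MiningReport`.
#' @param format `"tsv"` (level-ordered table), `"tree"` (indented text) or
#'   `"json"` (full report).
#' @param path Optional output file.
#' @return Character vector of lines (invisibly if `path` given).
#' @export
render_report <- function(report, format = c("tsv", "tree", "json"),
                          path = NULL) {
  format <- match.arg(format)
  nodes <- report$nodes
  out <- switch(format,
    tsv = {
      df <- nodes[order(nodes$depth, nodes$term_id), ]
      c(paste(colnames(df), collapse = "\t"),
        apply(df, 1L, function(r) paste(trimws(r), collapse = "\t")))
    },
    tree = {
      lab <- sprintf("%s%s [z=%.2f %s%s%s]",
                     strrep("  ", nodes$depth), nodes$term_id, nodes$z,
                     nodes$direction,
                     ifelse(nodes$term_id %in% report$actual_enriched,
                            " *actual*", ""),
                     ifelse(nodes$low_support, " (low support)", ""))
      lab
    },
    json = {
      r <- unclass(report)
      r$policy <- unclass(r$policy)
      strsplit(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), "\n")[[1]]
    })
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
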