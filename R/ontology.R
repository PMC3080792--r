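#' @importFrom stats p.adjust phyper rbinom rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Construct an ontology DAG
#'
#' Low-level constructor used by [parse_obo()] and the synthetic generator.
#' Validates identifier uniqueness, parent resolution, acyclicity and
#' reachability of a namespace root from every non-root term.
#'
#' @param terms data.frame with columns `term_id`, `name`, `namespace`,
#'   `obsolete` (logical). Namespaces are free strings; the GO trio
#'   (`biological_process`, `molecular_function`, `cellular_component`) and
#'   `custom` are the conventional values.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`). Obsolete terms must not appear.
#' @return An object of class `OntologyDAG`: a list with elements `terms`,
#'   `edges` and `roots` (named character vector, one root per namespace).
#' @export
ontology_dag <- function(terms, edges) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  terms <- terms[order(terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term_id: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  }
  if (nrow(edges)) {
    edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
    rownames(edges) <- NULL
    bad <- setdiff(c(edges$child, edges$parent), terms$term_id)
    if (length(bad)) {
      stop("edge references unknown term: ", paste(bad, collapse = ", "))
    }
    obs <- terms$term_id[terms$obsolete]
    if (length(intersect(c(edges$child, edges$parent), obs))) {
      stop("obsolete terms may not carry edges")
    }
    if (!all(edges$relation %in% c("is_a", "part_of"))) {
      stop("unknown relation type: ",
           paste(setdiff(edges$relation, c("is_a", "part_of")), collapse = ", "))
    }
  }
  live <- terms[!terms$obsolete, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("child", "parent")] else
      data.frame(child = character(), parent = character()),
    directed = TRUE, vertices = live$term_id)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop("cycle detected among terms: ", paste(sort(cyc), collapse = " -> "))
  }
  has_parent <- live$term_id %in% edges$child
  roots_df <- live[!has_parent, , drop = FALSE]
  if (anyDuplicated(roots_df$namespace)) {
    stop("namespace with multiple roots: ",
         paste(unique(roots_df$namespace[duplicated(roots_df$namespace)]),
               collapse = ", "))
  }
  roots <- setNames(roots_df$term_id, roots_df$namespace)
  # every live term must reach its namespace root
  for (ns in names(roots)) {
    ns_ids <- live$term_id[live$namespace == ns]
    reach <- names(igraph::subcomponent(g, roots[[ns]], mode = "in"))
    stray <- setdiff(ns_ids, reach)
    if (length(stray)) {
      stop("terms not connected to root of namespace '", ns, "': ",
           paste(stray, collapse = ", "))
    }
  }
  structure(list(terms = terms, edges = edges, roots = roots, graph = g),
            class = "OntologyDAG")
}

#' @export
print.OntologyDAG <- function(x, ...) {
  cat("OntologyDAG:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),", nrow(x$edges), "edges,",
      length(x$roots), "namespace root(s)\n")
  invisible(x)
}

#' Parse an OBO ontology file
#'
#' Reads the OBO 1.2/1.4 subset used by the Gene Ontology flat files:
#' `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete` lines. Obsolete terms are kept
#' in the term table (flagged) but carry no edges and are never
#' enrichment-eligible.
#'
#' @param path Path to an OBO file, or a character vector of lines.
#' @param part_of Capture `relationship: part_of` edges (default `TRUE`).
#' @return An [ontology_dag()] object.
#' @export
parse_obo <- function(path, part_of = TRUE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  stanza_at <- which(lines == "[Term]")
  if (!length(stanza_at)) stop("no [Term] stanza found")
  other_at <- grep("^\\[(?!Term\\])", lines, perl = TRUE)
  bounds <- sort(c(stanza_at, other_at, length(lines) + 1L))
  terms <- list()
  edges <- list()
  for (s in stanza_at) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, max(s + 1L, end))]
    field <- function(key) {
      v <- body[startsWith(body, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- field("id")[1]
    if (is.na(id) || !nzchar(id)) stop("[Term] stanza without id near line ", s)
    obs <- any(tolower(field("is_obsolete")) == "true")
    nm <- field("name")[1]
    ns <- field("namespace")[1]
    terms[[length(terms) + 1L]] <- data.frame(
      term_id = id,
      name = if (is.na(nm)) id else nm,
      namespace = if (is.na(ns)) "biological_process" else ns,
      obsolete = obs, stringsAsFactors = FALSE)
    if (!obs) {
      for (p in field("is_a")) {
        pid <- trimws(strsplit(p, "!", fixed = TRUE)[[1]][1])
        edges[[length(edges) + 1L]] <-
          data.frame(child = id, parent = pid, relation = "is_a")
      }
      if (part_of) {
        rel <- field("relationship")
        rel <- rel[startsWith(rel, "part_of")]
        for (p in rel) {
          pid <- trimws(sub("^part_of", "", p))
          pid <- trimws(strsplit(pid, "!", fixed = TRUE)[[1]][1])
          edges[[length(edges) + 1L]] <-
            data.frame(child = id, parent = pid, relation = "part_of")
        }
      }
    }
  }
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(child = character(), parent = character(),
               relation = character())
  dangling <- setdiff(edges$parent, terms$term_id[!terms$obsolete])
  if (length(dangling)) {
    stop("dangling parent id(s): ", paste(sort(dangling), collapse = ", "))
  }
  ontology_dag(terms, edges)
}

#' Write an ontology DAG to OBO
#'
#' Emits the same OBO subset [parse_obo()] reads, in identifier-sorted order
#' so output is byte-stable.
#'
#' @param dag An `OntologyDAG`.
#' @param path Output file path, or `NULL` to return the lines.
#' @return Invisibly, the character vector of lines written.
#' @export
write_obo <- function(dag, path = NULL) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    out <- c(out, "[Term]", paste0("id: ", t$term_id),
             paste0("name: ", t$name), paste0("namespace: ", t$namespace))
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    e <- dag$edges[dag$edges$child == t$term_id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[j] == "is_a")
        paste0("is_a: ", e$parent[j]) else
          paste0("relationship: part_of ", e$parent[j]))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Ancestors of a term
#'
#' All terms reachable from `term_id` by following child-to-parent edges,
#' excluding the term itself.
#'
#' @param dag An `OntologyDAG`.
#' @param term_id Single term identifier.
#' @param relations Relations to traverse; default both `is_a` and `part_of`.
#' @return Character vector of ancestor ids (sorted).
#' @export
dag_ancestors <- function(dag, term_id, relations = c("is_a", "part_of")) {
  g <- relation_graph(dag, relations)
  if (!term_id %in% igraph::V(g)$name) stop("unknown term: ", term_id)
  sort(setdiff(names(igraph::subcomponent(g, term_id, mode = "out")), term_id))
}

#' Direct children of a term
#' @inheritParams dag_ancestors
#' @return Sorted character vector of child term ids.
#' @export
dag_children <- function(dag, term_id, relations = c("is_a", "part_of")) {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  sort(unique(e$child[e$parent == term_id]))
}

relation_graph <- function(dag, relations) {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("child", "parent")], directed = TRUE,
    vertices = dag$terms$term_id[!dag$terms$obsolete])
}

#' General categories of a namespace
#'
#' The direct children of the namespace root — the top-level bars of a
#' classical ontology over-representation chart.
#'
#' @param dag An `OntologyDAG`.
#' @param namespace Namespace name, e.g. `"biological_process"`.
#' @return Character vector of term ids in identifier-sorted order.
#' @export
general_categories <- function(dag, namespace) {
  if (!namespace %in% names(dag$roots)) {
    stop("unknown namespace: ", namespace)
  }
  dag_children(dag, dag$roots[[namespace]])
}

#' Construct an annotation table
#'
#' @param assignments Named list mapping protein id to a character vector of
#'   term ids (possibly empty).
#' @param propagated Has true-path propagation been applied?
#' @param report Optional parse report list.
#' @return Object of class `AnnotationTable` with elements `assignments`,
#'   `N` (distinct protein count), `propagated`, `report`.
#' @export
annotation_table <- function(assignments, propagated = FALSE, report = NULL) {
  stopifnot(is.list(assignments))
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be uniquely named by protein id")
  }
  assignments <- assignments[order(names(assignments))]
  assignments <- lapply(assignments, function(x) sort(unique(as.character(x))))
  structure(list(assignments = assignments, N = length(assignments),
                 propagated = propagated, report = report),
            class = "AnnotationTable")
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat("AnnotationTable:", x$N, "proteins,",
      length(unique(unlist(x$assignments))), "distinct terms,",
      if (x$propagated) "propagated" else "not propagated", "\n")
  invisible(x)
}

#' Parse a protein-to-term annotation TSV
#'
#' Expects a header with `protein_id` and `term_id` columns (extra columns
#' such as `evidence` are ignored); `#` comment lines are skipped. Records
#' whose term is absent from the DAG (or obsolete) are dropped and counted
#' in the parse report; malformed rows are skipped with a warning.
#'
#' @param path TSV path or character vector of lines.
#' @param dag An `OntologyDAG` defining the known terms.
#' @return An un-propagated `AnnotationTable`; its `report` element is a list
#'   `records_in`, `records_kept`, `records_dropped_unknown_term`,
#'   `records_malformed`, `N`.
#' @export
parse_annotations <- function(path, dag) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("annotation table is empty")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ip <- match("protein_id", hdr); it <- match("term_id", hdr)
  if (is.na(ip) || is.na(it)) {
    stop("annotation table must have protein_id and term_id columns")
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  need <- max(ip, it)
  malformed <- which(vapply(body, length, 1L) < need)
  if (length(malformed)) {
    warning("skipping ", length(malformed), " malformed row(s): ",
            paste(malformed, collapse = ", "))
    body <- body[-malformed]
  }
  if (!length(body)) stop("annotation table is empty")
  prot <- vapply(body, `[[`, "", ip)
  term <- vapply(body, `[[`, "", it)
  known <- dag$terms$term_id[!dag$terms$obsolete]
  keep <- term %in% known
  report <- list(records_in = length(malformed) + length(prot),
                 records_kept = sum(keep),
                 records_dropped_unknown_term = sum(!keep),
                 records_malformed = length(malformed),
                 N = length(unique(prot)))
  assignments <- split(term[keep], prot[keep])
  # proteins whose every record was dropped still count toward the universe
  lost <- setdiff(unique(prot), names(assignments))
  if (length(lost)) {
    assignments <- c(assignments,
                     setNames(rep(list(character()), length(lost)), lost))
  }
  annotation_table(assignments, propagated = FALSE, report = report)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes every protein's term set under ancestry, so that annotation to a
#' term implies annotation to all of its ancestors. After propagation
#' `A(parent) >= A(child)` holds on every edge.
#'
#' @param table An un-propagated `AnnotationTable`.
#' @param dag An `OntologyDAG`.
#' @param part_of Traverse `part_of` edges as well as `is_a` (default
#'   `TRUE`, the GO convention).
#' @return The propagated `AnnotationTable`.
#' @export
propagate <- function(table, dag, part_of = TRUE) {
  stopifnot(inherits(table, "AnnotationTable"), inherits(dag, "OntologyDAG"))
  if (table$propagated) stop("table is already propagated")
  relations <- if (part_of) c("is_a", "part_of") else "is_a"
  g <- relation_graph(dag, relations)
  used <- sort(unique(unlist(table$assignments)))
  anc <- lapply(used, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))
  names(anc) <- used
  assignments <- lapply(table$assignments, function(ts) {
    if (!length(ts)) return(character())
    sort(unique(unlist(anc[ts], use.names = FALSE)))
  })
  annotation_table(assignments, propagated = TRUE, report = table$report)
}

#' Per-term annotation counts A(t)
#'
#' @param table An `AnnotationTable`.
#' @param terms Term ids to count; default every term seen in the table.
#' @return Named integer vector of protein counts per term.
#' @export
annotation_counts <- function(table, terms = NULL) {
  all_terms <- unlist(table$assignments, use.names = FALSE)
  tab <- table(all_terms)
  if (is.null(terms)) terms <- sort(names(tab))
  out <- setNames(integer(length(terms)), terms)
  hit <- intersect(terms, names(tab))
  out[hit] <- as.integer(tab[hit])
  out
}

#' Write an annotation table to TSV
#' @param table An `AnnotationTable`.
#' @param path Output path or `NULL` to return lines.
#' @return Invisibly, the lines written.
#' @export
write_annotations <- function(table, path = NULL) {
  rows <- unlist(lapply(names(table$assignments), function(p) {
    ts <- table$assignments[[p]]
    if (!length(ts)) return(character())
    paste(p, ts, sep = "\t")
  }), use.names = FALSE)
  out <- c("protein_id\tterm_id", rows)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
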