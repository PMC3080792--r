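#' Build a protein interaction graph from edge records
#'
#' Produces a simple undirected graph: duplicate edges are collapsed and
#' self-loops dropped with a warning. An optional `directed` edge flag
#' (expression-control annotation) and `provenance` are carried as edge
#' attributes but ignored by all statistics. Node attributes (molecule
#' class, ';'-separated function labels) are joined from `node_records`.
#'
#' @param edge_records data.frame with columns `source_id`, `target_id` and
#'   optional `directed`, `provenance`.
#' @param node_records Optional data.frame with columns `id` and any of
#'   `molecule_class`, `function_labels`.
#' @return An [igraph::igraph] object (undirected, simple).
#' @export
build_graph <- function(edge_records, node_records = NULL) {
  stopifnot(is.data.frame(edge_records),
            all(c("source_id", "target_id") %in% names(edge_records)))
  src <- as.character(edge_records$source_id)
  tgt <- as.character(edge_records$target_id)
  loops <- src == tgt
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s)")
    edge_records <- edge_records[!loops, , drop = FALSE]
    src <- src[!loops]; tgt <- tgt[!loops]
  }
  nodes <- sort(unique(c(src, tgt,
                         if (!is.null(node_records))
                           as.character(node_records$id))))
  # canonical endpoint order so duplicates collapse regardless of direction
  lo <- pmin(src, tgt); hi <- pmax(src, tgt)
  key <- paste(lo, hi)
  keep <- !duplicated(key)
  ed <- data.frame(from = lo[keep], to = hi[keep], stringsAsFactors = FALSE)
  if ("directed" %in% names(edge_records)) {
    ed$directed <- as.logical(edge_records$directed)[keep]
  }
  if ("provenance" %in% names(edge_records)) {
    ed$provenance <- as.character(edge_records$provenance)[keep]
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  igraph::V(g)$molecule_class <- NA_character_
  igraph::V(g)$function_labels <- ""
  igraph::V(g)$ratio_class <- "absent_white"
  if (!is.null(node_records)) {
    idx <- match(nodes, as.character(node_records$id))
    if ("molecule_class" %in% names(node_records)) {
      igraph::V(g)$molecule_class <-
        as.character(node_records$molecule_class)[idx]
    }
    if ("function_labels" %in% names(node_records)) {
      fl <- as.character(node_records$function_labels)[idx]
      igraph::V(g)$function_labels <- ifelse(is.na(fl), "", fl)
    }
  }
  g
}

#' Read an edge-list TSV into an interaction graph
#' @param path TSV with header `source_id`, `target_id`, optional
#'   `directed`, `provenance`.
#' @param node_path Optional node TSV (`id`, `molecule_class`,
#'   `function_labels`).
#' @return An igraph object via [build_graph()].
#' @export
read_edge_tsv <- function(path, node_path = NULL) {
  ed <- read.delim(path, stringsAsFactors = FALSE)
  nd <- if (!is.null(node_path)) read.delim(node_path,
                                            stringsAsFactors = FALSE)
  build_graph(ed, nd)
}

#' Write an interaction graph as an edge-list TSV
#' @param graph igraph object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_tsv <- function(graph, path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  names(ed)[1:2] <- c("source_id", "target_id")
  ed <- ed[order(ed$source_id, ed$target_id), , drop = FALSE]
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge interaction networks
#'
#' Union of node and edge sets with deduplication, the operation behind
#' building a global interactome from the top-ranked networks. On a node
#' attribute conflict the first graph's value is kept and the conflict
#' logged as a message.
#'
#' @param graphs list of igraph objects (length >= 1).
#' @return Merged igraph object.
#' @export
merge_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  eds <- lapply(graphs, function(g) {
    e <- igraph::as_data_frame(g, what = "edges")[, 1:2, drop = FALSE]
    names(e) <- c("source_id", "target_id"); e
  })
  ed <- do.call(rbind, eds)
  att <- list()
  for (g in graphs) {
    vd <- igraph::as_data_frame(g, what = "vertices")
    for (i in seq_len(nrow(vd))) {
      nm <- vd$name[i]
      if (is.null(att[[nm]])) {
        att[[nm]] <- vd[i, , drop = FALSE]
      } else if (!identical(unlist(att[[nm]]), unlist(vd[i, , drop = FALSE]))) {
        message("attribute conflict on node ", nm, ": keeping first value")
      }
    }
  }
  nodes <- do.call(rbind, unname(att))
  names(nodes)[names(nodes) == "name"] <- "id"
  merged <- build_graph(ed, nodes)
  if ("ratio_class" %in% names(nodes)) {
    idx <- match(igraph::V(merged)$name, nodes$id)
    igraph::V(merged)$ratio_class <- nodes$ratio_class[idx]
  }
  merged
}

#' Edge-to-node ratio of a network
#'
#' `|E| / |V|`, the cohesion summary used to describe interactomes (e.g.
#' 390 edges over 121 nodes giving 3.2). Reported at full precision;
#' round only in rendered views.
#'
#' @param graph igraph object, or a node count when `edges` is given.
#' @param edges Optional edge count for the arithmetic form.
#' @return Numeric ratio.
#' @export
edge_node_ratio <- function(graph, edges = NULL) {
  if (is.numeric(graph)) {
    stopifnot(!is.null(edges))
    if (graph == 0) stop("empty graph")
    return(edges / graph)
  }
  nv <- igraph::vcount(graph)
  if (nv == 0) stop("empty graph")
  igraph::ecount(graph) / nv
}

#' Isolated and missing molecules of an input set
#'
#' Splits an input molecule set against a network into members present but
#' with no interaction partner (degree 0) and members absent from the graph
#' altogether.
#'
#' @param graph igraph object.
#' @param input_set Character vector of molecule ids (nonempty).
#' @return list with `isolated_count`, `missing_count`, `isolated`,
#'   `missing`.
#' @export
isolated_and_missing <- function(graph, input_set) {
  input_set <- unique(as.character(input_set))
  if (!length(input_set)) stop("input set is empty")
  present <- intersect(input_set, igraph::V(graph)$name)
  missing <- sort(setdiff(input_set, present))
  deg <- igraph::degree(graph, v = present)
  isolated <- sort(present[deg == 0])
  list(isolated_count = length(isolated), missing_count = length(missing),
       isolated = isolated, missing = missing)
}

#' Hypergeometric network score
#'
#' The score of a candidate network is `-log10` of the right-tailed Fisher
#' exact (hypergeometric) probability of finding at least `focus_count` of
#' the `eligible_total` input molecules in a network of `network_size`
#' molecules drawn from a universe of `universe_total`. By construction the
#' more input molecules a network contains, the higher its score.
#'
#' @param focus_count Input-set molecules present in the network.
#' @param network_size Total molecules in the network.
#' @param eligible_total Input molecules eligible for network analysis.
#' @param universe_total Molecules in the reference knowledge base.
#' @return list of class `NetworkScore` with `focus_count`, `network_size`,
#'   `eligible_total`, `universe_total`, `p_right`, `score`.
#' @export
network_score <- function(focus_count, network_size, eligible_total,
                          universe_total) {
  check_counts(focus_count, network_size, eligible_total, universe_total)
  p <- hypergeom_tail(focus_count, network_size, eligible_total,
                      universe_total, side = "right")
  structure(list(focus_count = focus_count, network_size = network_size,
                 eligible_total = eligible_total,
                 universe_total = universe_total,
                 p_right = p, score = -log10(p)),
            class = "NetworkScore")
}

#' @export
print.NetworkScore <- function(x, ...) {
  cat(sprintf("NetworkScore: %d/%d focus molecules, p_right = %.3g, score = %.1f\n",
              x$focus_count, x$network_size, x$p_right, x$score))
  invisible(x)
}

#' Overlay quantification classes onto a network
#'
#' Colors each node by its membrane-enrichment class: `enriched_red` for
#' P/H > 1 or detected only in the membrane fraction, `depleted_green` for
#' P/H < 1, and `absent_white` for molecules without quantification
#' evidence (absent from the table, undefined, or exactly 1). An
#' `intensity` attribute holds `|log2(ratio)|` for finite ratios and `Inf`
#' (maximal) for membrane-only molecules.
#'
#' @param graph igraph object.
#' @param quant_records data.frame from [read_quant_tsv()] (needs
#'   `protein_id`, `ratio_PH`, `ratio_class`).
#' @return The graph with `ratio_class` and `intensity` node attributes.
#' @export
overlay_quant <- function(graph, quant_records) {
  idx <- match(igraph::V(graph)$name, quant_records$protein_id)
  cls <- quant_records$ratio_class[idx]
  ratio <- quant_records$ratio_PH[idx]
  igraph::V(graph)$ratio_class <- ifelse(
    is.na(cls) | cls == "undetermined", "absent_white",
    ifelse(cls %in% c("PM_enriched", "PM_only"), "enriched_red",
           "depleted_green"))
  igraph::V(graph)$intensity <- ifelse(
    is.na(ratio) | igraph::V(graph)$ratio_class == "absent_white", 0,
    ifelse(is.infinite(ratio), Inf, abs(log2(ratio))))
  graph
}

#' Extract a function subnetwork
#'
#' Induced subgraph on the nodes carrying a function label (or an explicit
#' node list), optionally augmented with extra molecules that enter without
#' any edges (the manually-imported molecules of an expanded map). Only
#' direct interactions between retained nodes survive; no inferred paths
#' are ever inserted.
#'
#' @param graph igraph object with a `function_labels` node attribute.
#' @param label Function label to match (against the ';'-separated labels).
#' @param nodes Explicit node list (alternative to `label`).
#' @param augment Extra node ids added as isolated vertices if not already
#'   retained.
#' @return Induced igraph subgraph.
#' @export
extract_subnetwork <- function(graph, label = NULL, nodes = NULL,
                               augment = character()) {
  if (is.null(label) && is.null(nodes)) stop("give a label or a node list")
  if (!is.null(label)) {
    labs <- strsplit(igraph::V(graph)$function_labels, ";", fixed = TRUE)
    hit <- vapply(labs, function(l) label %in% trimws(l), logical(1))
    nodes <- igraph::V(graph)$name[hit]
  }
  nodes <- intersect(unique(as.character(nodes)), igraph::V(graph)$name)
  if (!length(nodes)) stop("no nodes match")
  sub <- igraph::induced_subgraph(graph, nodes)
  extra <- setdiff(unique(as.character(augment)), igraph::V(sub)$name)
  if (length(extra)) sub <- igraph::add_vertices(sub, length(extra),
                                                 name = extra)
  sub
}

#' Write a graph to GraphML
#' @param graph igraph object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
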