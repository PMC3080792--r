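#' Assemble a pipeline run configuration
#'
#' @param obo Path to the ontology OBO file.
#' @param annotations Path to the protein-to-term annotation TSV.
#' @param membranome Path to the selected-protein list (one id per line, or
#'   a TSV whose first column is the id).
#' @param quant Optional quantification TSV path.
#' @param edges Optional character vector of interaction edge TSV paths.
#' @param out_dir Output directory (created if needed).
#' @param z_threshold,min_A,max_depth,expand_z_gt,force_expand,variance
#'   Mining and scoring policy knobs (see [mining_policy()] and
#'   [zscore()]).
#' @param namespace Ontology namespace to mine.
#' @param custom_categories Optional named list: category name ->
#'   protein-id vector, injected via [add_custom_category()] before mining.
#' @param part_of Propagate over part_of edges (default TRUE).
#' @return list of class `run_config`.
#' @export
run_config <- function(obo, annotations, membranome, quant = NULL,
                       edges = NULL, out_dir = "membranomics_out",
                       z_threshold = 2.0, min_A = 2, max_depth = 10,
                       expand_z_gt = 0, force_expand = character(),
                       variance = "hypergeometric",
                       namespace = "biological_process",
                       custom_categories = list(), part_of = TRUE) {
  structure(list(obo = obo, annotations = annotations,
                 membranome = membranome, quant = quant, edges = edges,
                 out_dir = out_dir, z_threshold = z_threshold,
                 min_A = min_A, max_depth = max_depth,
                 expand_z_gt = expand_z_gt, force_expand = force_expand,
                 variance = variance, namespace = namespace,
                 custom_categories = custom_categories, part_of = part_of),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Collects every problem without executing any pipeline stage; an empty
#' character vector means the configuration is runnable.
#'
#' @param config A [run_config()].
#' @return Character vector of problem descriptions (possibly empty).
#' @export
validate_run_config <- function(config) {
  problems <- character()
  for (f in c("obo", "annotations", "membranome")) {
    p <- config[[f]]
    if (is.null(p) || !file.exists(p)) {
      problems <- c(problems, paste0("missing input file (", f, "): ",
                                     if (is.null(p)) "<unset>" else p))
    }
  }
  for (p in c(config$quant, config$edges)) {
    if (!file.exists(p)) problems <- c(problems,
                                       paste0("missing input file: ", p))
  }
  if (config$z_threshold <= 0) {
    problems <- c(problems, "threshold must be positive")
  }
  if (config$max_depth < 1) problems <- c(problems, "max_depth must be >= 1")
  if (length(config$force_expand) && !is.null(config$obo) &&
      file.exists(config$obo)) {
    dag <- tryCatch(parse_obo(config$obo, part_of = config$part_of),
                    error = function(e) NULL)
    if (!is.null(dag)) {
      bad <- setdiff(config$force_expand,
                     dag$terms$term_id[!dag$terms$obsolete])
      if (length(bad)) {
        problems <- c(problems,
                      paste0("force-expand term not in DAG: ",
                             paste(bad, collapse = ", ")))
      }
    }
  }
  problems
}

read_protein_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- trimws(vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L))
  lines <- lines[nzchar(lines)]
  if (length(lines) && lines[1] == "protein_id") lines <- lines[-1]
  unique(lines)
}

#' Run the full pipeline
#'
#' parse -> propagate -> (custom categories) -> enrich -> mine -> quant ->
#' network -> report. Every artifact lands in `config$out_dir`; the
#' manifest lists each output with its checksum, so two runs on identical
#' inputs are byte-identical (no timestamps are written).
#'
#' @param config A validated [run_config()].
#' @return Invisibly, a list with the in-memory results (`dag`, `table`,
#'   `report`, `quant_summary`, `network_summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  problems <- validate_run_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)

  dag <- parse_obo(config$obo, part_of = config$part_of)
  table <- parse_annotations(config$annotations, dag)
  jsonlite::write_json(table$report, outp("parse_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  table <- propagate(table, dag, part_of = config$part_of)
  membranome <- read_protein_list(config$membranome)

  for (nm in names(config$custom_categories)) {
    upd <- add_custom_category(nm, config$custom_categories[[nm]],
                               dag, table, namespace = config$namespace)
    dag <- upd$dag; table <- upd$table
  }

  policy <- mining_policy(z_threshold = config$z_threshold,
                          expand_z_gt = config$expand_z_gt,
                          max_depth = config$max_depth,
                          min_A = config$min_A,
                          force_expand = config$force_expand)
  report <- mine(dag, table, membranome, policy,
                 namespace = config$namespace, variance = config$variance)
  ns_terms <- dag$terms$term_id[dag$terms$namespace == config$namespace &
                                  !dag$terms$obsolete]
  enr <- enrich_terms(membranome, table, terms = ns_terms,
                      z_threshold = config$z_threshold,
                      variance = config$variance)
  enr$name <- dag$terms$name[match(enr$term_id, dag$terms$term_id)]
  write_enrichment(enr, outp("enrichment.tsv"))
  render_report(report, "tsv", outp("mining_report.tsv"))
  render_report(report, "tree", outp("mining_tree.txt"))

  quant_summary <- NULL
  if (!is.null(config$quant)) {
    qr <- read_quant_tsv(config$quant)
    quant_summary <- location_summary(qr)
    write_quant_summary(quant_summary, outp("quant_summary.json"))
  }

  network_summary <- NULL
  if (length(config$edges)) {
    graphs <- lapply(config$edges, read_edge_tsv)
    merged <- if (length(graphs) > 1) merge_graphs(graphs) else graphs[[1]]
    if (!is.null(config$quant)) merged <- overlay_quant(merged, qr)
    iso <- isolated_and_missing(merged, membranome)
    network_summary <- list(
      nodes = igraph::vcount(merged), edges = igraph::ecount(merged),
      edge_node_ratio = edge_node_ratio(merged),
      isolated_from_input = iso$isolated_count,
      missing_from_input = iso$missing_count)
    jsonlite::write_json(network_summary, outp("network_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_edge_tsv(merged, outp("merged_network.tsv"))
  }

  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("membranomics")),
    config = config[c("z_threshold", "min_A", "max_depth", "expand_z_gt",
                      "force_expand", "variance", "namespace", "part_of")],
    input_checksums = as.list(tools::md5sum(
      unlist(config[c("obo", "annotations", "membranome", "quant",
                      "edges")], use.names = FALSE))),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, outputs))))
  names(manifest$input_checksums) <-
    basename(names(manifest$input_checksums))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(dag = dag, table = table, report = report,
                 enrichment = enr, quant_summary = quant_summary,
                 network_summary = network_summary, manifest = manifest))
}

#' Generate a complete synthetic demo dataset and run the pipeline on it
#'
#' Writes synthetic OBO/annotation/membranome/quant/edge inputs under
#' `out_dir/inputs`, then runs [run_pipeline()] into `out_dir/results`.
#' Fully deterministic under `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param config Optional [synth_config()]; its seed is overridden by
#'   `seed`. Default: desk-scale world (N = 3000, n = 300, one planted
#'   term with odds 5).
#' @return Invisibly, the [run_pipeline()] result.
#' @export
run_demo <- function(seed = 1L, out_dir = "membranomics_demo",
                     config = NULL) {
  if (is.null(config)) {
    config <- synth_config(seed = seed, N = 3000L, n = 300L,
                           planted_terms = c("SYN:0000021" = 5))
  } else {
    config$seed <- as.integer(seed)
  }
  ind <- file.path(out_dir, "inputs")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  dag <- generate_ontology(config)
  uni <- generate_universe(config, dag)
  memb <- generate_membranome(config, uni)
  quant <- generate_quant(config, memb)
  net <- generate_interactome(config)
  write_obo(dag, file.path(ind, "ontology.obo"))
  write_annotations(uni$table, file.path(ind, "annotations.tsv"))
  writeLines(c("protein_id", memb), file.path(ind, "membranome.tsv"))
  write_quant_tsv(quant$records, file.path(ind, "quant.tsv"))
  write_edge_tsv(net$graph, file.path(ind, "edges.tsv"))
  jsonlite::write_json(
    list(planted_terms = as.list(config$planted_terms),
         membrane_true = as.list(quant$truth$membrane_true),
         module = as.list(net$truth$module)),
    file.path(ind, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  rc <- run_config(obo = file.path(ind, "ontology.obo"),
                   annotations = file.path(ind, "annotations.tsv"),
                   membranome = file.path(ind, "membranome.tsv"),
                   quant = file.path(ind, "quant.tsv"),
                   edges = file.path(ind, "edges.tsv"),
                   out_dir = file.path(out_dir, "results"))
  invisible(run_pipeline(rc))
}

#' Command-line entry point
#'
#' Subcommands: `demo --seed S --out DIR`, `run --config FILE` (JSON copy
#' of [run_config()] fields), `validate --config FILE`. Results go to
#' files; logs to stderr.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: membranomics <demo|run|validate> [--seed S] [--out DIR] [--config FILE]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  status <- tryCatch({
    switch(cmd,
      demo = {
        run_demo(seed = as.integer(opt("--seed", "1")),
                 out_dir = opt("--out", "membranomics_demo"))
        message("demo complete")
        0L
      },
      run = {
        cfgf <- opt("--config")
        if (is.null(cfgf)) stop("run needs --config FILE")
        cfg <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
        rc <- do.call(run_config, cfg)
        run_pipeline(rc)
        message("run complete")
        0L
      },
      validate = {
        cfgf <- opt("--config")
        if (is.null(cfgf)) stop("validate needs --config FILE")
        cfg <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
        rc <- do.call(run_config, cfg)
        problems <- validate_run_config(rc)
        if (length(problems)) {
          message(paste(problems, collapse = "\n")); 1L
        } else {
          message("configuration valid"); 0L
        }
      },
      { message(usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
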