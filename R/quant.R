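#' P/H quantification ratio
#'
#' The relative membrane enrichment of a protein is the ratio of its
#' normalized spectral index in the membrane fraction (P) to that in the
#' total tissue homogenate (H). A protein detected in P but not H has an
#' infinite ratio (`Inf`, the table convention is the infinity sign); a
#' protein detected in neither has an undefined ratio (`NA`).
#'
#' @param sin_P,sin_H Non-negative normalized spectral index values;
#'   `NA` is treated as not detected.
#' @return Numeric ratio, `Inf` for P-only, `NA` for undefined (vectorised).
#' @export
compute_ratio <- function(sin_P, sin_H) {
  sin_P <- as.numeric(sin_P); sin_H <- as.numeric(sin_H)
  if (any(sin_P < 0, na.rm = TRUE) || any(sin_H < 0, na.rm = TRUE)) {
    stop("spectral index values must be non-negative")
  }
  p0 <- is.na(sin_P) | sin_P == 0
  h0 <- is.na(sin_H) | sin_H == 0
  ifelse(p0 & h0, NA_real_,
         ifelse(h0, Inf, ifelse(p0, 0, sin_P / sin_H)))
}

#' Classify a quantification record by its P/H ratio
#'
#' Finite ratio > 1 is `PM_enriched`; finite < 1 is `depleted`; infinite
#' (detected only in the membrane fraction) is `PM_only`; undefined or
#' exactly 1 is `undetermined` (the definition covers only strict
#' inequalities).
#'
#' @param ratio_PH Numeric ratio(s) as produced by [compute_ratio()].
#' @return Character vector in
#'   `{"PM_enriched", "depleted", "PM_only", "undetermined"}`.
#' @export
classify_record <- function(ratio_PH) {
  ratio_PH <- as.numeric(ratio_PH)
  ifelse(is.na(ratio_PH), "undetermined",
         ifelse(is.infinite(ratio_PH), "PM_only",
                ifelse(ratio_PH > 1, "PM_enriched",
                       ifelse(ratio_PH < 1, "depleted", "undetermined"))))
}

# split a free-text location field into normalized compartment tokens;
# "undecided"/"unknown"/"NA" dialects mean unannotated (empty token set)
parse_locations <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s)) return(character())
    toks <- unlist(strsplit(s, "[;,]"))
    toks <- tolower(trimws(toks))
    toks <- toks[nzchar(toks)]
    sort(unique(setdiff(toks, c("undecided", "unknown", "na"))))
  })
}

#' Read a protein quantification TSV
#'
#' Expected columns: `protein_id`, `accession`, `description`,
#' `abundance_P_ng_per_mg`, `sin_P`, `sin_H`, `ratio_PH`, `locations`
#' (';'-separated). Either `ratio_PH` or the `sin_P`/`sin_H` pair may be
#' absent; a present `ratio_PH` column wins and accepts the literals
#' `inf`, `Inf` and the infinity sign. `#` comment lines are skipped.
#'
#' @param path TSV path or character vector of lines.
#' @return data.frame of quantification records with numeric `ratio_PH`
#'   (`Inf`/`NA` markers), a `ratio_class` column from [classify_record()]
#'   and a `compartments` list-column of normalized location tokens.
#' @export
read_quant_tsv <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!startsWith(trimws(lines), "#")]
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!"protein_id" %in% names(df)) stop("quant TSV needs a protein_id column")
  if ("ratio_PH" %in% names(df)) {
    raw <- trimws(as.character(df$ratio_PH))
    inf <- raw %in% c("inf", "Inf", "INF", "∞")
    df$ratio_PH <- suppressWarnings(as.numeric(raw))
    df$ratio_PH[inf] <- Inf
  } else if (all(c("sin_P", "sin_H") %in% names(df))) {
    df$ratio_PH <- compute_ratio(df$sin_P, df$sin_H)
  } else {
    stop("quant TSV needs ratio_PH or sin_P/sin_H columns")
  }
  if ("abundance_P_ng_per_mg" %in% names(df)) {
    df$abundance_P_ng_per_mg <- as.numeric(df$abundance_P_ng_per_mg)
    if (any(df$abundance_P_ng_per_mg < 0, na.rm = TRUE)) {
      stop("negative abundance")
    }
  }
  df$ratio_class <- classify_record(df$ratio_PH)
  df$compartments <- parse_locations(
    if ("locations" %in% names(df)) df$locations else rep(NA, nrow(df)))
  df
}

#' Filter quantification records by a predicate specification
#'
#' The predicate is a named list combining (all conjunctive):
#' \describe{
#'   \item{ratio_class}{one or more of the [classify_record()] classes}
#'   \item{ratio_gt, ratio_lt}{bounds on the finite ratio (records with
#'     infinite or undefined ratios never match a finite bound)}
#'   \item{abundance_min, abundance_max}{bounds on `abundance_P_ng_per_mg`}
#'   \item{annotated}{`TRUE`/`FALSE`: has at least one compartment token}
#'   \item{compartment}{records whose token set contains this compartment}
#' }
#'
#' @param records data.frame from [read_quant_tsv()].
#' @param spec Named list of predicate fields; unknown fields are an error.
#' @return list with `count` and the sorted matching `ids`.
#' @export
filter_count <- function(records, spec = list()) {
  known <- c("ratio_class", "ratio_gt", "ratio_lt",
             "abundance_min", "abundance_max", "annotated", "compartment")
  bad <- setdiff(names(spec), known)
  if (length(bad)) stop("unknown predicate field(s): ",
                        paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(records))
  r <- records$ratio_PH
  if (!is.null(spec$ratio_class)) {
    keep <- keep & records$ratio_class %in% spec$ratio_class
  }
  if (!is.null(spec$ratio_gt)) {
    keep <- keep & !is.na(r) & is.finite(r) & r > spec$ratio_gt
  }
  if (!is.null(spec$ratio_lt)) {
    keep <- keep & !is.na(r) & is.finite(r) & r < spec$ratio_lt
  }
  if (!is.null(spec$abundance_min)) {
    keep <- keep & records$abundance_P_ng_per_mg >= spec$abundance_min
  }
  if (!is.null(spec$abundance_max)) {
    keep <- keep & records$abundance_P_ng_per_mg <= spec$abundance_max
  }
  ann <- vapply(records$compartments, length, 1L) > 0
  if (!is.null(spec$annotated)) keep <- keep & (ann == spec$annotated)
  if (!is.null(spec$compartment)) {
    comp <- tolower(spec$compartment)
    keep <- keep & vapply(records$compartments,
                          function(cs) comp %in% cs, logical(1))
  }
  ids <- sort(records$protein_id[keep & !is.na(keep)])
  list(count = length(ids), ids = ids)
}

#' Summarize quantification records
#'
#' Counts records by ratio class (the five classes partition the table:
#' enriched + depleted + infinite + undefined + exactly-one = n), counts
#' location-annotated records, tallies per-compartment membership (a record
#' with two compartments counts once in each), and reports the abundance
#' range of an optional subset of protein ids.
#'
#' @param records data.frame from [read_quant_tsv()].
#' @param abundance_subset Optional protein ids whose abundance range to
#'   report; default all records.
#' @return list of class `QuantSummary`.
#' @export
location_summary <- function(records, abundance_subset = NULL) {
  r <- records$ratio_PH
  n <- nrow(records)
  ann <- vapply(records$compartments, length, 1L) > 0
  comp_tab <- sort(table(unlist(records$compartments)), decreasing = TRUE)
  sel <- if (is.null(abundance_subset)) rep(TRUE, n) else
    records$protein_id %in% abundance_subset
  ab <- records$abundance_P_ng_per_mg[sel]
  out <- list(
    n_records = n,
    n_enriched = sum(!is.na(r) & is.finite(r) & r > 1),
    n_depleted = sum(!is.na(r) & is.finite(r) & r < 1),
    n_infinite = sum(is.infinite(r)),
    n_ratio_undefined = sum(is.na(r)),
    n_ratio_equal_one = sum(!is.na(r) & is.finite(r) & r == 1),
    n_location_annotated = sum(ann),
    per_compartment = as.list(setNames(as.integer(comp_tab),
                                       names(comp_tab))),
    abundance_range = if (length(ab) && any(!is.na(ab)))
      c(min(ab, na.rm = TRUE), max(ab, na.rm = TRUE)) else c(NA_real_, NA_real_))
  class(out) <- "QuantSummary"
  out
}

#' @export
print.QuantSummary <- function(x, ...) {
  cat("QuantSummary:", x$n_records, "records |",
      x$n_enriched, "PM-enriched,", x$n_depleted, "depleted,",
      x$n_infinite, "PM-only,", x$n_ratio_undefined + x$n_ratio_equal_one,
      "undetermined |", x$n_location_annotated, "annotated\n")
  invisible(x)
}

#' Write a quantification summary as JSON
#' @param summary A `QuantSummary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_quant_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
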