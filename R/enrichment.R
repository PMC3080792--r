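#' Validate a category count tuple
#'
#' A category count is the 2x2 margin (a, n, A, N): `a` proteins of the
#' selected set of size `n` fall in a category that contains `A` of the `N`
#' universe proteins.
#'
#' @param a,n,A,N Non-negative integers with `a <= min(n, A)`, `A <= N`,
#'   `0 < n <= N`.
#' @return Invisibly `TRUE`; otherwise an error naming the violated
#'   invariant.
#' @export
check_counts <- function(a, n, A, N) {
  if (any(c(a, n, A, N) < 0)) stop("counts must be non-negative")
  if (n <= 0) stop("invariant violated: 0 < n")
  if (n > N) stop("invariant violated: n <= N")
  if (A > N) stop("invariant violated: A <= N")
  if (a > A) stop("invariant violated: a <= A")
  if (a > n) stop("invariant violated: a <= n")
  # the complementary cell must also be feasible
  if (n - a > N - A) stop("invariant violated: n - a <= N - A")
  invisible(TRUE)
}

#' Hypergeometric Z-score for category over-representation
#'
#' The enrichment statistic `z = (a - mu) / sigma` with `mu = n*A/N` and,
#' under the default hypergeometric sampling model,
#' `sigma^2 = n * (A/N) * (1 - A/N) * (N - n)/(N - 1)`. Positive values mean
#' over-representation of the category in the selected set. Setting
#' `variance = "binomial"` drops the finite-population correction factor.
#'
#' When the variance is zero (`A = 0`, `A = N` or `n = N`) the score is 0 if
#' `a` equals its expectation and a signed infinity otherwise, with a
#' warning; callers decide how to treat the marker.
#'
#' @inheritParams check_counts
#' @param variance `"hypergeometric"` (default) or `"binomial"`.
#' @return Numeric Z-score (vectorised over the count arguments).
#' @export
zscore <- function(a, n, A, N,
                   variance = c("hypergeometric", "binomial")) {
  variance <- match.arg(variance)
  invisible(mapply(check_counts, a, n, A, N))
  if (any(N < 2)) stop("N must be at least 2")
  p <- A / N
  mu <- n * p
  v <- n * p * (1 - p)
  if (variance == "hypergeometric") v <- v * (N - n) / (N - 1)
  z <- ifelse(v > 0, (a - mu) / sqrt(v),
              ifelse(a == mu, 0, sign(a - mu) * Inf))
  if (any(is.infinite(z))) {
    warning("zero-variance category with a != mu: returning signed infinity")
  }
  unname(z)
}

#' Exact hypergeometric tail probability
#'
#' `P(X >= a)` (right) or `P(X <= a)` (left) for
#' `X ~ Hypergeometric(N, A, n)` — the null distribution of the category
#' count when `n` proteins are drawn without replacement from a universe of
#' `N` containing `A` category members. Computed in log space via
#' [stats::phyper()]; both tails include the point mass at `a`, so they sum
#' to at least 1.
#'
#' @inheritParams check_counts
#' @param side `"right"` (default) or `"left"`.
#' @return Probability in `[0, 1]` (vectorised).
#' @export
hypergeom_tail <- function(a, n, A, N, side = c("right", "left")) {
  side <- match.arg(side)
  invisible(mapply(check_counts, a, n, A, N))
  unname(if (side == "right") {
    phyper(a - 1, A, N - A, n, lower.tail = FALSE)
  } else {
    phyper(a, A, N - A, n, lower.tail = TRUE)
  })
}

#' Classify a Z-score as enriched, depleted or neutral
#'
#' The significance rule is inclusive at the threshold: `z >= z_threshold`
#' is enriched, `z <= -z_threshold` depleted (default threshold 2.0, the
#' approximate 95% CI rule), anything else neutral.
#'
#' @param z Numeric Z-score(s); signed infinities are accepted.
#' @param z_threshold Positive significance threshold (default 2.0).
#' @return Character vector in `{"enriched", "depleted", "neutral"}`.
#' @export
classify <- function(z, z_threshold = 2.0) {
  stopifnot(is.numeric(z), z_threshold > 0)
  ifelse(z >= z_threshold, "enriched",
         ifelse(z <= -z_threshold, "depleted", "neutral"))
}

#' Ontology term enrichment for a protein set
#'
#' For each term, counts `a` = selected proteins annotated to the term and
#' compares with the universe count `A` out of `N` via the hypergeometric
#' Z-score and exact tails. Selected proteins absent from the universe
#' cannot contribute to any category and are excluded from `n`; the
#' exclusion count is reported as an attribute.
#'
#' Benjamini-Hochberg `q_right` values are supplied as a convenience column;
#' the classification itself uses only the raw `|z| >= z_threshold` rule.
#'
#' @param membranome Character vector of selected protein ids.
#' @param table A propagated `AnnotationTable` (defines `A` and `N`).
#' @param terms Term ids to test; default all annotated terms.
#' @param z_threshold Significance threshold passed to [classify()].
#' @param variance Variance convention passed to [zscore()].
#' @return data.frame with columns `term_id`, `a`, `n`, `A`, `N`, `z`,
#'   `p_right`, `p_left`, `q_right`, `direction`, ordered by `term_id`;
#'   attribute `n_excluded` counts selected proteins missing from the
#'   universe.
#' @export
enrich_terms <- function(membranome, table, terms = NULL,
                         z_threshold = 2.0,
                         variance = c("hypergeometric", "binomial")) {
  variance <- match.arg(variance)
  stopifnot(inherits(table, "AnnotationTable"))
  if (!table$propagated) {
    warning("annotation table is not propagated; counts will not obey the ",
            "true-path rule")
  }
  membranome <- unique(as.character(membranome))
  inside <- intersect(membranome, names(table$assignments))
  if (!length(inside)) stop("no membranome protein found in universe")
  n_excluded <- length(membranome) - length(inside)
  n <- length(inside)
  N <- table$N
  if (is.null(terms)) terms <- sort(unique(unlist(table$assignments)))
  terms <- sort(unique(terms))
  A <- annotation_counts(table, terms)
  sel <- unlist(table$assignments[inside], use.names = FALSE)
  a <- setNames(integer(length(terms)), terms)
  tab <- table(sel)
  hit <- intersect(terms, names(tab))
  a[hit] <- as.integer(tab[hit])
  z <- suppressWarnings(zscore(a, n, A, N, variance = variance))
  out <- data.frame(
    term_id = terms, a = as.integer(a), n = n, A = as.integer(A), N = N,
    z = z,
    p_right = hypergeom_tail(a, n, A, N, "right"),
    p_left = hypergeom_tail(a, n, A, N, "left"),
    stringsAsFactors = FALSE)
  out$q_right <- p.adjust(out$p_right, method = "BH")
  out$direction <- classify(out$z, z_threshold)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write an enrichment result table to TSV
#'
#' @param results data.frame from [enrich_terms()] (optionally with extra
#'   columns such as `name` or `depth`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
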