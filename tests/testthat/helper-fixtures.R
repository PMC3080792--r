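# shared fixtures and independent brute-force oracles

tiny_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: child", "namespace: biological_process",
    "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: grandchild",
    "namespace: biological_process", "is_a: GO:2", "")
}

# a small hand-built DAG: root R; general categories G1 (with chain
# C1 -> C2 leaf L) and G2; all biological_process
chain_dag <- function() {
  terms <- data.frame(
    term_id = c("R", "G1", "G2", "C1", "L1"),
    name = paste("term", c("R", "G1", "G2", "C1", "L1")),
    namespace = "biological_process", obsolete = FALSE,
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("G1", "G2", "C1", "L1"),
    parent = c("R", "R", "G1", "C1"),
    relation = "is_a", stringsAsFactors = FALSE)
  ontology_dag(terms, edges)
}

# brute-force ancestral closure walking the raw edge table (independent of
# the igraph-based implementation path)
brute_closure <- function(dag, term_ids) {
  out <- unique(term_ids)
  repeat {
    parents <- dag$edges$parent[dag$edges$child %in% out]
    grown <- unique(c(out, parents))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

# exact hypergeometric PMF from factorial ratios (log-gamma), independent
# of stats::phyper / stats::dhyper
brute_pmf <- function(k, n, A, N) {
  exp(lgamma(A + 1) - lgamma(k + 1) - lgamma(A - k + 1) +
        lgamma(N - A + 1) - lgamma(n - k + 1) - lgamma(N - A - n + k + 1) -
        (lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1)))
}

brute_tail <- function(a, n, A, N, side) {
  lo <- max(0, n - (N - A)); hi <- min(n, A)
  ks <- lo:hi
  p <- brute_pmf(ks, n, A, N)
  if (side == "right") sum(p[ks >= a]) else sum(p[ks <= a])
}

brute_moments <- function(n, A, N) {
  lo <- max(0, n - (N - A)); hi <- min(n, A)
  ks <- lo:hi
  p <- brute_pmf(ks, n, A, N)
  mu <- sum(ks * p)
  list(mu = mu, sd = sqrt(sum((ks - mu)^2 * p)))
}

# random valid (a, n, A, N) count tuples
random_tuples <- function(m, N_max = 200) {
  unname(t(vapply(seq_len(m), function(i) {
    N <- sample(2:N_max, 1)
    n <- sample(1:N, 1)
    A <- sample(0:N, 1)
    lo <- max(0, n - (N - A)); hi <- min(n, A)
    a <- if (lo == hi) lo else sample(lo:hi, 1)
    c(a = a, n = n, A = A, N = N)
  }, numeric(4))))
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "membranomics")
  if (nzchar(p)) p else file.path("../../inst/extdata", f)
}
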