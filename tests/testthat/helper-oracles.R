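# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (iterative deletion, exhaustive enumeration,
# explicit running sums) and never call the code paths they check.

# k-core by repeated deletion: for each k, strip nodes of degree < k until
# stable; a node's core number is the largest k at which it survives.
brute_kcore <- function(graph) {
  nodes <- igraph::V(graph)$name
  core <- stats::setNames(rep(0L, length(nodes)), nodes)
  k <- 1L
  repeat {
    g <- graph
    repeat {
      low <- igraph::V(g)$name[igraph::degree(g) < k]
      if (length(low) == 0) break
      g <- igraph::delete_vertices(g, low)
    }
    surv <- igraph::V(g)$name
    if (length(surv) == 0) break
    core[surv] <- k
    k <- k + 1L
  }
  core
}

# hypergeometric upper tail P(overlap >= k) by exhausting every n-subset of
# a universe 1..N whose first K elements form the gene set
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# exact two-sided Mann-Whitney p by enumerating every labeling of the pooled
# sample (tie-free inputs only)
enum_mwu <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# GSEA enrichment score by an explicit element-by-element running sum
trace_gsea_es <- function(ranked_genes, rank_metric, gene_set, exponent = 1) {
  rank_metric <- unname(rank_metric)
  N <- length(ranked_genes)
  hit <- ranked_genes %in% gene_set
  wsum <- sum(abs(rank_metric[hit])^exponent)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) run + abs(rank_metric[i])^exponent / wsum
           else run - 1 / (N - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# seeded Erdos-Renyi graph with named vertices
random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# small, fast simulation settings used where full-size data is unnecessary
small_sim <- function(seed = 1, ...) {
  sim_config(n_mrna = 300, n_lncrna = 80, n_mirna = 60, n_de_mrna = 30,
             n_de_lncrna = 12, n_triples = 16, hub_lnc_mirna_fanout = 10,
             ppi_hub_extra_degree = 10, seed = seed, ...)
}

# igraph from a plain edge list given as a 2-column matrix of names
graph_from_pairs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(m, directed = FALSE)
}

# fixtures for module detection
fixture_k4_pendant <- function() {
  graph_from_pairs("a","b", "a","c", "a","d", "b","c", "b","d", "c","d",
                   "d","p")
}
fixture_p6 <- function() {
  graph_from_pairs("a","b", "b","c", "c","d", "d","e", "e","f")
}
fixture_double_k4_bridge <- function() {
  graph_from_pairs("a","b", "a","c", "a","d", "b","c", "b","d", "c","d",
                   "d","x", "x","e",
                   "e","f", "e","g", "e","h", "f","g", "f","h", "g","h")
}
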