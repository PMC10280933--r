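#' Load a scored PPI edge list with a combined-score filter
#'
#' Edges with combined score below \code{min_score} are dropped (the boundary
#' is inclusive, so a score exactly at the cutoff is retained); duplicate
#' edges are merged keeping the maximum score; self-loops are removed.
#'
#' @param edge_rows a data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{combined_score}, or a path to such a TSV.
#' @param min_score combined-score cutoff in [0, 1], default 0.7.
#' @return An object of class \code{ppi_graph}: an undirected \code{igraph}
#'   graph with a \code{score} edge attribute.
#' @export
load_ppi <- function(edge_rows, min_score = 0.7) {
  if (is.character(edge_rows) && length(edge_rows) == 1)
    edge_rows <- utils::read.delim(edge_rows, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(edge_rows))
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(edge_rows)))
    stop("load_ppi: need columns gene_a, gene_b, combined_score")
  s <- edge_rows$combined_score
  bad <- which(!is.finite(s) | s < 0 | s > 1)
  if (length(bad) > 0)
    stop("load_ppi: combined score outside [0,1] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df <- edge_rows[s >= min_score, need, drop = FALSE]
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df) > 0) {
    a <- pmin(df$gene_a, df$gene_b)
    b <- pmax(df$gene_a, df$gene_b)
    key <- paste(a, b, sep = "\r")
    score <- tapply(df$combined_score, key, max)
    parts <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
    df <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                     score = unname(score), stringsAsFactors = FALSE)
    df <- df[order(df$gene_a, df$gene_b), ]
  } else {
    df <- data.frame(gene_a = character(), gene_b = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  class(g) <- c("ppi_graph", class(g))
  g
}

#' Degree-ranked hub genes in a PPI graph
#'
#' Supports both the strict gate used on the whole PPI network
#' (degree > threshold) and the inclusive gate used on the ceRNA-restricted
#' PPI (degree >= threshold).
#'
#' @param graph a \code{ppi_graph} (any igraph works).
#' @param threshold degree threshold.
#' @param comparator \code{">"} or \code{">="}.
#' @return A \code{hub_set} data.frame (see \code{\link{hub_lncrnas}}).
#' @export
degree_hubs <- function(graph, threshold = 20, comparator = ">") {
  deg <- igraph::degree(graph)
  hub_set(deg, threshold, comparator)
}

#' k-core decomposition
#'
#' Core number of each node: the largest k such that the node belongs to a
#' subgraph in which every node has degree >= k.
#'
#' @param graph an igraph graph.
#' @return Named integer vector node -> core number.
#' @export
k_core <- function(graph) {
  igraph::coreness(graph)
}

#' MCODE vertex weighting
#'
#' For each node, build the closed neighborhood (the node plus its
#' neighbors), find the highest k-core of that neighborhood graph, and set
#' weight = k * density of that k-core. Isolated nodes get weight 0.
#'
#' @param graph an igraph graph.
#' @return A data.frame with columns \code{node_id}, \code{k} (highest
#'   neighborhood core), \code{core_density}, \code{weight}, ordered by
#'   node_id.
#' @export
mcode_weights <- function(graph) {
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
    nodes <- igraph::V(graph)$name
  }
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  rows <- lapply(seq_along(nodes), function(i) {
    nb <- c(nodes[i], adj[[i]]$name)
    if (length(nb) < 2)
      return(data.frame(node_id = nodes[i], k = 0, core_density = 0,
                        weight = 0, stringsAsFactors = FALSE))
    sub <- igraph::induced_subgraph(graph, nb)
    cn <- igraph::coreness(sub)
    kmax <- max(cn)
    core_nodes <- names(cn)[cn == kmax]
    core <- igraph::induced_subgraph(sub, core_nodes)
    nv <- igraph::vcount(core)
    dens <- if (nv < 2) 0 else 2 * igraph::ecount(core) / (nv * (nv - 1))
    data.frame(node_id = nodes[i], k = kmax, core_density = dens,
               weight = kmax * dens, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$node_id), ]
  rownames(out) <- NULL
  out
}

#' MCODE-style dense-module detection
#'
#' Seed-and-grow molecular complex detection: vertices are weighted by their
#' closed-neighborhood k-core (\code{\link{mcode_weights}}); complexes are
#' grown from the highest-weight unseen seed outward, admitting neighbors
#' whose weight is at least \code{seed_weight * (1 - node_score_cutoff)}, up
#' to \code{max_depth} steps from the seed. Post-processing discards modules
#' without a k-core of order \code{k_core} and, with \code{haircut},
#' iteratively strips singly-connected members. Each node belongs to at most
#' one module; ties break by lexicographic node id so output is deterministic
#' regardless of insertion order. Module score is density x size.
#'
#' @param graph an igraph graph (edge scores are ignored here; filtering
#'   happens in \code{\link{load_ppi}}).
#' @param degree_cutoff minimum degree for a seed vertex (default 2).
#' @param node_score_cutoff admission slack relative to the seed weight
#'   (default 0.2, the published default).
#' @param k_core required core order of a reported module (default 2).
#' @param max_depth maximum growth distance from the seed (default 100).
#' @param haircut iteratively remove degree-1 members (default TRUE).
#' @param fluff optional neighbor fluffing (default FALSE; when TRUE,
#'   neighbors whose neighborhood density exceeds \code{fluff_density} are
#'   appended after haircut and may appear in several modules).
#' @param fluff_density density cutoff used when \code{fluff = TRUE}.
#' @return A list of class \code{mcode_result}; each element has
#'   \code{members} (sorted ids), \code{seed}, \code{score}, \code{size},
#'   \code{density}. Sorted by score desc, size desc, seed id.
#' @export
mcode_modules <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                          k_core = 2, max_depth = 100, haircut = TRUE,
                          fluff = FALSE, fluff_density = 0.5) {
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  w <- mcode_weights(graph)
  weights <- stats::setNames(w$weight, w$node_id)
  deg <- igraph::degree(graph)
  seeds <- w$node_id[deg[w$node_id] >= degree_cutoff]
  seeds <- seeds[order(-weights[seeds], seeds)]
  used <- character(0)
  modules <- list()
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                function(v) v$name)
  names(adj) <- igraph::V(graph)$name
  for (s in seeds) {
    if (s %in% used) next
    thresh <- weights[[s]] * (1 - node_score_cutoff)
    members <- s
    frontier <- s
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- sort(unique(unlist(adj[frontier], use.names = FALSE)))
      nxt <- setdiff(nxt, c(members, used))
      nxt <- nxt[weights[nxt] >= thresh]
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    used <- c(used, members)
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      # iterative degree-1 strip == restrict to the 2-core of the module
      cn <- igraph::coreness(sub)
      keep <- names(cn)[cn >= 2]
      if (length(keep) < 2) next
      sub <- igraph::induced_subgraph(graph, keep)
      members <- keep
    }
    if (fluff) {
      nbrs <- setdiff(sort(unique(unlist(adj[members], use.names = FALSE))),
                      members)
      nd <- vapply(nbrs, function(v) {
        nb <- c(v, adj[[v]])
        subv <- igraph::induced_subgraph(graph, nb)
        nv <- igraph::vcount(subv)
        if (nv < 2) 0 else 2 * igraph::ecount(subv) / (nv * (nv - 1))
      }, numeric(1))
      members <- c(members, nbrs[nd > fluff_density])
      sub <- igraph::induced_subgraph(graph, members)
    }
    nv <- length(members)
    dens <- if (nv < 2) 0 else 2 * igraph::ecount(sub) / (nv * (nv - 1))
    modules[[length(modules) + 1]] <-
      list(members = sort(members), seed = s, score = dens * nv,
           size = nv, density = dens)
  }
  if (length(modules) > 0) {
    ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
                 -vapply(modules, `[[`, numeric(1), "size"),
                 vapply(modules, `[[`, character(1), "seed"))
    modules <- modules[ord]
  }
  structure(modules, class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("mcode_result: %d module(s)\n", length(x)))
  for (i in seq_along(x)) {
    m <- x[[i]]
    cat(sprintf("  [%d] size %d, score %.3f, seed %s: %s%s\n", i, m$size,
                m$score, m$seed,
                paste(utils::head(m$members, 8), collapse = ", "),
                if (m$size > 8) ", ..." else ""))
  }
  invisible(x)
}

#' Write MCODE modules to a TSV
#'
#' Columns: \code{module_id}, \code{score}, \code{size}, \code{members}
#' (comma-separated).
#'
#' @param modules an \code{mcode_result}.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_mcode <- function(modules, path) {
  df <- data.frame(
    module_id = seq_along(modules),
    score = vapply(modules, `[[`, numeric(1), "score"),
    size = vapply(modules, `[[`, numeric(1), "size"),
    members = vapply(modules, function(m) paste(m$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
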