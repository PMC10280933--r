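#' Assemble the co-dysregulated lncRNA-miRNA-mRNA network
#'
#' A triple (l, m, g) enters the network iff (l, g) is a retained
#' co-expression pair, l -> m is in the lncRNA-miRNA table and m -> g is in
#' the miRNA-mRNA table. The network is the union of the included triples'
#' nodes and edges: only lncRNA-miRNA and miRNA-mRNA edges exist, never a
#' direct lncRNA-mRNA edge, and every node participates in at least one
#' triple. Assembly is order-independent; duplicate interaction rows are
#' de-duplicated with a logged count.
#'
#' @param pairs a \code{coexpr_pairs} data.frame (columns \code{lncrna_id},
#'   \code{mrna_id}).
#' @param lnc_mir data.frame with columns \code{source_id} (lncRNA) and
#'   \code{target_id} (miRNA).
#' @param mir_mrna data.frame with columns \code{source_id} (miRNA) and
#'   \code{target_id} (mRNA).
#' @param de_records optional \code{cerna_de} table; when given, per-node
#'   direction labels are attached.
#' @return An object of class \code{cerna_network}: list with
#'   \code{lncrna_nodes}, \code{mirna_nodes}, \code{mrna_nodes},
#'   \code{edges} (data.frame \code{from}, \code{to}, \code{type} in
#'   \code{lnc-mir}/\code{mir-mrna}), \code{triples} (data.frame),
#'   \code{node_attrs} (data.frame \code{node_id}, \code{type},
#'   \code{direction}).
#' @export
assemble_cerna <- function(pairs, lnc_mir, mir_mrna, de_records = NULL) {
  stopifnot(is.data.frame(pairs), is.data.frame(lnc_mir),
            is.data.frame(mir_mrna))
  lm <- unique(lnc_mir[, c("source_id", "target_id")])
  mm <- unique(mir_mrna[, c("source_id", "target_id")])
  ndup <- (nrow(lnc_mir) - nrow(lm)) + (nrow(mir_mrna) - nrow(mm))
  if (ndup > 0)
    message("assemble_cerna: dropped ", ndup, " duplicate interaction row(s)")
  if (nrow(pairs) == 0) {
    warning("assemble_cerna: no co-expression pairs; returning empty network")
    return(new_cerna_network(empty_triples(), de_records))
  }
  # shared-miRNA join: lnc->mir joined with mir->mrna, filtered to pairs
  merged <- merge(lm, mm, by.x = "target_id", by.y = "source_id",
                  suffixes = c("", ".y"))
  if (nrow(merged) == 0) return(new_cerna_network(empty_triples(), de_records))
  triples <- data.frame(lncrna_id = merged$source_id,
                        mirna_id = merged$target_id,
                        mrna_id = merged$target_id.y,
                        stringsAsFactors = FALSE)
  key <- paste(triples$lncrna_id, triples$mrna_id, sep = "\r")
  pkey <- paste(pairs$lncrna_id, pairs$mrna_id, sep = "\r")
  triples <- unique(triples[key %in% pkey, , drop = FALSE])
  triples <- triples[order(triples$lncrna_id, triples$mirna_id,
                           triples$mrna_id), , drop = FALSE]
  rownames(triples) <- NULL
  new_cerna_network(triples, de_records)
}

empty_triples <- function() {
  data.frame(lncrna_id = character(), mirna_id = character(),
             mrna_id = character(), stringsAsFactors = FALSE)
}

new_cerna_network <- function(triples, de_records = NULL) {
  n <- nrow(triples)
  edges <- unique(rbind(
    data.frame(from = triples$lncrna_id, to = triples$mirna_id,
               type = rep("lnc-mir", n), stringsAsFactors = FALSE),
    data.frame(from = triples$mirna_id, to = triples$mrna_id,
               type = rep("mir-mrna", n), stringsAsFactors = FALSE)))
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  lnc <- sort(unique(triples$lncrna_id))
  mir <- sort(unique(triples$mirna_id))
  mrna <- sort(unique(triples$mrna_id))
  ids <- c(lnc, mir, mrna)
  attrs <- data.frame(node_id = ids,
                      type = rep(c("lncRNA", "miRNA", "mRNA"),
                                 c(length(lnc), length(mir), length(mrna))),
                      direction = rep(NA_character_, length(ids)),
                      stringsAsFactors = FALSE)
  if (!is.null(de_records)) {
    idx <- match(attrs$node_id, de_records$gene_id)
    attrs$direction <- de_records$direction[idx]
  }
  structure(list(lncrna_nodes = lnc, mirna_nodes = mir, mrna_nodes = mrna,
                 edges = edges, triples = triples, node_attrs = attrs),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d lncRNAs, %d miRNAs, %d mRNAs; %d edges; %d triples\n",
              length(x$lncrna_nodes), length(x$mirna_nodes),
              length(x$mrna_nodes), nrow(x$edges), nrow(x$triples)))
  invisible(x)
}

#' Node degrees in the tripartite ceRNA network
#'
#' Degree counts incident edges; for a lncRNA this equals its number of
#' distinct miRNA partners (the mediating miRNAs), which is the degree the
#' hub-lncRNA gate is applied to.
#'
#' @param network a \code{cerna_network}.
#' @return Named integer vector, node_id -> degree, sorted by node_id.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  nodes <- c(network$lncrna_nodes, network$mirna_nodes, network$mrna_nodes)
  if (length(nodes) == 0) return(stats::setNames(integer(0), character(0)))
  deg <- table(factor(c(network$edges$from, network$edges$to), levels = nodes))
  out <- stats::setNames(as.integer(deg), names(deg))
  out[order(names(out))]
}

#' Hub lncRNAs by node degree
#'
#' @param network a \code{cerna_network}.
#' @param min_degree degree threshold (default 20).
#' @param comparator \code{">"} (strict, the default) or \code{">="}.
#' @return A data.frame of class \code{hub_set} with columns \code{node_id},
#'   \code{degree}, sorted by degree descending then node_id; attributes
#'   \code{threshold} and \code{comparator} record the gate used.
#' @export
hub_lncrnas <- function(network, min_degree = 20, comparator = ">") {
  stopifnot(inherits(network, "cerna_network"))
  deg <- node_degrees(network)
  deg <- deg[names(deg) %in% network$lncrna_nodes]
  hub_set(deg, min_degree, comparator)
}

hub_set <- function(degrees, threshold, comparator) {
  comparator <- match.arg(comparator, c(">", ">="))
  keep <- if (comparator == ">") degrees > threshold else degrees >= threshold
  degrees <- degrees[keep]
  ord <- order(-degrees, names(degrees))
  out <- data.frame(node_id = names(degrees)[ord],
                    degree = unname(degrees[ord]), stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "comparator") <- comparator
  class(out) <- c("hub_set", "data.frame")
  out
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set: %d node(s) with degree %s %s\n", nrow(x),
              attr(x, "comparator"), attr(x, "threshold")))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Restrict a ceRNA network to the triples of chosen lncRNAs
#'
#' @param network a \code{cerna_network}.
#' @param lncrna_ids lncRNA ids to keep; must all be network lncRNA nodes.
#' @return The restricted \code{cerna_network}.
#' @export
extract_subnetwork <- function(network, lncrna_ids) {
  stopifnot(inherits(network, "cerna_network"))
  unknown <- setdiff(lncrna_ids, network$lncrna_nodes)
  if (length(unknown) > 0)
    stop("extract_subnetwork: unknown lncRNA id(s): ",
         paste(unknown, collapse = ", "))
  triples <- network$triples[network$triples$lncrna_id %in% lncrna_ids, ,
                             drop = FALSE]
  rownames(triples) <- NULL
  net <- new_cerna_network(triples)
  # carry direction labels through the restriction
  idx <- match(net$node_attrs$node_id, network$node_attrs$node_id)
  net$node_attrs$direction <- network$node_attrs$direction[idx]
  net
}

#' Intersection of named gene sets (core-gene merge)
#'
#' Generic n-way intersection used to merge the mRNAs of the core ceRNA
#' subnetwork with the hub genes of the ceRNA-restricted and whole PPI
#' networks; any >= 2 named sets are accepted.
#'
#' @param sets a named list of >= 2 character vectors.
#' @return Sorted character vector of the common members, with a
#'   \code{membership} attribute: a data.frame (gene x set logical) over the
#'   union of all sets, suitable for Venn-style export.
#' @examples
#' core_mrnas(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                 c = c("C", "B")))
#' @export
core_mrnas <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stop("core_mrnas: need >= 2 named sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("core_mrnas: sets must be named")
  if (any(lengths(sets) == 0))
    stop("core_mrnas: sets must be non-empty")
  sets <- lapply(sets, unique)
  core <- sort(Reduce(intersect, sets))
  universe <- sort(Reduce(union, sets))
  membership <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) membership[[nm]] <- universe %in% sets[[nm]]
  attr(core, "membership") <- membership
  core
}

#' Export / import a ceRNA network as plain-text files
#'
#' \code{export_cerna} writes a Cytoscape SIF edge file
#' (\code{source  interaction  target}), a triples TSV, a node-attribute TSV,
#' and a GraphML file (node attributes: type, direction, degree).
#' \code{import_cerna} reads the triples and node attributes back into an
#' identical network.
#'
#' @param network a \code{cerna_network}.
#' @param dir output directory.
#' @return \code{export_cerna}: invisibly, the written file paths.
#' @export
export_cerna <- function(network, dir) {
  stopifnot(inherits(network, "cerna_network"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("export_cerna: cannot create ", dir)
  sif <- file.path(dir, "cerna_network.sif")
  writeLines(paste(network$edges$from, network$edges$type, network$edges$to,
                   sep = "\t"), sif)
  trip <- file.path(dir, "cerna_triples.tsv")
  utils::write.table(network$triples, trip, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- file.path(dir, "cerna_nodes.tsv")
  na <- network$node_attrs
  deg <- node_degrees(network)
  na$degree <- unname(deg[na$node_id])
  utils::write.table(na, nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  gml <- file.path(dir, "cerna_network.graphml")
  g <- cerna_igraph(network)
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(sif = sif, triples = trip, nodes = nodes, graphml = gml))
}

#' @rdname export_cerna
#' @export
import_cerna <- function(dir) {
  trip <- utils::read.delim(file.path(dir, "cerna_triples.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  net <- new_cerna_network(trip)
  nodes_path <- file.path(dir, "cerna_nodes.tsv")
  if (file.exists(nodes_path)) {
    na <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
    idx <- match(net$node_attrs$node_id, na$node_id)
    net$node_attrs$direction <- as.character(na$direction[idx])
  }
  net
}

#' Convert a ceRNA network to an igraph object
#'
#' Nodes carry \code{type}, \code{direction} and \code{degree} attributes;
#' edges carry \code{interaction}.
#'
#' @param network a \code{cerna_network}.
#' @return An undirected \code{igraph} graph.
#' @export
cerna_igraph <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  na <- network$node_attrs
  deg <- node_degrees(network)
  vertices <- data.frame(name = na$node_id, type = na$type,
                         direction = ifelse(is.na(na$direction), "na",
                                            na$direction),
                         degree = unname(deg[na$node_id]),
                         stringsAsFactors = FALSE)
  ed <- data.frame(from = network$edges$from, to = network$edges$to,
                   interaction = network$edges$type, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vertices)
}
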