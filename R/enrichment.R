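#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated \code{name}, \code{description},
#' then member genes. Duplicate members within a set are collapsed; a
#' duplicate set name or a line with fewer than 3 fields is an error naming
#' the offending line.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors, with a \code{descriptions}
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("read_gmt: malformed line ", i, " (fewer than 3 fields)")
    nm <- f[1]
    if (nm %in% names(sets))
      stop("read_gmt: duplicate set name '", nm, "' at line ", i)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("read_gmt: empty set '", nm, "' at line ", i)
    sets[[nm]] <- members
    descs[nm] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors; an optional
#'   \code{descriptions} attribute supplies the second column (default
#'   \code{"na"}).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query overlaps the set more than
#' expected under sampling without replacement from the universe:
#' p = P(overlap >= k) from the hypergeometric distribution with universe
#' size N, in-universe set size K and query size n. Benjamini-Hochberg
#' adjustment is applied across the tested sets of the collection.
#'
#' @param query character vector of gene ids; members outside the universe
#'   are dropped with a warning.
#' @param universe character vector of gene ids (the platform universe).
#' @param collection named list of gene sets (see \code{\link{read_gmt}}).
#' @param min_size,max_size set-size bounds (after intersection with the
#'   universe); sets outside are skipped.
#' @return A data.frame of class \code{ora_result} with columns
#'   \code{set_name}, \code{N}, \code{K}, \code{n}, \code{k}, \code{p},
#'   \code{q}, \code{fold_enrichment}, ordered by p then set name.
#' @export
ora <- function(query, universe, collection, min_size = 5, max_size = 500) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("ora: empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning("ora: dropping ", length(outside),
            " query gene(s) outside the universe")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(query, set))
    p <- hyper_tail_p(N, K, n, k)
    fe <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(set_name = nm, N = N, K = K, n = n, k = k, p = p,
               fold_enrichment = fe, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(set_name = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      q = numeric(), fold_enrichment = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ora_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name),
             c("set_name", "N", "K", "n", "k", "p", "q", "fold_enrichment")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

# upper-tail over-representation probability P(overlap >= k)
hyper_tail_p <- function(N, K, n, k) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walking down the ranked list, in-set genes ("hits") increment the running
#' sum by \code{|metric|^exponent} normalized by the in-set total, and
#' out-of-set genes ("misses") decrement it by \code{1 / (N - N_set)}. The
#' enrichment score is the signed maximum deviation from zero.
#'
#' @param ranked_genes character vector of gene ids, ranked (no duplicates).
#' @param rank_metric numeric vector of per-gene weights aligned to
#'   \code{ranked_genes} (or named by gene id).
#' @param gene_set character vector; must intersect the ranked list.
#' @param exponent weighting exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return The enrichment score, a single number in [-1, 1].
#' @export
gsea_es <- function(ranked_genes, rank_metric, gene_set, exponent = 1) {
  if (anyDuplicated(ranked_genes))
    stop("gsea_es: ranked list has duplicate genes")
  if (!is.null(names(rank_metric)))
    rank_metric <- rank_metric[ranked_genes]
  if (length(rank_metric) != length(ranked_genes))
    stop("gsea_es: rank_metric must align with ranked_genes")
  hit <- ranked_genes %in% gene_set
  if (!any(hit))
    stop("gsea_es: gene set does not intersect the ranked list")
  N <- length(ranked_genes)
  nh <- sum(hit)
  if (nh == N)
    stop("gsea_es: gene set covers the whole ranked list")
  w <- abs(rank_metric)^exponent
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' GSEA permutation p-value by gene-label reshuffling
#'
#' The null reassigns set membership uniformly over the ranked list (gene
#' permutation). With only a handful of samples per group, phenotype
#' permutation admits too few distinct label splits to be useful, so the gene
#' permutation null is the default and only null here. The two-sided
#' empirical p uses +1 smoothing: \code{(1 + #(|ES*| >= |ES|)) / (n_perm + 1)}.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100, default 1000).
#' @param seed integer seed for the permutation stream.
#' @return A list of class \code{gsea_result}: \code{set_size}, \code{es},
#'   \code{p}, \code{n_perm}, \code{seed}.
#' @export
gsea_permutation_p <- function(ranked_genes, rank_metric, gene_set,
                               exponent = 1, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("gsea_permutation_p: n_perm must be >= 100")
  es <- gsea_es(ranked_genes, rank_metric, gene_set, exponent)
  nh <- sum(ranked_genes %in% gene_set)
  N <- length(ranked_genes)
  if (!is.null(names(rank_metric)))
    rank_metric <- rank_metric[ranked_genes]
  w <- abs(rank_metric)^exponent
  miss_step <- 1 / (N - nh)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits_extreme <- 0L
  for (b in seq_len(n_perm)) {
    pos <- sort(sample.int(N, nh))
    es_b <- es_from_hits(pos, w, miss_step, N)
    if (abs(es_b) >= abs(es)) hits_extreme <- hits_extreme + 1L
  }
  structure(list(set_size = nh, es = es,
                 p = (1 + hits_extreme) / (n_perm + 1),
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "gsea_result")
}

# ES from sorted hit positions without materializing the full running sum:
# extremes of the walk occur immediately after a hit or immediately before
# the next hit.
es_from_hits <- function(pos, w, miss_step, N) {
  wh <- w[pos]
  cum_hit <- cumsum(wh) / sum(wh)
  j <- seq_along(pos)
  after_hit <- cum_hit - (pos - j) * miss_step
  before_hit <- c(0, cum_hit[-length(cum_hit)]) - (pos - j) * miss_step
  # the walk ends at zero after the last hit, so the extremes all lie
  # immediately after a hit or immediately before the next hit
  cand <- c(after_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: set size %d, ES = %.4f, p = %.4g (%d gene permutations, seed %d)\n",
              x$set_size, x$es, x$p, x$n_perm, x$seed))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
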