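#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return r in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: unequal lengths")
  if (length(x) < 3) stop("pearson: need >= 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("pearson: zero variance")
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact-null t transform \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)}
#' on n - 2 degrees of freedom. \code{|r| = 1} returns p = 0 by convention.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @return Two-sided p in [0, 1].
#' @export
pearson_pvalue <- function(r, n) {
  if (n < 3) stop("pearson_pvalue: need n >= 3")
  if (abs(r) > 1 + 1e-12) stop("pearson_pvalue: |r| > 1")
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' lncRNA-mRNA co-expression screening among differential genes
#'
#' Correlates every differential lncRNA against every differential mRNA across
#' all samples (case and control pooled) and keeps pairs with
#' \code{r > r_min} (strict, signed; or \code{|r| > r_min} with
#' \code{use_absolute}) and \code{p < p_max}. Genes with zero variance across
#' samples are skipped with a message rather than an error.
#'
#' With the default study design (n = 8 samples) the r > 0.97 gate already
#' implies p far below 0.01, but the p gate is enforced as stated.
#'
#' @param de_records a \code{cerna_de} table from
#'   \code{\link{differential_expression}}.
#' @param matrix the \code{\link{expression_matrix}} the records came from.
#' @param r_min correlation gate, strict \code{>} (default 0.97).
#' @param p_max p-value gate, strict \code{<} (default 0.01).
#' @param use_absolute gate on \code{|r|} instead of signed r (default FALSE).
#' @return A data.frame of class \code{coexpr_pairs} with columns
#'   \code{lncrna_id}, \code{mrna_id}, \code{r}, \code{p}, \code{n}, ordered
#'   by (lncrna_id, mrna_id).
#' @export
coexpression_pairs <- function(de_records, matrix, r_min = 0.97,
                               p_max = 0.01, use_absolute = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"), is.data.frame(de_records))
  dif <- de_records[de_records$direction != "ns", ]
  lncs <- sort(dif$gene_id[dif$biotype == "lncRNA"])
  mrnas <- sort(dif$gene_id[dif$biotype == "mRNA"])
  if (length(lncs) == 0 || length(mrnas) == 0)
    stop("coexpression_pairs: need >= 1 differential lncRNA and >= 1 differential mRNA")
  vals <- matrix$values
  n <- ncol(vals)
  sds <- apply(vals[c(lncs, mrnas), , drop = FALSE], 1, stats::sd)
  zero <- names(sds)[sds == 0]
  if (length(zero) > 0) {
    message("coexpression_pairs: skipping ", length(zero),
            " zero-variance gene(s): ", paste(utils::head(zero, 5), collapse = ", "))
    lncs <- setdiff(lncs, zero)
    mrnas <- setdiff(mrnas, zero)
  }
  if (length(lncs) == 0 || length(mrnas) == 0)
    return(empty_coexpr())
  rmat <- stats::cor(t(vals[lncs, , drop = FALSE]),
                     t(vals[mrnas, , drop = FALSE]))
  rv <- pmin(1, pmax(-1, as.vector(rmat)))
  pv <- vapply(rv, pearson_pvalue, numeric(1), n = n)
  out <- data.frame(lncrna_id = rep(lncs, times = length(mrnas)),
                    mrna_id = rep(mrnas, each = length(lncs)),
                    r = rv, p = pv, n = n, stringsAsFactors = FALSE)
  gate <- if (use_absolute) abs(out$r) > r_min else out$r > r_min
  out <- out[gate & out$p < p_max, ]
  out <- out[order(out$lncrna_id, out$mrna_id), ]
  rownames(out) <- NULL
  class(out) <- c("coexpr_pairs", "data.frame")
  out
}

empty_coexpr <- function() {
  out <- data.frame(lncrna_id = character(), mrna_id = character(),
                    r = numeric(), p = numeric(), n = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("coexpr_pairs", "data.frame")
  out
}

#' @export
print.coexpr_pairs <- function(x, ...) {
  cat(sprintf("coexpr_pairs: %d retained lncRNA-mRNA pair(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  invisible(x)
}
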