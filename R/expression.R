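#' Expression matrix with biotypes and sample groups
#'
#' Light container for a normalized log2 expression matrix (genes x samples)
#' carrying a per-gene biotype (\code{"mRNA"} or \code{"lncRNA"}) and a
#' per-sample group label (\code{"case"} or \code{"control"}). This is the
#' single source for differential expression and co-expression screening.
#'
#' @param values numeric matrix of log2 intensities, genes in rows, samples in
#'   columns; rownames are gene ids, colnames are sample ids.
#' @param biotype character vector, one of \code{"mRNA"}/\code{"lncRNA"} per
#'   gene, in row order.
#' @param groups character vector, one of \code{"case"}/\code{"control"} per
#'   sample, in column order.
#' @return An object of class \code{expr_matrix}: a list with elements
#'   \code{values}, \code{biotype}, \code{groups}.
#' @examples
#' m <- matrix(rnorm(8, 8), 2, 4,
#'             dimnames = list(c("G1", "L1"), paste0("s", 1:4)))
#' expression_matrix(m, c("mRNA", "lncRNA"), rep(c("case", "control"), 2))
#' @export
expression_matrix <- function(values, biotype, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("all expression values must be finite; non-finite values are rejected, not imputed")
  biotype <- as.character(biotype)
  groups <- as.character(groups)
  if (length(biotype) != nrow(values))
    stop("'biotype' must have one entry per gene")
  if (!all(biotype %in% c("mRNA", "lncRNA")))
    stop("biotype must be 'mRNA' or 'lncRNA'")
  if (length(groups) != ncol(values))
    stop("'groups' must have one entry per sample")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (any(table(factor(groups, levels = c("case", "control"))) < 2))
    stop("each group needs at least 2 samples")
  structure(list(values = values, biotype = biotype, groups = groups),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d genes (%d mRNA, %d lncRNA) x %d samples (%d case, %d control)\n",
    nrow(x$values), sum(x$biotype == "mRNA"), sum(x$biotype == "lncRNA"),
    ncol(x$values), sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and sample sheet from TSV
#'
#' The matrix TSV has columns \code{gene_id}, \code{biotype}, then one column
#' per sample; the sample sheet has columns \code{sample_id}, \code{group}.
#'
#' @param matrix_path path to the expression TSV.
#' @param samples_path path to the sample-sheet TSV.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(matrix_path, samples_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "biotype") %in% names(tab)))
    stop("matrix TSV must have 'gene_id' and 'biotype' columns")
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ss)))
    stop("sample sheet must have 'sample_id' and 'group' columns")
  sample_cols <- setdiff(names(tab), c("gene_id", "biotype"))
  if (!setequal(sample_cols, ss$sample_id))
    stop("sample columns and sample sheet disagree")
  vals <- as.matrix(tab[, ss$sample_id, drop = FALSE])
  rownames(vals) <- tab$gene_id
  expression_matrix(vals, tab$biotype, ss$group)
}

#' Write an expression matrix and sample sheet to TSV
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param matrix_path,samples_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(x, matrix_path, samples_path) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(gene_id = rownames(x$values), biotype = x$biotype,
                    x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss <- data.frame(sample_id = colnames(x$values), group = x$groups,
                   stringsAsFactors = FALSE)
  utils::write.table(ss, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, samples_path))
}
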