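#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); ddCt = mean dCt(case) -
#' mean dCt(control); the group fold change is 2^-ddCt. Per-sample relative
#' quantities 2^-(dCt - mean dCt(control)) are emitted alongside for plotting
#' and group testing. Groups are treated as unpaired.
#'
#' @param records data.frame with columns \code{sample_id}, \code{group}
#'   (\code{case}/\code{control}), \code{gene_id}, \code{ct_target},
#'   \code{ct_reference}.
#' @param gene_id the target gene to quantify.
#' @return A list of class \code{ddct_result}: \code{per_sample} (data.frame
#'   \code{sample_id}, \code{group}, \code{dct}, \code{rq}), \code{ddct},
#'   \code{fold}.
#' @examples
#' recs <- data.frame(sample_id = c("c1", "n1"),
#'                    group = c("case", "control"), gene_id = "G",
#'                    ct_target = c(24, 22), ct_reference = c(20, 20))
#' ddct_fold(recs, "G")$fold  # 0.25
#' @export
ddct_fold <- function(records, gene_id) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "group", "gene_id", "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop("ddct_fold: records need columns ", paste(need, collapse = ", "))
  recs <- records[records$gene_id == gene_id, , drop = FALSE]
  if (nrow(recs) == 0) stop("ddct_fold: no records for gene ", gene_id)
  miss <- !is.finite(recs$ct_reference) | recs$ct_reference <= 0
  if (any(miss))
    stop("ddct_fold: missing/invalid reference Ct for sample(s) ",
         paste(recs$sample_id[miss], collapse = ", "))
  if (any(!is.finite(recs$ct_target) | recs$ct_target <= 0))
    stop("ddct_fold: invalid target Ct values")
  if (!all(c("case", "control") %in% recs$group))
    stop("ddct_fold: need >= 1 record per group for gene ", gene_id)
  dct <- recs$ct_target - recs$ct_reference
  mean_ctrl <- mean(dct[recs$group == "control"])
  mean_case <- mean(dct[recs$group == "case"])
  ddct <- mean_case - mean_ctrl
  per_sample <- data.frame(sample_id = recs$sample_id, group = recs$group,
                           dct = dct, rq = 2^(-(dct - mean_ctrl)),
                           stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, ddct = ddct, fold = 2^(-ddct)),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt: ddCt = %.3f, fold change (case vs control) = %.4g\n",
              x$ddct, x$fold))
  invisible(x)
}

#' Mann-Whitney U test (exact or normal approximation)
#'
#' Exact two-sided p when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. The branch taken is reported in \code{method}.
#'
#' @param x,y numeric vectors, non-empty.
#' @return A list of class \code{mwu_result}: \code{u} (U statistic for x),
#'   \code{p} (two-sided, in (0, 1]), \code{method}
#'   (\code{"exact"} or \code{"normal-approx"}).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney: both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    # every observation tied: no evidence of a shift by construction
    return(structure(list(u = length(x) * length(y) / 2, p = 1,
                          method = "normal-approx"), class = "mwu_result"))
  }
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(u = unname(ht$statistic), p = min(1, ht$p.value),
                 method = if (exact) "exact" else "normal-approx"),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %.4g (%s)\n",
              x$u, x$p, x$method))
  invisible(x)
}

#' qPCR group comparison for every gene in a Ct table
#'
#' Runs \code{\link{ddct_fold}} and \code{\link{mann_whitney}} (on the
#' per-sample relative quantities) per gene.
#'
#' @param records a Ct table (see \code{\link{ddct_fold}}) or a path to such
#'   a TSV.
#' @return A data.frame with one row per gene: \code{gene_id}, \code{ddct},
#'   \code{fold}, \code{u}, \code{p}, \code{method}.
#' @export
qpcr_compare <- function(records) {
  if (is.character(records) && length(records) == 1)
    records <- utils::read.delim(records, stringsAsFactors = FALSE)
  genes <- sort(unique(records$gene_id))
  rows <- lapply(genes, function(g) {
    dd <- ddct_fold(records, g)
    ps <- dd$per_sample
    mw <- mann_whitney(ps$rq[ps$group == "case"],
                       ps$rq[ps$group == "control"])
    data.frame(gene_id = g, ddct = dd$ddct, fold = dd$fold, u = mw$u,
               p = mw$p, method = mw$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
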