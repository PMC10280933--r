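#' Linear fold change from log2 group values
#'
#' Fold change is the ratio of geometric group means on the linear scale,
#' i.e. \code{2^(mean(case) - mean(control))} on log2 data — the microarray
#' convention.
#'
#' @param case_values,control_values numeric log2 intensities.
#' @return Strictly positive linear fold change.
#' @examples
#' fold_change(c(5, 5), c(3, 3))  # 4
#' @export
fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0)
    stop("fold_change: both groups must be non-empty")
  if (!all(is.finite(case_values)) || !all(is.finite(control_values)))
    stop("fold_change: values must be finite")
  2^(mean(case_values) - mean(control_values))
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom, as used for
#' the per-gene case/control comparison. Degenerate zero-variance inputs
#' follow a documented convention: both groups constant with equal means gives
#' p = 1; both constant with unequal means gives p = 0.
#'
#' @param x,y numeric vectors, at least 2 values each.
#' @return A list with \code{t}, \code{p} (two-sided), \code{df}.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t_test: need >= 2 values per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Two-group differential expression with fold-change and p-value gates
#'
#' Tests every gene case vs control with Welch's t on the log2 values, and
#' calls direction \code{"up"} when fold change >= \code{fc_up} and
#' p < \code{alpha}, \code{"down"} when fold change <= \code{fc_down} and
#' p < \code{alpha}, otherwise \code{"ns"}. Both fold-change boundaries are
#' inclusive. No multiple-testing correction is applied at this stage: the
#' downstream gates use raw p-values.
#'
#' @param matrix an \code{\link{expression_matrix}}.
#' @param fc_up,fc_down linear fold-change gates (defaults 2.0 and 0.5).
#' @param alpha raw p-value gate (default 0.05).
#' @return A data.frame of class \code{cerna_de} with columns \code{gene_id},
#'   \code{biotype}, \code{fc}, \code{log2fc}, \code{p}, \code{direction},
#'   ordered by biotype then gene_id.
#' @export
differential_expression <- function(matrix, fc_up = 2.0, fc_down = 0.5,
                                    alpha = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (fc_up <= 0 || fc_down <= 0 || fc_down > fc_up)
    stop("differential_expression: need 0 < fc_down <= fc_up")
  case <- matrix$values[, matrix$groups == "case", drop = FALSE]
  ctrl <- matrix$values[, matrix$groups == "control", drop = FALSE]
  if (ncol(case) < 2 || ncol(ctrl) < 2)
    stop("differential_expression: each group needs >= 2 samples")
  log2fc <- rowMeans(case) - rowMeans(ctrl)
  p <- vapply(seq_len(nrow(case)),
              function(i) welch_t_test(case[i, ], ctrl[i, ])$p,
              numeric(1))
  fc <- 2^log2fc
  direction <- rep("ns", length(fc))
  direction[fc >= fc_up & p < alpha] <- "up"
  direction[fc <= fc_down & p < alpha] <- "down"
  out <- data.frame(gene_id = rownames(matrix$values),
                    biotype = matrix$biotype,
                    fc = fc, log2fc = log2fc, p = p, direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$biotype, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("cerna_de", "data.frame")
  out
}

#' Up/down counts per biotype for a differential-expression table
#'
#' @param de a \code{cerna_de} data.frame.
#' @return A data.frame with columns \code{biotype}, \code{up}, \code{down},
#'   \code{ns}.
#' @export
de_summary <- function(de) {
  stopifnot(is.data.frame(de), all(c("biotype", "direction") %in% names(de)))
  tb <- table(factor(de$biotype, levels = c("lncRNA", "mRNA")),
              factor(de$direction, levels = c("up", "down", "ns")))
  data.frame(biotype = rownames(tb), up = tb[, "up"], down = tb[, "down"],
             ns = tb[, "ns"], row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cerna_de <- function(x, ...) {
  s <- de_summary(x)
  cat("Differential expression calls:\n")
  print.data.frame(s)
  cat(sprintf("(%d genes tested)\n", nrow(x)))
  invisible(x)
}
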