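#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Assemble an expression SummarizedExperiment
#'
#' Wraps a genes-by-samples matrix of linear-scale expression values
#' (RPKM-like, non-negative) and per-sample metadata into a
#' \link[SummarizedExperiment]{SummarizedExperiment} with assay name
#' \code{"expr"}.
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples.
#' @param sampleMeta data.frame with one row per sample; typically columns
#'   \code{tissue}, \code{treatment} (control/stress), \code{genotype}.
#'   Rownames or a \code{sample_id} column must match the matrix columns.
#' @return a SummarizedExperiment.
#' @export
makeExpressionSet <- function(values, sampleMeta) {
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if ("sample_id" %in% names(sampleMeta))
    rownames(sampleMeta) <- sampleMeta$sample_id
  if (!all(colnames(values) %in% rownames(sampleMeta)))
    stop("sample metadata missing for: ",
         paste(setdiff(colnames(values), rownames(sampleMeta)),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  sampleMeta <- sampleMeta[colnames(values), , drop = FALSE]
  SummarizedExperiment(assays = list(expr = values),
                       colData = S4Vectors::DataFrame(sampleMeta))
}

#' Read an expression TSV and its sample-metadata TSV
#'
#' Expression file: first column \code{gene_id}, remaining columns one per
#' sample. Metadata file: columns \code{sample_id}, \code{tissue},
#' \code{treatment}, \code{genotype}.
#'
#' @param exprPath,metaPath file paths.
#' @return a SummarizedExperiment (see [makeExpressionSet()]).
#' @export
readExpression <- function(exprPath, metaPath) {
  df <- utils::read.delim(exprPath, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- utils::read.delim(metaPath, comment.char = "#",
                            stringsAsFactors = FALSE)
  makeExpressionSet(m, meta)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs do not raise: two constant
#' equal groups return `t = 0, p = 1`; two constant unequal groups return
#' `p = 0`; both are flagged via the \code{degenerate} element.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @return named list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite")
  res <- rowWelch(matrix(a, nrow = 1), matrix(b, nrow = 1))
  list(t = res$t[1], df = res$df[1], p = res$p[1],
       degenerate = res$degenerate[1])
}

# Vectorised row-wise Welch t over two sample matrices (genes in rows).
rowWelch <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- se2 == 0
  t[degenerate & ma == mb] <- 0
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  df[degenerate] <- NA_real_
  list(t = t, df = df, p = p, degenerate = degenerate)
}

# Pooled-variance (Student) variant, behind the varEqual flag of runDE().
rowStudent <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  sp2 <- (rowSums((A - ma)^2) + rowSums((B - mb)^2)) / (na + nb - 2)
  se2 <- sp2 * (1 / na + 1 / nb)
  t <- (ma - mb) / sqrt(se2)
  df <- rep(na + nb - 2, length(t))
  degenerate <- se2 == 0
  t[degenerate & ma == mb] <- 0
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Two-group differential expression with fold-change gating
#'
#' For each gene, tests the contrast's two sample groups with a (Welch, by
#' default) t-test and computes the fold change of linear-scale group means
#' (a pseudo-count of 1e-9 guards zero means). The test is run on
#' `log2(x + 1)`-transformed values by default, the usual variance-stabilising
#' choice for RPKM-like data; set `testLog = FALSE` to test the linear values.
#' p-values are BH-adjusted across genes, and each gene is classified
#' \code{up} / \code{down} / \code{ns}: significant (on q if `useFDR`, else
#' on p) and |log2 fold change| at or beyond the fold threshold.
#'
#' @param se SummarizedExperiment from [makeExpressionSet()].
#' @param contrast character vector \code{c(attribute, levelA, levelB)}:
#'   the colData attribute to group by, the numerator level (e.g. "stress")
#'   and the denominator level (e.g. "control"). Each level must select at
#'   least 2 samples.
#' @param alpha significance threshold (default 0.01).
#' @param foldThreshold minimum linear fold change (default 2).
#' @param useFDR gate significance on BH-adjusted q (default TRUE).
#' @param varEqual use the pooled-variance t instead of Welch.
#' @param testLog run the t-test on log2(x + 1) values (default TRUE).
#' @return data.frame ordered by ascending p (ties by gene id) with columns
#'   \code{gene_id}, \code{log2fc}, \code{t}, \code{df}, \code{p}, \code{q},
#'   \code{class}.
#' @export
runDE <- function(se, contrast, alpha = 0.01, foldThreshold = 2,
                  useFDR = TRUE, varEqual = FALSE, testLog = TRUE) {
  stopifnot(length(contrast) == 3L)
  attribute <- contrast[1]; levelA <- contrast[2]; levelB <- contrast[3]
  cd <- colData(se)
  if (!attribute %in% names(cd))
    stop("unknown grouping attribute: ", attribute)
  grp <- as.character(cd[[attribute]])
  selA <- grp == levelA; selB <- grp == levelB
  if (sum(selA) < 2L)
    stop("contrast level '", levelA, "' selects fewer than 2 samples")
  if (sum(selB) < 2L)
    stop("contrast level '", levelB, "' selects fewer than 2 samples")
  x <- assay(se, "expr")
  A <- x[, selA, drop = FALSE]; B <- x[, selB, drop = FALSE]
  eps <- 1e-9
  log2fc <- log2((rowMeans(A) + eps) / (rowMeans(B) + eps))
  TA <- if (testLog) log2(A + 1) else A
  TB <- if (testLog) log2(B + 1) else B
  tt <- if (varEqual) rowStudent(TA, TB) else rowWelch(TA, TB)
  q <- bhAdjust(pmax(tt$p, .Machine$double.xmin))
  out <- data.frame(gene_id = rownames(x), log2fc = log2fc, t = tt$t,
                    df = tt$df, p = tt$p, q = q, class = "ns",
                    stringsAsFactors = FALSE)
  sig <- if (useFDR) out$q < alpha else out$p < alpha
  lfcMin <- log2(foldThreshold)
  # up takes precedence at a degenerate fold threshold of 1 (lfcMin = 0)
  out$class[sig & out$log2fc <= -lfcMin] <- "down"
  out$class[sig & out$log2fc >= lfcMin] <- "up"
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "foldThreshold") <- foldThreshold
  attr(out, "useFDR") <- useFDR
  out
}

#' Recount volcano classes under new thresholds
#'
#' Pure reclassification of a [runDE()] result: no statistic is recomputed,
#' only the significance and fold gates are reapplied. Class counts always
#' sum to the number of genes.
#'
#' @param results a [runDE()] result data.frame.
#' @param alpha significance threshold.
#' @param foldThreshold minimum linear fold change.
#' @param useFDR gate on q (default) or on raw p.
#' @return named integer vector with elements \code{up}, \code{down},
#'   \code{ns}.
#' @export
volcanoClassify <- function(results, alpha, foldThreshold, useFDR = TRUE) {
  sig <- if (useFDR) results$q < alpha else results$p < alpha
  lfcMin <- log2(foldThreshold)
  isUp <- sig & results$log2fc >= lfcMin
  isDown <- sig & results$log2fc <= -lfcMin & !isUp
  c(up = sum(isUp), down = sum(isDown),
    ns = nrow(results) - sum(isUp) - sum(isDown))
}
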