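#' Log-normalize a UMI count matrix
#'
#' Standard library-size normalization: each cell's counts are scaled to a
#' common total and log1p-transformed, `ln(1 + count * scale_total /
#' cell_total)`.
#'
#' @param counts Sparse gene x cell UMI matrix.
#' @param scale_total Target per-cell total (default 1e4).
#' @return Sparse gene x cell matrix of log-normalized values.
#' @export
lognormalize <- function(counts, scale_total = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("cells with zero total counts cannot be normalized: ",
         sum(totals <= 0), " cell(s)", call. = FALSE)
  m <- methods::as(counts, "CsparseMatrix")
  sf <- scale_total / totals
  m@x <- log1p(m@x * rep.int(sf, diff(m@p)))
  m
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For each gene, a two-sided rank-sum test (normal approximation with tie
#' and continuity correction - the approximation scRNA-seq tools apply at
#' these group sizes), the Seurat-convention average log2 fold change
#' `log2(mean(expm1(a)) + 1) - log2(mean(expm1(b)) + 1)` (positive = up in
#' group A), detection fractions, and BH-adjusted p-values.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param group_a,group_b Column names (cell ids) of the two groups; each
#'   needs >= 2 cells.
#' @param genes Genes to test (default: all rows).
#' @return data.frame with `gene`, `avg_log2fc`, `p_raw`, `p_adj`,
#'   `pct_a`, `pct_b`, sorted by `p_raw`.
#' @export
wilcoxon_de <- function(norm, group_a, group_b, genes = rownames(norm)) {
  if (length(genes) == 0L)
    stop("empty gene list", call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("both groups need at least 2 cells (got ", length(group_a),
         " and ", length(group_b), ")", call. = FALSE)
  a <- as.matrix(norm[genes, group_a, drop = FALSE])
  b <- as.matrix(norm[genes, group_b, drop = FALSE])
  na <- ncol(a); nb <- ncol(b); n <- na + nb

  p_raw <- vapply(seq_along(genes), function(g) {
    rank_sum_p(a[g, ], b[g, ])
  }, numeric(1))

  mean_a <- rowMeans(expm1(a))
  mean_b <- rowMeans(expm1(b))
  avg_log2fc <- log2(mean_a + 1) - log2(mean_b + 1)

  out <- data.frame(
    gene = genes,
    avg_log2fc = avg_log2fc,
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    pct_a = rowMeans(a > 0),
    pct_b = rowMeans(b > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p_raw), , drop = FALSE]
}

# two-sided rank-sum p, normal approximation with tie correction and
# continuity correction (the classic asymptotic wilcox.test path)
rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U of group A
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure: sorted p-values are scaled by `m / rank`
#' and a cumulative minimum is taken from the largest rank down, clipped
#' at 1.  The result is invariant to input ordering.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values aligned to the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Select differentially expressed genes
#'
#' Keeps genes with BH-adjusted p strictly below `p_adj_cut` and absolute
#' average log2 fold change strictly above `log2fc_cut`.  The two cut
#' regimes used for condition comparisons (|log2FC| > 0.26, i.e. FC >
#' ~1.2) and subtype comparisons (|log2FC| > ~1.58, i.e. FC > ~3) are both
#' just parameter choices here.  An optional `exclude` list supports the
#' "unique to treatment" subtraction: genes passing the same cuts in a
#' reference comparison are removed.
#'
#' @param results A [wilcoxon_de()] table.
#' @param p_adj_cut Adjusted-p cutoff (strict `<`).
#' @param log2fc_cut Absolute log2 fold-change cutoff (strict `>`).
#' @param exclude Character vector of genes to subtract.
#' @return Character vector of selected gene names.
#' @export
select_de_genes <- function(results, p_adj_cut = 0.05, log2fc_cut = 0.26,
                            exclude = NULL) {
  stopifnot(log2fc_cut >= 0)
  sel <- results$p_adj < p_adj_cut & abs(results$avg_log2fc) > log2fc_cut
  genes <- results$gene[sel]
  setdiff(genes, exclude)
}

#' Run pairwise-condition differential expression within each cell type
#'
#' For every cell type and every ordered condition pair, runs
#' [wilcoxon_de()] on the log-normalized layer.  Comparisons where either
#' group has fewer than `min_cells` cells are skipped and logged in the
#' result.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param cells Metadata with `cell_id`, `condition`, and the grouping
#'   column.
#' @param groupby Metadata column defining the strata (default
#'   `cell_type`).
#' @param contrasts List of `c(group_a_condition, group_b_condition)`
#'   pairs; default: all unordered condition pairs, first-listed condition
#'   as group A.
#' @param genes Genes to test.
#' @param min_cells Minimum cells per group (default 3).
#' @return Named list (by `"<type>|<condA>_vs_<condB>"`) of DE tables;
#'   skipped comparisons carry `NULL` with reasons in
#'   `attr(, "skipped")`.
#' @export
de_by_cell_type <- function(norm, cells, groupby = "cell_type",
                            contrasts = NULL, genes = rownames(norm),
                            min_cells = 3L) {
  conds <- unique(cells$condition)
  if (is.null(contrasts)) {
    cc <- utils::combn(conds, 2, simplify = FALSE)
    contrasts <- cc
  }
  res <- list()
  skipped <- character(0)
  for (ct in unique(cells[[groupby]])) {
    in_ct <- cells[[groupby]] == ct & !is.na(cells[[groupby]])
    for (pair in contrasts) {
      key <- sprintf("%s|%s_vs_%s", ct, pair[1], pair[2])
      ga <- cells$cell_id[in_ct & cells$condition == pair[1]]
      gb <- cells$cell_id[in_ct & cells$condition == pair[2]]
      if (length(ga) < min_cells || length(gb) < min_cells) {
        skipped <- c(skipped, key)
        next
      }
      res[[key]] <- wilcoxon_de(norm, ga, gb, genes)
    }
  }
  attr(res, "skipped") <- skipped
  res
}
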