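#' Flag cells with high mitochondrial expression
#'
#' A cell fails when the percentage of its UMIs mapping to mitochondrial
#' genes is strictly above the cutoff (default 12.5%, applied uniformly
#' across replicates).
#'
#' @param cells data.frame with a `mito_pct` column on the 0-100 scale.
#' @param cutoff_pct Percentage cutoff in (0, 100].
#' @return Logical vector, `TRUE` = flagged for removal.
#' @export
flag_high_mito <- function(cells, cutoff_pct = 12.5) {
  stopifnot(cutoff_pct > 0, cutoff_pct <= 100)
  if (is.null(cells$mito_pct))
    stop("cells lack a mito_pct column", call. = FALSE)
  cells$mito_pct > cutoff_pct
}

#' Flag suspected doublets by extreme total UMI count
#'
#' Within each (replicate, condition) group of size n, the k = round(rate
#' x n) cells with the highest UMI totals are flagged (half-up rounding;
#' the expected doublet rate of droplet chemistry, 0.9%, is the default).
#' Ties at the k-th rank are broken by lexicographic cell id so the result
#' is deterministic and permutation-invariant.
#'
#' @param cells data.frame with `umi_count`, `replicate`, `condition`,
#'   `cell_id`.
#' @param rate Fraction of each group to flag, in \[0, 1).
#' @param per_1000 If `TRUE`, scale the rate by group size / 1000
#'   (the "0.9% per 1000 cells" doublet model); default `FALSE` applies
#'   the flat rate.
#' @return Logical vector aligned to `cells` rows.
#' @export
flag_umi_doublets <- function(cells, rate = 0.009, per_1000 = FALSE) {
  stopifnot(rate >= 0, rate < 1)
  group <- paste(cells$replicate, cells$condition, sep = "\r")
  flag <- logical(nrow(cells))
  for (g in unique(group)) {
    idx <- which(group == g)
    r <- if (per_1000) rate * length(idx) / 1000 else rate
    k <- floor(r * length(idx) + 0.5)  # half-up
    if (k <= 0L) next
    ord <- idx[order(-cells$umi_count[idx], cells$cell_id[idx])]
    flag[ord[seq_len(min(k, length(idx)))]] <- TRUE
  }
  flag
}

#' Flag cells with low feature (gene) detection
#'
#' A cell fails when its detected-gene count is strictly below the
#' supplied cutoff.  Deriving the cutoff (e.g. from cells whose type could
#' not be predicted) is upstream of this package; the number is a config
#' value.
#'
#' @param cells data.frame with a `gene_count` column.
#' @param cutoff Minimum detected-gene count (cells at the cutoff pass).
#' @return Logical vector, `TRUE` = flagged.
#' @export
flag_low_features <- function(cells, cutoff) {
  stopifnot(cutoff >= 0)
  if (is.null(cells$gene_count))
    stop("cells lack a gene_count column", call. = FALSE)
  cells$gene_count < cutoff
}

#' Apply the full cell-level QC cascade
#'
#' Removes the union of the three QC failures (high mitochondrial
#' percentage, top-UMI doublets, low feature detection) first, then cells
#' flagged as pruned (low-confidence reference typing), matching the
#' published ordering where QC counts are quoted before pruning.  Each
#' criterion is also counted independently, so the union can be audited
#' against inclusion-exclusion bounds.
#'
#' @param cells Per-cell metadata data.frame (see [flag_high_mito()],
#'   [flag_umi_doublets()], [flag_low_features()]; a logical `pruned`
#'   column is honoured when present).
#' @param mito_cutoff_pct,doublet_rate,feature_cutoff Stage parameters.
#' @param per_1000 Passed to [flag_umi_doublets()].
#' @return list with `kept` (data.frame) and `report` (named list:
#'   `n_input`, `n_fail_mito`, `n_fail_umi`, `n_fail_feature`,
#'   `n_fail_pruned`, `n_fail_union`, `n_kept`).
#' @export
apply_cell_filters <- function(cells, mito_cutoff_pct = 12.5,
                               doublet_rate = 0.009, feature_cutoff = 0,
                               per_1000 = FALSE) {
  f_mito <- flag_high_mito(cells, mito_cutoff_pct)
  f_umi <- flag_umi_doublets(cells, doublet_rate, per_1000)
  f_feat <- flag_low_features(cells, feature_cutoff)
  f_union <- f_mito | f_umi | f_feat
  pruned <- if (!is.null(cells$pruned)) as.logical(cells$pruned)
            else logical(nrow(cells))
  f_pruned <- pruned & !f_union  # pruned removal applied after QC union
  kept <- cells[!(f_union | f_pruned), , drop = FALSE]
  report <- list(n_input = nrow(cells),
                 n_fail_mito = sum(f_mito),
                 n_fail_umi = sum(f_umi),
                 n_fail_feature = sum(f_feat),
                 n_fail_pruned = sum(f_pruned),
                 n_fail_union = sum(f_union),
                 n_kept = nrow(kept))
  list(kept = kept, report = report)
}

#' Filter lowly expressed genes by per-replicate detection
#'
#' A gene is kept only when, in EVERY replicate, it is detected with a UMI
#' count of at least `min_umi` in at least `min_cells` cells.
#'
#' @param counts Sparse gene x cell matrix (columns must cover every
#'   replicate present in `cells`).
#' @param cells data.frame with `cell_id` and `replicate` for the kept
#'   cells; columns of `counts` are matched by `cell_id`.
#' @param min_cells Minimum qualifying cells per replicate.
#' @param min_umi Minimum UMI count for a cell to qualify.
#' @return Character vector of kept gene names.
#' @export
filter_genes <- function(counts, cells, min_cells = 2L, min_umi = 2L) {
  if (is.null(colnames(counts)) || !all(cells$cell_id %in% colnames(counts)))
    stop("counts columns do not cover the supplied cells", call. = FALSE)
  m <- counts[, cells$cell_id, drop = FALSE]
  reps <- sort(unique(cells$replicate))
  detected <- m >= min_umi
  keep <- rep(TRUE, nrow(m))
  for (r in reps) {
    cols <- cells$replicate == r
    if (!any(cols))
      stop("replicate ", r, " has zero cells; gene criterion undefined",
           call. = FALSE)
    keep <- keep &
      (Matrix::rowSums(detected[, cols, drop = FALSE]) >= min_cells)
  }
  rownames(m)[keep]
}
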