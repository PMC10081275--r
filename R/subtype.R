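#' Assign basal/luminal subtype from marker detection
#'
#' The marker rule of urothelial subtyping: cells expressing any level of
#' the basal keratin (Krt5) but not the luminal marker (Psca) are basal;
#' cells expressing the luminal marker but not the basal one are luminal;
#' double-positive and double-negative cells stay unassigned.  "Any level"
#' means detection (raw count > 0), evaluated on the UMI layer.
#'
#' @param expr_krt5,expr_psca Per-cell raw counts (or any non-negative
#'   values; detection = value > 0) for the basal and luminal marker.
#' @return Character vector in `{basal, luminal, unassigned}`.
#' @examples
#' assign_marker_subtype(c(1, 0, 2, 0), c(0, 3, 2, 0))
#' @export
assign_marker_subtype <- function(expr_krt5, expr_psca) {
  stopifnot(length(expr_krt5) == length(expr_psca))
  b <- expr_krt5 > 0
  l <- expr_psca > 0
  out <- rep("unassigned", length(b))
  out[b & !l] <- "basal"
  out[l & !b] <- "luminal"
  out
}

#' Propagate marker subtypes through unsupervised clusters
#'
#' Cells sharing a cluster with marker-labelled (seed) cells inherit the
#' majority seed label of that cluster; clusters with no seeds or a tied
#' vote stay unassigned.  Marker-labelled cells always keep their own
#' label.
#'
#' @param marker_labels Character vector from [assign_marker_subtype()].
#' @param clusters Per-cell cluster labels (same length).
#' @param cell_id Optional cell ids for the output table.
#' @return data.frame with `cell_id`, `subtype`, `provenance`
#'   (`marker`/`propagated`/`none`) and attribute `seed_counts` (cluster x
#'   label seed table).
#' @export
propagate_by_cluster <- function(marker_labels, clusters, cell_id = NULL) {
  stopifnot(length(marker_labels) == length(clusters))
  if (anyNA(clusters))
    stop("every cell needs a cluster label", call. = FALSE)
  if (is.null(cell_id)) cell_id <- as.character(seq_along(clusters))
  seeded <- marker_labels %in% c("basal", "luminal")
  seed_counts <- table(cluster = clusters[seeded],
                       label = marker_labels[seeded])
  cluster_label <- rep(NA_character_, length(unique(clusters)))
  names(cluster_label) <- unique(clusters)
  for (cl in rownames(seed_counts)) {
    v <- seed_counts[cl, ]
    win <- names(v)[v == max(v)]
    if (length(win) == 1L && max(v) > 0) cluster_label[cl] <- win
  }
  subtype <- marker_labels
  provenance <- ifelse(seeded, "marker", "none")
  fill <- !seeded & !is.na(cluster_label[as.character(clusters)])
  subtype[fill] <- cluster_label[as.character(clusters[fill])]
  provenance[fill] <- "propagated"
  out <- data.frame(cell_id = cell_id, subtype = subtype,
                    provenance = provenance,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "seed_counts") <- seed_counts
  out
}

#' Per-cell stemness score (simplified differentiation proxy)
#'
#' A deliberately simplified stand-in for CytoTRACE's core signal: genes
#' whose expression correlates with per-cell detected-gene counts mark
#' less differentiated cells.  Per gene, the Pearson correlation with the
#' per-cell gene-count vector is computed on the log-normalized layer; the
#' mean expression of the `top_k` most-correlated genes is then
#' rank-transformed to \[0, 1\] (most stem-like cell = 1).  The full
#' published algorithm (with graph smoothing) is NOT reproduced; only the
#' downstream `differentiation = 1 - stemness` convention is.
#'
#' @param norm Log-normalized gene x cell matrix (tumor cells).
#' @param top_k Number of top-correlated genes averaged.
#' @return data.frame with `cell_id`, `stemness`, `differentiation`
#'   (`= 1 - stemness` exactly).
#' @export
stemness_score <- function(norm, top_k = 200L) {
  if (ncol(norm) < 2L)
    stop("stemness score needs at least 2 cells", call. = FALSE)
  gene_counts <- Matrix::colSums(norm > 0)
  if (stats::sd(gene_counts) == 0)
    stop("per-cell gene counts are constant; correlation undefined",
         call. = FALSE)
  x <- as.matrix(norm)
  cors <- suppressWarnings(stats::cor(t(x), gene_counts))[, 1]
  cors[is.na(cors)] <- -Inf  # constant genes cannot be selected
  top <- order(cors, decreasing = TRUE)[seq_len(min(top_k, nrow(x)))]
  score <- colMeans(x[top, , drop = FALSE])
  r <- rank(score, ties.method = "average")
  stemness <- (r - min(r)) / max(max(r) - min(r), 1)
  data.frame(cell_id = colnames(norm) %||% as.character(seq_len(ncol(norm))),
             stemness = stemness, differentiation = 1 - stemness,
             stringsAsFactors = FALSE, row.names = NULL)
}
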