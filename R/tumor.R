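#' Classify cells as somatic-variant-containing (tumor) cells
#'
#' A variant position qualifies in a cell when total coverage (ref + alt)
#' is strictly above `min_coverage`, alt reads strictly above `min_alt`,
#' and per-position VAF (alt / (ref + alt)) strictly above `min_vaf`.  A
#' cell is called variant-positive when at least `min_positions` positions
#' qualify.  Cells with no covered position are negative, not missing;
#' `n_covered_positions` supports downstream sensitivity analysis.
#'
#' @param ac An `allele_counts` object (see [allele_counts()]).
#' @param min_positions Minimum qualifying variant positions (>=).
#' @param min_coverage Coverage threshold in reads (>).
#' @param min_alt Alt-read threshold (>).
#' @param min_vaf Per-position VAF threshold as a fraction (>).
#' @return data.frame with `cell_id`, `status`
#'   (`variant_positive`/`variant_negative`), `n_qualifying_positions`,
#'   `n_covered_positions`, `qualifying_variant_ids` (comma-separated).
#' @examples
#' ref <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(14, 20),
#'                             dims = c(2, 1))
#' alt <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(7, 6),
#'                             dims = c(2, 1))
#' classify_cells(allele_counts(ref, alt))$status  # both positions qualify
#' @export
classify_cells <- function(ac, min_positions = 2L, min_coverage = 20,
                           min_alt = 5, min_vaf = 0.10) {
  stopifnot(min_positions >= 0, min_coverage >= 0, min_alt >= 0,
            min_vaf >= 0, min_vaf <= 1)
  if (!identical(dim(ac$ref), dim(ac$alt)))
    stop("ref and alt matrices must have identical shape", call. = FALSE)
  n_cells <- ncol(ac$ref)

  # align on positions covered in either matrix via sparse addition
  covm <- methods::as(ac$ref + ac$alt, "CsparseMatrix")
  s <- Matrix::summary(covm)
  i <- s$i; j <- s$j; cov <- s$x
  covered <- cov > 0  # drop stored explicit zeros, if any
  i <- i[covered]; j <- j[covered]; cov <- cov[covered]
  alt_v <- ac$alt[cbind(i, j)]
  qual <- cov > min_coverage & alt_v > min_alt & alt_v / cov > min_vaf

  n_cov <- tabulate(j, nbins = n_cells)
  n_qual <- tabulate(j[qual], nbins = n_cells)
  qual_ids <- rep("", n_cells)
  if (any(qual)) {
    by_cell <- split(ac$variants[i[qual]], j[qual])
    qual_ids[as.integer(names(by_cell))] <-
      vapply(by_cell, function(v) paste(sort(v), collapse = ","), "")
  }
  data.frame(
    cell_id = ac$cells,
    status = ifelse(n_qual >= min_positions, "variant_positive",
                    "variant_negative"),
    n_qualifying_positions = n_qual,
    n_covered_positions = n_cov,
    qualifying_variant_ids = qual_ids,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cross-tabulate tumor calls against independent epithelial evidence
#'
#' Builds the 2 x 2 x 2 table over (variant-positive, typed epithelial,
#' Epcam detected) used to confirm that variant status separates tumor
#' cells from normal epithelial cells.
#'
#' @param calls Output of [classify_cells()].
#' @param cells Per-cell metadata with `cell_id` and `cell_type`.
#' @param epithelial_label The cell-type label counting as epithelial.
#' @param epcam_expression Named per-cell expression (or count) vector for
#'   the epithelial marker; detection = value > 0.
#' @return list with `table` (2x2x2 contingency array), `fractions`
#'   (proportions of the same array), and `n`.
#' @export
concordance_with_labels <- function(calls, cells,
                                    epithelial_label = "epithelial",
                                    epcam_expression) {
  if (nrow(calls) == 0L)
    stop("empty call table", call. = FALSE)
  orphans <- setdiff(calls$cell_id, cells$cell_id)
  if (length(orphans))
    stop("cells missing metadata: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) " ..." else "", call. = FALSE)
  meta <- cells[match(calls$cell_id, cells$cell_id), ]
  epcam <- epcam_expression[calls$cell_id]
  if (anyNA(epcam))
    stop("epcam_expression missing for some called cells", call. = FALSE)
  tab <- table(
    variant_positive = calls$status == "variant_positive",
    epithelial = meta$cell_type == epithelial_label,
    epcam_detected = epcam > 0
  )
  list(table = tab, fractions = tab / sum(tab), n = sum(tab))
}

#' T/NK-family cell-type labels
#' @return Character vector of fine labels counted as T or NK lineage.
#' @export
tnk_family_labels <- function() {
  c("CD4", "CD4.Naive", "CD8.Naive", "CD8.Eff", "CD8.Mem",
    "NK", "NKT", "Tgd", "Treg")
}

#' Concordance of receptor detection with expression-based typing
#'
#' Computes the fraction of BCR-detected cells typed as B cells and the
#' fraction of TCR-detected cells typed as any T/NK-family type.  With
#' zero receptor-detected cells the corresponding fraction is reported as
#' `NA` (absent), never 0.
#'
#' @param cells data.frame with `cell_type`, `bcr_detected`,
#'   `tcr_detected`.
#' @param b_label Label counting as B cell.
#' @param tnk_labels Labels counting as T/NK family.
#' @return list with `bcr` and `tcr`, each holding `fraction`,
#'   `numerator`, `denominator`.
#' @export
receptor_concordance <- function(cells, b_label = "B",
                                 tnk_labels = tnk_family_labels()) {
  frac <- function(det, ok) {
    d <- sum(det)
    list(fraction = if (d == 0) NA_real_ else sum(det & ok) / d,
         numerator = sum(det & ok), denominator = d)
  }
  list(bcr = frac(as.logical(cells$bcr_detected),
                  cells$cell_type == b_label),
       tcr = frac(as.logical(cells$tcr_detected),
                  cells$cell_type %in% tnk_labels))
}
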