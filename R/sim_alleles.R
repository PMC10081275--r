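#' Simulate per-cell ref/alt allele counts at somatic variant positions
#'
#' Emulates allele counting of scRNA-seq reads at known somatic variant
#' sites (the VarTrix step): in each cell only a random subset of variants
#' is covered; covered positions get a Poisson depth, and alt reads are
#' binomial at the variant's true VAF in tumor cells or at a small error
#' rate in non-tumor cells.
#'
#' @param sim A [simulate_counts()] result (supplies cell ids and tumor
#'   ground truth).
#' @param variant_table A [simulate_variant_table()] result (supplies true
#'   VAFs; passing variants only are used when `truth_pass` is present).
#' @param config A [sim_config()].
#' @return A list of class `allele_counts` with sparse variant x cell
#'   matrices `ref` and `alt` (identical shape), `cells`, `variants`.
#' @export
simulate_allele_counts <- function(sim, variant_table, config) {
  config <- validate_sim_config(config)
  if (nrow(variant_table) == 0L)
    stop("variant table is empty", call. = FALSE)
  vt <- variant_table
  if ("truth_pass" %in% names(vt) && any(vt$truth_pass))
    vt <- vt[vt$truth_pass, , drop = FALSE]
  set.seed(config$seed + 303L)

  cell_ids <- sim$cells$cell_id
  is_tumor <- sim$truth$is_tumor[cell_ids]
  n_cells <- length(cell_ids)
  n_var <- nrow(vt)

  # covered (cell, variant) pairs
  n_cov <- stats::rbinom(n_cells, n_var, config$variant_coverage_prob)
  j <- rep.int(seq_len(n_cells), n_cov)
  i <- unlist(lapply(n_cov, function(k) sample.int(n_var, k)),
              use.names = FALSE)
  depth <- stats::rpois(length(i), config$variant_depth_mean)
  keep <- depth > 0L
  i <- i[keep]; j <- j[keep]; depth <- depth[keep]

  p_alt <- ifelse(is_tumor[j], vt$tumor_vaf[i], config$allele_error_rate)
  alt <- stats::rbinom(length(depth), depth, p_alt)
  ref <- depth - alt

  dn <- list(vt$variant_id, cell_ids)
  ac <- list(
    ref = Matrix::sparseMatrix(i = i, j = j, x = ref,
                               dims = c(n_var, n_cells), dimnames = dn),
    alt = Matrix::sparseMatrix(i = i, j = j, x = alt,
                               dims = c(n_var, n_cells), dimnames = dn),
    variants = vt$variant_id, cells = cell_ids
  )
  class(ac) <- "allele_counts"
  ac
}

#' Construct an allele-count container from ref/alt matrices
#'
#' @param ref,alt Sparse (or dense) variant x cell matrices of identical
#'   shape holding reference- and alternate-allele read counts.
#' @return An `allele_counts` object.
#' @export
allele_counts <- function(ref, alt) {
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt matrices must have identical shape", call. = FALSE)
  ref <- methods::as(methods::as(ref, "CsparseMatrix"), "generalMatrix")
  alt <- methods::as(methods::as(alt, "CsparseMatrix"), "generalMatrix")
  if (any(ref@x < 0) || any(alt@x < 0))
    stop("allele counts must be non-negative", call. = FALSE)
  structure(list(ref = ref, alt = alt,
                 variants = rownames(ref) %||% sprintf("var%d", seq_len(nrow(ref))),
                 cells = colnames(ref) %||% sprintf("cell%d", seq_len(ncol(ref)))),
            class = "allele_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
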