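#' Read a gene-barcode matrix directory (MatrixMarket trio)
#'
#' Reads the 10x-style `matrix.mtx` / `features.tsv` / `barcodes.tsv`
#' layout into a sparse gene x cell matrix.
#'
#' @param dir Directory containing the three files.
#' @return dgCMatrix with gene rownames and barcode colnames.
#' @export
read_counts_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                           header = FALSE, stringsAsFactors = FALSE)
  dimnames(m) <- list(feats[[1]], bcs[[1]])
  m
}

#' Write a gene-barcode matrix directory (MatrixMarket trio)
#'
#' @param counts Sparse gene x cell matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_dir <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member symbols.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(length(names(gene_sets)) == length(gene_sets))
  lines <- mapply(function(nm, genes, desc)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(gene_sets), gene_sets, rep_len(description, length(gene_sets)))
  writeLines(lines, path)
  invisible(path)
}

#' Write all synthetic pipeline inputs to disk
#'
#' Materializes a simulation as the plain-file formats the pipeline stages
#' consume: counts as an MTX trio, cell metadata and the variant table as
#' TSV, ref/alt allele counts as two MTX files with shared barcode/variant
#' TSVs, gene sets as GMT, ground truth and the generating parameters as
#' JSON sidecars.
#'
#' @param sim A [simulate_counts()] result.
#' @param variant_table A [simulate_variant_table()] result.
#' @param ac A [simulate_allele_counts()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, variant_table, ac, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_dir(sim$counts, file.path(dir, "counts"))
  utils::write.table(sim$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(variant_table, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(ac$ref, file.path(dir, "allele_ref.mtx"))
  Matrix::writeMM(ac$alt, file.path(dir, "allele_alt.mtx"))
  writeLines(ac$variants, file.path(dir, "allele_variants.tsv"))
  writeLines(ac$cells, file.path(dir, "allele_barcodes.tsv"))
  write_gmt(sim$config$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- sim$truth
  truth_json <- list(
    is_tumor = unname(truth$is_tumor),
    true_type = unname(truth$true_type),
    true_subtype = unname(truth$true_subtype),
    stemness_level = unname(truth$stemness_level),
    planted_mito = unname(truth$planted_mito),
    planted_doublet = unname(truth$planted_doublet),
    planted_low_feature = unname(truth$planted_low_feature),
    cell_id = sim$cells$cell_id
  )
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"))
  cfg <- sim$config
  cfg_json <- cfg[setdiff(names(cfg), c("cell_type_spec", "gene_set_effects",
                                        "gene_sets"))]
  cfg_json$cell_type_spec <- cfg$cell_type_spec
  cfg_json$gene_set_effects <- cfg$gene_set_effects
  cfg_json$gene_sets <- cfg$gene_sets
  jsonlite::write_json(cfg_json, file.path(dir, "sim_params.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read ref/alt allele counts from MTX files
#'
#' VarTrix-compatible layout: two MatrixMarket files sharing one variant
#' list and one barcode list.
#'
#' @param ref_path,alt_path MTX paths.
#' @param variants_path,barcodes_path One id per line.
#' @return An `allele_counts` object.
#' @export
read_allele_counts <- function(ref_path, alt_path, variants_path,
                               barcodes_path) {
  ref <- methods::as(Matrix::readMM(ref_path), "CsparseMatrix")
  alt <- methods::as(Matrix::readMM(alt_path), "CsparseMatrix")
  vr <- readLines(variants_path)
  bc <- readLines(barcodes_path)
  dimnames(ref) <- dimnames(alt) <- list(vr, bc)
  allele_counts(ref, alt)
}
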