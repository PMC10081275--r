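#' Hallmark interferon-gamma response genes (mouse symbols)
#'
#' The mouse-symbol subset of the MSigDB hallmark IFN-gamma response gene
#' set that the pipeline uses by default: the interferon-induced genes most
#' relevant to the bladder-cancer ICB setting (antigen presentation,
#' GTPases, chemokines).  Bundled so the synthetic generator and the
#' enrichment stage share one planted/tested set.
#'
#' @return Character vector of mouse gene symbols.
#' @export
ifng_response_genes <- function() {
  c("B2m", "Gbp2", "H2-D1", "Ifitm1", "Parp14", "Psme2", "Rtp4",
    "Tmem140", "Wars", "Cxcl9", "Cxcl10", "Gbp8", "Icam1", "Nfkbia")
}

#' Default cell-type composition for the synthetic tumor microenvironment
#'
#' Fifteen cell types mirroring the lymphocyte / myeloid / stromal /
#' epithelial populations of a checkpoint-blockade-treated urothelial
#' tumor, each with a mixture proportion and two planted marker genes.
#' Epithelial cells host the tumor population.
#'
#' @return data.frame with columns `type`, `proportion`, `markers`
#'   (comma-separated gene symbols).
#' @export
default_cell_types <- function() {
  types <- c("B", "CD4", "CD4.Naive", "CD8.Naive", "CD8.Eff", "CD8.Mem",
             "NK", "Treg", "dendritic", "endothelial", "epithelial",
             "fibroblast", "macrophage", "monocyte", "neutrophil")
  prop <- c(0.10, 0.08, 0.05, 0.05, 0.08, 0.04,
            0.05, 0.04, 0.05, 0.08, 0.12,
            0.06, 0.08, 0.06, 0.06)
  markers <- c("Cd79a,Ms4a1", "Cd4,Il7r", "Ccr7,Sell", "Cd8a,Lef1",
               "Cd8a,Gzmb", "Cd8a,Il7r", "Ncr1,Klrb1c", "Foxp3,Il2ra",
               "Itgax,Flt3", "Pecam1,Tek", "Epcam,Krt8",
               "Col3a1,Col1a1", "Adgre1,C1qa", "Ly6c2,Ccr2", "Ly6g,S100a8")
  data.frame(type = types, proportion = prop, markers = markers,
             stringsAsFactors = FALSE)
}

#' Default planted gene-set perturbations
#'
#' The condition-dependent regulation pattern planted by default: the
#' IFN-gamma response set is up-regulated (x2) under ICB in endothelial
#' cells, neutrophils and luminal tumor cells, and down-regulated (x0.5)
#' under ICB in macrophages and monocytes.
#'
#' @return data.frame with columns `set_name`, `cell_type`, `condition`,
#'   `effect` (multiplicative).
#' @export
default_gene_set_effects <- function() {
  data.frame(
    set_name  = "HALLMARK_IFN_GAMMA_RESPONSE",
    cell_type = c("endothelial", "neutrophil", "luminal",
                  "macrophage", "monocyte"),
    condition = "ICB",
    effect    = c(2, 2, 2, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Build a validated simulation configuration
#'
#' Describes the full synthetic study design: 5 biological replicates x 3
#' conditions (untreated control, combined PD-1/CTLA-4 blockade `ICB`, and
#' blockade after CD4+ T-cell depletion `ICBdT`), a 15-type cell mixture
#' with planted markers, a clonal somatic variant profile (VAFs centred
#' near 0.5 with a hemizygous VAF = 1 subpopulation), planted QC failures,
#' and condition-dependent gene-set effects.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_replicates Biological replicates per condition.
#' @param conditions Condition labels; first is the reference.
#' @param n_cells_per_sample Cells per (replicate, condition) sample.
#' @param cell_type_spec data.frame as [default_cell_types()].
#' @param n_genes Size of the gene universe (includes markers and set genes).
#' @param n_variants Somatic variants to simulate.
#' @param clonal_vaf_mean,clonal_vaf_sd Clonal VAF distribution (fractions).
#' @param frac_vaf1 Fraction of variants fixed at VAF exactly 1.
#' @param vaf1_chrom Chromosome preferentially carrying VAF = 1 variants.
#' @param vaf1_chrom_prob Probability a VAF = 1 variant lands on `vaf1_chrom`.
#' @param gene_set_effects data.frame as [default_gene_set_effects()].
#' @param gene_sets Named list of character vectors; the planted gene sets.
#' @param tumor_fraction Fraction of all cells that are tumor cells
#'   (they carry the epithelial label).
#' @param variant_depth_mean Mean per-position sequencing depth in the
#'   allele-count simulation (Poisson).
#' @param variant_coverage_prob Probability a given variant is covered in a
#'   given cell (sparsity of the allele-count matrices).
#' @param allele_error_rate Alt-read rate at variant positions in
#'   non-tumor cells.
#' @param qc_fail_fractions Named numeric: `mito`, `doublet`, `low_feature`
#'   planted failure fractions.
#' @param receptor_error_rate Planted error rate of BCR/TCR status flags.
#' @param pruned_fraction Fraction of cells flagged as pruned (low-confidence
#'   reference typing).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_cells_per_sample = 100, n_genes = 300)
#' @export
sim_config <- function(seed = 1L,
                       n_replicates = 5L,
                       conditions = c("control", "ICB", "ICBdT"),
                       n_cells_per_sample = 500L,
                       cell_type_spec = default_cell_types(),
                       n_genes = 2000L,
                       n_variants = 1000L,
                       clonal_vaf_mean = 0.5,
                       clonal_vaf_sd = 0.08,
                       frac_vaf1 = 0.016,
                       vaf1_chrom = "chrX",
                       vaf1_chrom_prob = 0.708,
                       gene_set_effects = default_gene_set_effects(),
                       gene_sets = list(
                         HALLMARK_IFN_GAMMA_RESPONSE = ifng_response_genes()),
                       tumor_fraction = 0.10,
                       variant_depth_mean = 30,
                       variant_coverage_prob = 0.02,
                       allele_error_rate = 0.002,
                       qc_fail_fractions = c(mito = 0.03, doublet = 0.009,
                                             low_feature = 0.03),
                       receptor_error_rate = 0.05,
                       pruned_fraction = 0.02) {
  cfg <- list(seed = as.integer(seed),
              n_replicates = as.integer(n_replicates),
              conditions = as.character(conditions),
              n_cells_per_sample = as.integer(n_cells_per_sample),
              cell_type_spec = cell_type_spec,
              n_genes = as.integer(n_genes),
              n_variants = as.integer(n_variants),
              clonal_vaf_mean = clonal_vaf_mean,
              clonal_vaf_sd = clonal_vaf_sd,
              frac_vaf1 = frac_vaf1,
              vaf1_chrom = vaf1_chrom,
              vaf1_chrom_prob = vaf1_chrom_prob,
              gene_set_effects = gene_set_effects,
              gene_sets = gene_sets,
              tumor_fraction = tumor_fraction,
              variant_depth_mean = variant_depth_mean,
              variant_coverage_prob = variant_coverage_prob,
              allele_error_rate = allele_error_rate,
              qc_fail_fractions = qc_fail_fractions,
              receptor_error_rate = receptor_error_rate,
              pruned_fraction = pruned_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_variants <= 0L)
    stop("n_variants must be positive", call. = FALSE)
  if (cfg$n_cells_per_sample <= 0L || cfg$n_replicates <= 0L)
    stop("n_cells_per_sample and n_replicates must be positive",
         call. = FALSE)
  p <- cfg$cell_type_spec$proportion
  if (abs(sum(p) - 1) > 1e-9)
    stop("cell type proportions must sum to 1 (got ", sum(p), ")",
         call. = FALSE)
  fracs <- c(cfg$frac_vaf1, cfg$tumor_fraction, cfg$qc_fail_fractions,
             cfg$receptor_error_rate, cfg$pruned_fraction,
             cfg$variant_coverage_prob, cfg$allele_error_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  needed <- c("mito", "doublet", "low_feature")
  if (!all(needed %in% names(cfg$qc_fail_fractions)))
    stop("qc_fail_fractions must name mito, doublet and low_feature",
         call. = FALSE)
  if (anyDuplicated(cfg$cell_type_spec$type))
    stop("duplicated cell type names", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study design:\n")
  cat(sprintf("  %d replicates x %d conditions (%s), %d cells/sample\n",
              x$n_replicates, length(x$conditions),
              paste(x$conditions, collapse = ", "), x$n_cells_per_sample))
  cat(sprintf("  %d genes, %d cell types, %d somatic variants\n",
              x$n_genes, nrow(x$cell_type_spec), x$n_variants))
  invisible(x)
}

# split markers field into a character vector
marker_list <- function(cell_type_spec) {
  lapply(strsplit(cell_type_spec$markers, ","), trimws)
}
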