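#' Simulate a cell x gene UMI count matrix with per-cell metadata
#'
#' Generates negative-binomial UMI counts for the full study design
#' (`n_replicates` x `conditions` samples), with:
#' * gene-level baseline means drawn log-normal and a log-normal per-cell
#'   library-size factor (so the top-UMI doublet rule has signal);
#' * cell-type marker genes up-scaled in their own type and suppressed
#'   elsewhere;
#' * tumor cells (epithelial label) split into basal/luminal subtypes with
#'   planted `Krt5` / `Psca` marker expression and a per-cell stemness
#'   level that scales transcriptome breadth (basal = more stem-like);
#' * multiplicative gene-set effects applied to set-member genes in the
#'   designated (cell type, condition) strata;
#' * planted QC failures: high mitochondrial percentage, inflated-library
#'   doublets, and low-feature cells;
#' * BCR/TCR receptor status flags true for B and T/NK lineages with a
#'   planted error rate.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_counts` with elements `counts` (sparse
#'   gene x cell dgCMatrix of UMIs), `cells` (per-cell metadata
#'   data.frame), `genes` (character), and `truth` (ground-truth list with
#'   per-cell `is_tumor`, `true_subtype`, `stemness_level` and planted QC
#'   failure flags).
#' @export
simulate_counts <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 202L)

  spec <- config$cell_type_spec
  markers <- marker_list(spec)
  subtype_markers <- list(basal = c("Krt5", "Krt14", "Cd44"),
                          luminal = c("Psca", "Elf3", "Cd24a"))
  set_genes <- unique(unlist(config$gene_sets))
  named <- unique(c(unlist(markers), unlist(subtype_markers), set_genes))
  if (length(named) > config$n_genes)
    stop("n_genes smaller than the number of named marker/set genes",
         call. = FALSE)
  genes <- c(named, sprintf("Gene%04d", seq_len(config$n_genes - length(named))))
  n_genes <- length(genes)

  # gene baseline means: log-normal, named genes given a solid baseline so
  # detection-based rules (markers, receptor status, Krt5/Psca) have signal
  base_mu <- stats::rlnorm(n_genes, meanlog = log(0.08), sdlog = 1.2)
  names(base_mu) <- genes
  base_mu[named] <- pmax(base_mu[named], 0.5)

  # per-(gene, cell type) factors for planted markers
  types <- spec$type
  type_factor <- matrix(1, n_genes, length(types),
                        dimnames = list(genes, types))
  for (i in seq_along(types)) {
    mk <- intersect(markers[[i]], genes)
    type_factor[mk, ] <- 0.05          # background in other types
    type_factor[mk, i] <- 8            # up-scaled in own type
  }
  # subtype markers: near-silent everywhere, switched on per subtype below
  for (mk in unlist(subtype_markers)) type_factor[mk, ] <- 0.002

  # study design
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        condition = config$conditions,
                        stringsAsFactors = FALSE)
  n_samples <- nrow(design)
  n_cells <- n_samples * config$n_cells_per_sample

  cell_type <- sample(types, n_cells, replace = TRUE, prob = spec$proportion)
  replicate <- rep(design$replicate, each = config$n_cells_per_sample)
  condition <- rep(design$condition, each = config$n_cells_per_sample)
  cell_id <- sprintf("cell%06d-%s-r%d", seq_len(n_cells), condition, replicate)

  # tumor cells live inside the epithelial population
  epi <- cell_type == "epithelial"
  p_epi <- mean(epi)
  p_tumor_given_epi <- min(1, config$tumor_fraction / max(p_epi, 1e-12))
  is_tumor <- epi & stats::runif(n_cells) < p_tumor_given_epi
  true_subtype <- rep(NA_character_, n_cells)
  true_subtype[is_tumor] <- sample(c("basal", "luminal"),
                                   sum(is_tumor), replace = TRUE)

  # stemness: basal tumor cells are less differentiated (higher stemness).
  # The planted signal is transcriptome BREADTH, not uniform depth (which
  # library-size normalization would cancel): a "stemness program" of
  # background genes is expressed proportionally to the per-cell stemness
  # level, so stem-like cells detect more genes - the signal the
  # gene-count-correlation proxy keys on.
  stemness_level <- rep(NA_real_, n_cells)
  stemness_level[which(true_subtype == "basal")] <-
    stats::rbeta(sum(true_subtype == "basal", na.rm = TRUE), 5, 2)
  stemness_level[which(true_subtype == "luminal")] <-
    stats::rbeta(sum(true_subtype == "luminal", na.rm = TRUE), 2, 5)
  filler <- setdiff(genes, named)
  program_genes <- filler[seq_len(floor(length(filler) * 0.3))]
  base_mu[program_genes] <- pmax(base_mu[program_genes], 0.3)
  stem_factor <- ifelse(is.na(stemness_level), 1,
                        0.1 + 2.4 * stemness_level)

  # planted QC failures
  qc <- config$qc_fail_fractions
  planted_mito <- stats::runif(n_cells) < qc[["mito"]]
  planted_doublet <- stats::runif(n_cells) < qc[["doublet"]]
  planted_lowfeat <- stats::runif(n_cells) < qc[["low_feature"]]

  lib <- stats::rlnorm(n_cells, meanlog = 0, sdlog = 0.3)
  lib[planted_doublet] <- lib[planted_doublet] * 2.5
  lowfeat_scale <- ifelse(planted_lowfeat, 0.08, 1)
  cell_scale <- lib * lowfeat_scale

  # multiplicative gene-set effects per (cell type, condition)
  eff <- config$gene_set_effects
  # stratum label: tumor subtypes override the epithelial label for effects
  stratum <- cell_type
  stratum[is_tumor] <- true_subtype[is_tumor]

  counts <- make_nb_counts(genes, base_mu, type_factor, cell_type, stratum,
                           condition, cell_scale, eff, config$gene_sets,
                           subtype_markers, program_genes, stem_factor,
                           size = 2)
  colnames(counts) <- cell_id

  umi_count <- Matrix::colSums(counts)
  gene_count <- Matrix::colSums(counts > 0)

  # mitochondrial percentage is metadata (mito genes not in the matrix)
  mito_pct <- stats::rbeta(n_cells, 2, 38) * 100
  mito_pct[planted_mito] <- stats::runif(sum(planted_mito), 15, 60)

  # receptor detection: high sensitivity in the true lineage, plus an
  # error fraction of detections relocated onto out-of-lineage cells, so
  # the fraction of receptor-positive cells with a concordant type label
  # is ~ (1 - receptor_error_rate)
  tnk <- c("CD4", "CD4.Naive", "CD8.Naive", "CD8.Eff", "CD8.Mem",
           "NK", "NKT", "Tgd", "Treg")
  err <- config$receptor_error_rate
  plant_receptor <- function(in_lineage, sensitivity = 0.8) {
    det <- in_lineage & stats::runif(n_cells) < sensitivity
    misplaced <- which(det)[stats::runif(sum(det)) < err]
    det[misplaced] <- FALSE
    pool <- which(!in_lineage)
    if (length(misplaced) && length(pool))
      det[sample(pool, min(length(misplaced), length(pool)))] <- TRUE
    det
  }
  bcr_detected <- plant_receptor(cell_type == "B")
  tcr_detected <- plant_receptor(cell_type %in% tnk)

  pruned <- stats::runif(n_cells) < config$pruned_fraction

  cluster <- stratum  # clusters mirror cell types; tumor splits by subtype
  cluster[is_tumor] <- paste0("tumor_", true_subtype[is_tumor])

  cells <- data.frame(
    cell_id = cell_id, replicate = replicate, condition = condition,
    mito_pct = mito_pct, umi_count = as.integer(umi_count),
    gene_count = as.integer(gene_count),
    cell_type = cell_type, cluster = cluster, pruned = pruned,
    bcr_detected = bcr_detected, tcr_detected = tcr_detected,
    stringsAsFactors = FALSE, row.names = NULL
  )

  truth <- list(
    is_tumor = stats::setNames(is_tumor, cell_id),
    true_type = stats::setNames(cell_type, cell_id),
    true_subtype = stats::setNames(true_subtype, cell_id),
    stemness_level = stats::setNames(stemness_level, cell_id),
    planted_mito = stats::setNames(planted_mito, cell_id),
    planted_doublet = stats::setNames(planted_doublet, cell_id),
    planted_low_feature = stats::setNames(planted_lowfeat, cell_id),
    gene_set_effects = eff
  )

  structure(list(counts = counts, cells = cells, genes = genes,
                 truth = truth, config = config),
            class = "sim_counts")
}

# Draw NB counts block-wise over (cell type, condition) strata and return a
# sparse gene x cell matrix.  Effects and subtype markers are applied to the
# mean matrix before sampling.
make_nb_counts <- function(genes, base_mu, type_factor, cell_type, stratum,
                           condition, cell_scale, eff, gene_sets,
                           subtype_markers, program_genes, stem_factor,
                           size) {
  n_genes <- length(genes)
  n_cells <- length(cell_type)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  key <- paste(stratum, condition, sep = "\r")
  for (k in unique(key)) {
    cells_k <- which(key == k)
    st <- stratum[cells_k[1]]
    cond <- condition[cells_k[1]]
    base_type <- cell_type[cells_k[1]]
    mu_g <- base_mu * type_factor[, base_type]
    if (st %in% c("basal", "luminal"))
      mu_g[subtype_markers[[st]]] <- pmax(base_mu[subtype_markers[[st]]], 1.5)
    hit <- eff$cell_type == st & eff$condition == cond
    for (r in which(hit)) {
      sg <- intersect(gene_sets[[eff$set_name[r]]], genes)
      mu_g[sg] <- mu_g[sg] * eff$effect[r]
    }
    mu_block <- outer(mu_g, cell_scale[cells_k])
    if (st %in% c("basal", "luminal")) {
      prog <- match(program_genes, genes)
      mu_block[prog, ] <- sweep(mu_block[prog, , drop = FALSE], 2,
                                stem_factor[cells_k], `*`)
    }
    x <- stats::rnbinom(length(mu_block), size = size, mu = as.vector(mu_block))
    nz <- which(x > 0L)
    ii <- c(ii, ((nz - 1L) %% n_genes) + 1L)
    jj <- c(jj, cells_k[((nz - 1L) %/% n_genes) + 1L])
    xx <- c(xx, x[nz])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(n_genes, n_cells),
                       dimnames = list(genes, NULL))
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("Simulated scRNA-seq data: %d genes x %d cells (%d samples)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(paste(x$cells$replicate, x$cells$condition)))))
  invisible(x)
}
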