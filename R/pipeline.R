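#' Build a validated end-to-end pipeline configuration
#'
#' Collects every stage parameter (with the published defaults: mito
#' cutoff 12.5%, doublet rate 0.9%, tumor-call thresholds 2 positions /
#' 20X / 5 alt reads / 10% VAF, DE cuts 0.05 and |log2FC| 0.26) plus input
#' and output locations.  Unknown arguments are rejected.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param input_dir Directory holding pipeline inputs in the
#'   [write_simulation()] layout; `NULL` requires `simulate = TRUE`.
#' @param simulate Generate inputs with the synthetic-data module.
#' @param seed Seed used for simulation and permutation nulls.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param mito_cutoff_pct,doublet_rate,feature_cutoff QC parameters.
#' @param min_positions,min_coverage,min_alt,min_vaf Tumor-call
#'   thresholds.
#' @param p_adj_cut,log2fc_cut DE-gene cuts.
#' @param gsea_n_perm GSEA permutation count.
#' @param target_size_mb Denominator for the mutation-burden summary.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, simulate = is.null(input_dir),
                            seed = 1L, sim = sim_config(seed = seed),
                            mito_cutoff_pct = 12.5, doublet_rate = 0.009,
                            feature_cutoff = 100,
                            min_positions = 2L, min_coverage = 20,
                            min_alt = 5, min_vaf = 0.10,
                            p_adj_cut = 0.05, log2fc_cut = 0.26,
                            gsea_n_perm = 200L, target_size_mb = 2500) {
  if (!simulate && is.null(input_dir))
    stop("either supply input_dir or set simulate = TRUE", call. = FALSE)
  cfg <- list(out_dir = out_dir, input_dir = input_dir, simulate = simulate,
              seed = as.integer(seed), sim = sim,
              mito_cutoff_pct = mito_cutoff_pct, doublet_rate = doublet_rate,
              feature_cutoff = feature_cutoff,
              min_positions = min_positions, min_coverage = min_coverage,
              min_alt = min_alt, min_vaf = min_vaf,
              p_adj_cut = p_adj_cut, log2fc_cut = log2fc_cut,
              gsea_n_perm = as.integer(gsea_n_perm),
              target_size_mb = target_size_mb)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stages <- c("simulate", "variants", "qc", "tumor-call",
                     "subtype", "de", "enrich")

stage_dir <- function(cfg, stage) {
  file.path(cfg$out_dir, switch(stage,
    simulate = "inputs", variants = "01_variants", qc = "02_qc",
    `tumor-call` = "03_tumor", subtype = "04_subtype", de = "05_de",
    enrich = "06_enrich"))
}

#' Run the pipeline end-to-end (or a subset of stages)
#'
#' Executes the stage order simulate (optional) -> variants -> qc ->
#' tumor-call -> subtype -> de -> enrich with plain-file handoff between
#' stages, so any single stage can be re-run from cached upstream outputs.
#' Every stage writes a JSON report; a run manifest records package
#' version, seed, parameters and input checksums.  A stage error aborts
#' with the stage name; earlier outputs are preserved.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Stages to run (default: all applicable).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg, stages = pipeline_stages) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!cfg$simulate) stages <- setdiff(stages, "simulate")
  stages <- intersect(pipeline_stages, stages)
  for (stage in stages) {
    message("[icbscl] stage: ", stage)
    fun <- switch(stage,
      simulate = stage_simulate, variants = stage_variants, qc = stage_qc,
      `tumor-call` = stage_tumor, subtype = stage_subtype, de = stage_de,
      enrich = stage_enrich)
    tryCatch(fun(cfg), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- write_manifest(cfg, stages)
  invisible(manifest)
}

input_path <- function(cfg, ...) {
  base <- if (cfg$simulate) stage_dir(cfg, "simulate") else cfg$input_dir
  file.path(base, ...)
}

require_input <- function(path) {
  missing <- path[!file.exists(path)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  path
}

write_report <- function(obj, dir, name = "report.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, file.path(dir, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

stage_simulate <- function(cfg) {
  sim <- simulate_counts(cfg$sim)
  vt <- simulate_variant_table(cfg$sim)
  ac <- simulate_allele_counts(sim, vt, cfg$sim)
  write_simulation(sim, vt, ac, stage_dir(cfg, "simulate"))
  invisible(NULL)
}

stage_variants <- function(cfg) {
  vt <- read_variant_table(require_input(input_path(cfg, "variants.tsv")))
  res <- filter_somatic_variants(vt)
  vs <- vaf_summary(res$kept)
  d <- stage_dir(cfg, "variants")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$kept, file.path(d, "kept.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(list(
    rejection_counts = as.list(res$rejection_counts),
    n_kept = nrow(res$kept),
    median_vaf = vs$median_vaf,
    n_vaf_one = vs$n_vaf_one,
    chrom_fractions_at_vaf_one = as.list(vs$chrom_fractions_at_vaf_one),
    mutation_burden_per_mb = mutation_burden(nrow(res$kept),
                                             cfg$target_size_mb)), d)
  invisible(NULL)
}

stage_qc <- function(cfg) {
  cells <- utils::read.table(require_input(input_path(cfg, "cells.tsv")),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  counts <- read_counts_dir(require_input(input_path(cfg, "counts")))
  res <- apply_cell_filters(cells, cfg$mito_cutoff_pct, cfg$doublet_rate,
                            cfg$feature_cutoff)
  genes <- filter_genes(counts, res$kept)
  d <- stage_dir(cfg, "qc")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$kept, file.path(d, "cells_kept.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(genes, file.path(d, "genes_kept.txt"))
  write_report(c(res$report, list(n_genes_kept = length(genes),
                                  n_genes_input = nrow(counts))), d)
  invisible(NULL)
}

read_kept_cells <- function(cfg) {
  utils::read.table(file.path(stage_dir(cfg, "qc"), "cells_kept.tsv"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

stage_tumor <- function(cfg) {
  paths <- require_input(input_path(cfg, c("allele_ref.mtx", "allele_alt.mtx",
                                           "allele_variants.tsv",
                                           "allele_barcodes.tsv")))
  ac <- read_allele_counts(paths[1], paths[2], paths[3], paths[4])
  calls <- classify_cells(ac, cfg$min_positions, cfg$min_coverage,
                          cfg$min_alt, cfg$min_vaf)
  kept <- read_kept_cells(cfg)
  calls <- calls[calls$cell_id %in% kept$cell_id, , drop = FALSE]
  rc <- receptor_concordance(kept)
  d <- stage_dir(cfg, "tumor-call")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(calls, file.path(d, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(list(n_cells = nrow(calls),
                    n_variant_positive = sum(calls$status == "variant_positive"),
                    receptor_concordance = rc), d)
  invisible(NULL)
}

stage_subtype <- function(cfg) {
  counts <- read_counts_dir(input_path(cfg, "counts"))
  kept <- read_kept_cells(cfg)
  calls <- utils::read.table(file.path(stage_dir(cfg, "tumor-call"),
                                       "calls.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  tumor_ids <- calls$cell_id[calls$status == "variant_positive"]
  meta <- kept[kept$cell_id %in% tumor_ids, , drop = FALSE]
  d <- stage_dir(cfg, "subtype")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  if (nrow(meta) < 2L) {
    write_report(list(n_tumor_cells = nrow(meta), note = "too few tumor cells"), d)
    return(invisible(NULL))
  }
  krt5 <- get_gene_counts(counts, "Krt5", meta$cell_id)
  psca <- get_gene_counts(counts, "Psca", meta$cell_id)
  marker <- assign_marker_subtype(krt5, psca)
  assign <- propagate_by_cluster(marker, meta$cluster, meta$cell_id)
  norm_t <- lognormalize(counts[, meta$cell_id, drop = FALSE])
  score <- stemness_score(norm_t)
  out <- merge(assign, score, by = "cell_id", sort = TRUE)
  utils::write.table(out, file.path(d, "subtypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(list(n_tumor_cells = nrow(out),
                    n_basal = sum(out$subtype == "basal"),
                    n_luminal = sum(out$subtype == "luminal"),
                    n_unassigned = sum(out$subtype == "unassigned")), d)
  invisible(NULL)
}

get_gene_counts <- function(counts, gene, cell_ids) {
  if (!gene %in% rownames(counts))
    return(stats::setNames(numeric(length(cell_ids)), cell_ids))
  v <- counts[gene, cell_ids]
  stats::setNames(as.numeric(v), cell_ids)
}

# cell-type labels with tumor cells replaced by their subtype
effective_types <- function(kept, subtypes) {
  ct <- stats::setNames(kept$cell_type, kept$cell_id)
  sub <- subtypes[subtypes$subtype %in% c("basal", "luminal"), ]
  ct[sub$cell_id] <- sub$subtype
  ct
}

stage_de <- function(cfg) {
  counts <- read_counts_dir(input_path(cfg, "counts"))
  kept <- read_kept_cells(cfg)
  genes <- readLines(file.path(stage_dir(cfg, "qc"), "genes_kept.txt"))
  sub_path <- file.path(stage_dir(cfg, "subtype"), "subtypes.tsv")
  subtypes <- if (file.exists(sub_path))
    utils::read.table(sub_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else data.frame(cell_id = character(0), subtype = character(0))
  kept$cell_type <- unname(effective_types(kept, subtypes))
  sub <- counts[genes, kept$cell_id, drop = FALSE]
  keep_cells <- kept[Matrix::colSums(sub) > 0, , drop = FALSE]
  norm <- lognormalize(sub[, keep_cells$cell_id, drop = FALSE])
  de <- de_by_cell_type(norm, keep_cells, genes = genes)
  d <- stage_dir(cfg, "de")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (k in names(de)) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", k), ".tsv")
    utils::write.table(de[[k]], file.path(d, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_report(list(n_comparisons = length(de),
                    skipped = as.list(attr(de, "skipped")),
                    keys = as.list(names(de))), d)
  invisible(NULL)
}

read_de_tables <- function(cfg) {
  d <- stage_dir(cfg, "de")
  rep <- jsonlite::read_json(file.path(d, "report.json"),
                             simplifyVector = TRUE)
  keys <- rep$keys
  tabs <- lapply(keys, function(k) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", k), ".tsv")
    utils::read.table(file.path(d, fn), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  })
  names(tabs) <- keys
  tabs
}

stage_enrich <- function(cfg) {
  de <- read_de_tables(cfg)
  sets <- read_gmt(require_input(input_path(cfg, "gene_sets.gmt")))
  set <- sets[[1]]
  d <- stage_dir(cfg, "enrich")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  m_sum <- screening_matrix(de, set, "sum_fc")
  m_q <- screening_matrix(de, set, "ora_q",
                          p_adj_cut = cfg$p_adj_cut,
                          log2fc_cut = cfg$log2fc_cut)
  m_nes <- screening_matrix(de, set, "nes", n_perm = cfg$gsea_n_perm,
                            seed = cfg$seed)
  for (nm in c("sum_fc", "ora_q", "nes")) {
    m <- switch(nm, sum_fc = m_sum, ora_q = m_q, nes = m_nes)
    utils::write.table(data.frame(cell_type = rownames(m), m,
                                  check.names = FALSE),
                       file.path(d, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  plot_screening_matrix(m_sum, file.path(d, "sum_fc_heatmap.png"),
                        main = names(sets)[1])
  write_report(list(gene_set = names(sets)[1], n_set_genes = length(set),
                    n_comparisons = length(de)), d)
  invisible(NULL)
}

write_manifest <- function(cfg, stages) {
  inputs <- c("variants.tsv", "cells.tsv", "gene_sets.gmt",
              "allele_ref.mtx", "allele_alt.mtx")
  paths <- input_path(cfg, inputs)
  sums <- tools::md5sum(paths[file.exists(paths)])
  names(sums) <- basename(names(sums))
  params <- cfg[setdiff(names(cfg), c("sim", "out_dir", "input_dir"))]
  manifest <- list(
    package = "icbscl",
    version = as.character(utils::packageVersion("icbscl")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    stages = as.list(stages),
    parameters = params,
    input_checksums = as.list(sums)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
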