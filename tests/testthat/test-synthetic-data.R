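test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(n_variants = 0), "n_variants")
  bad_spec <- default_cell_types()
  bad_spec$proportion[1] <- bad_spec$proportion[1] + 0.1
  expect_error(sim_config(cell_type_spec = bad_spec), "sum to 1")
  expect_error(sim_config(tumor_fraction = 1.2), "fractions")
  expect_error(sim_config(qc_fail_fractions = c(mito = 0.1)),
               "low_feature")
})

test_that("fixing the seed reproduces identical outputs", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cells, b$cells)
  expect_identical(simulate_variant_table(cfg), simulate_variant_table(cfg))
  expect_identical(simulate_allele_counts(a, simulate_variant_table(cfg), cfg),
                   simulate_allele_counts(b, simulate_variant_table(cfg), cfg))
})

test_that("simulated VAFs follow the configured clonal distribution", {
  vt <- simulate_variant_table(
    sim_config(seed = 1, n_variants = 1000, clonal_vaf_mean = 0.5,
               clonal_vaf_sd = 0.08, frac_vaf1 = 0))
  expect_equal(median(vt$tumor_vaf), 0.5, tolerance = 0.02 / 0.5)
  expect_true(abs(median(vt$tumor_vaf) - 0.5) <= 0.02)

  all_one <- simulate_variant_table(sim_config(seed = 1, n_variants = 50,
                                               frac_vaf1 = 1))
  expect_true(all(all_one$tumor_vaf == 1))

  # VAF = 1 variants preferentially on the designated hemizygous chromosome
  vt2 <- simulate_variant_table(sim_config(seed = 3, n_variants = 2000,
                                           frac_vaf1 = 0.1))
  at1 <- vt2[vt2$tumor_vaf == 1, ]
  expect_gt(mean(at1$chrom == "chrX"), 0.5)
  expect_true(any(!vt2$truth_pass))
  expect_true(any(vt2$n_callers < 2 & !vt2$truth_pass))
})

test_that("gene-set effects shift mean expression multiplicatively", {
  eff <- default_gene_set_effects()
  # null effects: means equal across conditions within sampling error
  null_eff <- eff; null_eff$effect <- 1
  cfg0 <- tiny_config(seed = 11, gene_set_effects = null_eff)
  sim0 <- simulate_counts(cfg0)
  set_genes <- intersect(ifng_response_genes(), rownames(sim0$counts))
  endo <- sim0$cells$cell_type == "endothelial"
  sparse_mean <- function(m) sum(m) / length(m)
  m_icb <- sparse_mean(sim0$counts[set_genes,
                                   endo & sim0$cells$condition == "ICB"])
  m_ctl <- sparse_mean(sim0$counts[set_genes,
                                   endo & sim0$cells$condition == "control"])
  expect_lt(abs(log2(m_icb / m_ctl)), 0.4)

  # planted x2 effect recovered within a 3 s.d. Monte-Carlo band
  cfg2 <- sim_config(seed = 1, n_cells_per_sample = 250, n_genes = 600,
                     n_variants = 100)
  sim2 <- simulate_counts(cfg2)
  endo2 <- sim2$cells$cell_type == "endothelial"
  a <- sim2$counts[set_genes, endo2 & sim2$cells$condition == "ICB"]
  b <- sim2$counts[set_genes, endo2 & sim2$cells$condition == "control"]
  ratio <- (sum(a) / length(a)) / (sum(b) / length(b))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("planted QC failure counts follow binomial expectations", {
  cfg <- sim_config(seed = 5, n_cells_per_sample = 667, n_genes = 400,
                    n_variants = 50,
                    qc_fail_fractions = c(mito = 0.05, doublet = 0.009,
                                          low_feature = 0.05))
  sim <- simulate_counts(cfg)
  n <- nrow(sim$cells)
  expected <- n * 0.05
  band <- 3 * sqrt(n * 0.05 * 0.95)
  expect_lt(abs(sum(sim$truth$planted_mito) - expected), band)
  expect_lt(abs(sum(sim$truth$planted_low_feature) - expected), band)
  # planted failures carry the signal the filters key on
  expect_true(all(sim$cells$mito_pct[sim$truth$planted_mito] > 12.5))
  lf <- sim$truth$planted_low_feature
  expect_lt(median(sim$cells$gene_count[lf]),
            0.3 * median(sim$cells$gene_count[!lf]))
})

test_that("marker genes exceed n_genes budget raises an error", {
  expect_error(simulate_counts(sim_config(n_genes = 10)), "n_genes")
})

test_that("allele counts respect tumor truth and marginal conservation", {
  ts <- cached_tiny_sim()
  ac <- ts$ac
  expect_identical(dim(ac$ref), dim(ac$alt))
  # non-tumor cells with error rate 0: all alt counts are zero
  cfg0 <- tiny_config(seed = 2, allele_error_rate = 0)
  sim0 <- simulate_counts(cfg0)
  vt0 <- simulate_variant_table(cfg0)
  ac0 <- simulate_allele_counts(sim0, vt0, cfg0)
  normals <- names(which(!sim0$truth$is_tumor))
  expect_identical(sum(ac0$alt[, normals]), 0)

  # tumor cell alt fraction tracks VAF (~0.5) over covered positions
  tumors <- names(which(sim0$truth$is_tumor))
  alt_sum <- sum(ac0$alt[, tumors])
  tot_sum <- sum(ac0$ref[, tumors]) + alt_sum
  expect_gt(tot_sum / 30, 50)  # enough covered positions for the band
  expect_lt(abs(alt_sum / tot_sum - 0.5), 0.05)

  # zero depth: empty matrices, classifier calls everything negative
  cfgz <- tiny_config(seed = 3, variant_depth_mean = 0)
  simz <- simulate_counts(cfgz)
  acz <- simulate_allele_counts(simz, simulate_variant_table(cfgz), cfgz)
  expect_identical(length(acz$ref@x), 0L)
  calls <- classify_cells(acz)
  expect_true(all(calls$status == "variant_negative"))

  expect_error(simulate_allele_counts(simz, simz$cells[0, ], cfgz), "empty")
})

test_that("simulation round-trips through the plain-file writers", {
  ts <- cached_tiny_sim()
  dir <- withr::local_tempdir()
  write_simulation(ts$sim, ts$vt, ts$ac, dir)
  counts2 <- read_counts_dir(file.path(dir, "counts"))
  expect_equal(unname(as.matrix(counts2[1:20, 1:20])),
               unname(as.matrix(ts$sim$counts[1:20, 1:20])))
  vt2 <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(vt2$tumor_vaf, ts$vt$tumor_vaf, tolerance = 1e-12)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets[[1]], ifng_response_genes())
  ac2 <- read_allele_counts(file.path(dir, "allele_ref.mtx"),
                            file.path(dir, "allele_alt.mtx"),
                            file.path(dir, "allele_variants.tsv"),
                            file.path(dir, "allele_barcodes.tsv"))
  expect_equal(sum(ac2$alt), sum(ts$ac$alt))
})
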