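make_cells <- function(n, seed = 1, n_rep = 3, conds = c("control", "ICB")) {
  set.seed(seed)
  data.frame(
    cell_id = sprintf("c%05d", sample.int(n)),
    replicate = sample.int(n_rep, n, TRUE),
    condition = sample(conds, n, TRUE),
    mito_pct = runif(n, 0, 30),
    umi_count = rpois(n, 2000),
    gene_count = rpois(n, 400),
    pruned = runif(n) < 0.05,
    stringsAsFactors = FALSE
  )
}

test_that("mito and feature flags use strict boundaries", {
  cells <- data.frame(mito_pct = c(12.5, 12.51, 99, 0),
                      gene_count = c(100, 99, 100, 0))
  expect_identical(flag_high_mito(cells, 12.5), c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(flag_low_features(cells, 100), c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(flag_low_features(cells, 0), rep(FALSE, 4))
  expect_error(flag_high_mito(data.frame(x = 1)), "mito_pct")
  expect_error(flag_low_features(data.frame(x = 1), 10), "gene_count")
})

test_that("doublet flagging takes the top round(rate*n) per group", {
  # small-group rounding: round(0.09) = 0 flagged
  small <- make_cells(10, seed = 2, n_rep = 1, conds = "control")
  expect_identical(sum(flag_umi_doublets(small, 0.009)), 0L)
  expect_identical(sum(flag_umi_doublets(small, 0)), 0L)

  big <- make_cells(1000, seed = 3, n_rep = 1, conds = "control")
  f <- flag_umi_doublets(big, 0.009)
  expect_identical(sum(f), 9L)
  expect_identical(sort(big$umi_count[f], decreasing = TRUE),
                   sort(big$umi_count, decreasing = TRUE)[1:9])

  # permutation invariance with deterministic tie-break by cell_id
  perm <- sample.int(nrow(big))
  f2 <- flag_umi_doublets(big[perm, ], 0.009)
  expect_setequal(big$cell_id[f], big$cell_id[perm][f2])

  # the per-1000 scaling variant flags rate*n/1000 of each group
  f3 <- flag_umi_doublets(big, 0.009, per_1000 = TRUE)
  expect_identical(sum(f3), 9L)  # n = 1000 so identical here
  mid <- make_cells(500, seed = 4, n_rep = 1, conds = "control")
  expect_identical(sum(flag_umi_doublets(mid, 0.009, per_1000 = TRUE)), 2L)
})

test_that("cell filter cascade reports union and pruned counts correctly", {
  cells <- make_cells(400, seed = 5)
  # nothing fails with impossible cutoffs and no pruning
  c0 <- cells; c0$pruned <- FALSE
  res0 <- apply_cell_filters(c0, mito_cutoff_pct = 100, doublet_rate = 0,
                             feature_cutoff = 0)
  expect_identical(res0$report$n_kept, nrow(cells))

  # one cell fails two criteria: union counts it once
  c1 <- make_cells(50, seed = 6, n_rep = 1, conds = "control")
  c1$pruned <- FALSE
  c1$mito_pct <- 5; c1$gene_count <- 500
  c1$mito_pct[1] <- 50
  c1$umi_count <- 1000; c1$umi_count[1] <- 99999
  res1 <- apply_cell_filters(c1, doublet_rate = 0.02, feature_cutoff = 0)
  expect_identical(res1$report$n_fail_mito, 1L)
  expect_identical(res1$report$n_fail_umi, 1L)
  expect_identical(res1$report$n_fail_union, 1L)

  # report arithmetic: inclusion-exclusion bounds and kept-count identity
  cells2 <- make_cells(600, seed = 7)
  res <- apply_cell_filters(cells2, mito_cutoff_pct = 20,
                            doublet_rate = 0.01, feature_cutoff = 380)
  rp <- res$report
  indiv <- c(rp$n_fail_mito, rp$n_fail_umi, rp$n_fail_feature)
  expect_gte(rp$n_fail_union, max(indiv))
  expect_lte(rp$n_fail_union, sum(indiv))
  expect_identical(rp$n_kept, rp$n_input - rp$n_fail_union - rp$n_fail_pruned)
  # pruned counted only after QC union (disjoint accounting)
  expect_lte(rp$n_fail_pruned, sum(cells2$pruned))

  # union equals brute-force set union on randomized instances
  truth <- oracle_cell_filter_union(cells2, 20, 0.01, 380)
  expect_identical(rp$n_fail_union, sum(truth))
  expect_setequal(res$kept$cell_id,
                  cells2$cell_id[!truth & !(cells2$pruned & !truth)])
})

test_that("planted QC failures are recovered at the designed cutoffs", {
  ts <- cached_tiny_sim()
  sim <- ts$sim
  truth <- ts$sim$truth
  f_mito <- flag_high_mito(sim$cells, 12.5)
  expect_true(all(f_mito[truth$planted_mito[sim$cells$cell_id]]))
  # a cutoff between the two populations recovers exactly the planted cells
  planted <- truth$planted_low_feature[sim$cells$cell_id]
  hi <- min(sim$cells$gene_count[!planted])
  lo <- max(sim$cells$gene_count[planted])
  skip_if(lo >= hi, "populations overlap at this seed")
  cut <- (lo + hi) / 2
  expect_identical(unname(flag_low_features(sim$cells, cut)), unname(planted))
})

test_that("gene filter requires >=2 qualifying cells in every replicate", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:12),
                      replicate = rep(1:3, each = 4),
                      stringsAsFactors = FALSE)
  m <- Matrix::Matrix(0, 3, 12, sparse = TRUE,
                      dimnames = list(c("gA", "gB", "gC"), cells$cell_id))
  m["gA", ] <- 3                      # everywhere: kept
  m["gB", ] <- 1                      # UMI 1 per cell: never qualifies
  m["gC", ] <- 3; m["gC", 9:12] <- c(3, 1, 0, 0)  # one replicate short
  kept <- filter_genes(m, cells)
  expect_identical(kept, "gA")

  cells_bad <- cells; cells_bad$replicate[cells_bad$replicate == 3] <- 2
  extra <- data.frame(cell_id = "c99", replicate = 3)
  expect_error(filter_genes(m, rbind(cells_bad[1:8, ], extra)), "cover")

  # brute-force oracle over random count patterns
  set.seed(8)
  n_genes <- 200; n_cells <- 90
  dm <- matrix(rpois(n_genes * n_cells, 0.8), n_genes, n_cells,
               dimnames = list(sprintf("g%03d", 1:n_genes),
                               sprintf("c%03d", 1:n_cells)))
  cc <- data.frame(cell_id = colnames(dm),
                   replicate = rep(1:5, length.out = n_cells))
  kept2 <- filter_genes(Matrix::Matrix(dm, sparse = TRUE), cc)
  truth <- oracle_gene_filter(dm, cc$replicate)
  expect_identical(kept2, rownames(dm)[truth])
})
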