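norm_toy <- function(n_genes = 20, n_cells = 30, seed = 1) {
  set.seed(seed)
  counts <- Matrix::Matrix(
    matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("c%03d", seq_len(n_cells)))),
    sparse = TRUE)
  lognormalize(counts)
}

test_that("lognormalize matches the closed form and conserves totals", {
  counts <- Matrix::Matrix(matrix(c(0, 1, 9999, 0, 5, 5), 3), sparse = TRUE)
  rownames(counts) <- c("a", "b", "c"); colnames(counts) <- c("x", "y")
  norm <- lognormalize(counts, scale_total = 1e4)
  expect_equal(norm[1, 1], 0)                       # count 0 -> 0
  expect_equal(norm[2, 1], log(2))                  # total 1e4, count 1
  # conservation: rowSums of expm1 per cell equal scale_total
  expect_equal(unname(Matrix::colSums(expm1(norm))), c(1e4, 1e4))

  zero <- counts; zero[, 2] <- 0
  expect_error(lognormalize(zero), "zero total")
})

test_that("identical groups give zero fold change and flat p-values", {
  norm <- norm_toy()
  g <- colnames(norm)[1:10]
  de <- wilcoxon_de(norm, g, g)
  expect_true(all(de$avg_log2fc == 0))
  expect_true(all(de$p_raw > 0.9))
  expect_error(wilcoxon_de(norm, g[1], g), "at least 2")
  expect_error(wilcoxon_de(norm, g, g, genes = character(0)), "empty gene")
})

test_that("rank-sum p reproduces the reference approximation at small n", {
  # the approximation itself must agree exactly with the canonical
  # continuity-corrected implementation; its distance to the exact
  # enumeration is bounded by the enumerated worst case (0.0305 at 4v4)
  set.seed(3)
  for (rep in 1:20) {
    x <- round(runif(4), 3)
    y <- round(runif(4), 3)
    m <- Matrix::Matrix(matrix(c(x, y), 1, 8), sparse = TRUE)
    rownames(m) <- "g"; colnames(m) <- sprintf("c%d", 1:8)
    de <- wilcoxon_de(m, colnames(m)[1:4], colnames(m)[5:8], "g")
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(de$p_raw, ref, tolerance = 1e-12)
    expect_lt(abs(de$p_raw - oracle_exact_ranksum_p(x, y)), 0.031)
  }

  # with ties present, the tie-corrected variance matches the reference
  xt <- c(1, 1, 2, 3); yt <- c(2, 2, 3, 4)
  mt <- Matrix::Matrix(matrix(c(xt, yt), 1, 8), sparse = TRUE,
                       dimnames = list("g", sprintf("c%d", 1:8)))
  det <- wilcoxon_de(mt, sprintf("c%d", 1:4), sprintf("c%d", 5:8), "g")
  reft <- suppressWarnings(
    wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(det$p_raw, reft, tolerance = 1e-12)
})

test_that("swapping groups negates fold change and preserves p", {
  norm <- norm_toy(n_genes = 40, n_cells = 24, seed = 5)
  a <- colnames(norm)[1:12]; b <- colnames(norm)[13:24]
  ab <- wilcoxon_de(norm, a, b)
  ba <- wilcoxon_de(norm, b, a)
  ba <- ba[match(ab$gene, ba$gene), ]
  expect_equal(ab$avg_log2fc, -ba$avg_log2fc)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$pct_a, ba$pct_b)
})

test_that("BH step-up matches the closed form and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (rep in 1:10) {
    p <- runif(50)^2
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))         # independent reference
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p
    perm <- sample.int(50)
    expect_equal(bh_adjust(p[perm]), adj[perm])  # order-stable
  }
})

test_that("DE gene selection applies strict cuts and the exclusion list", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    avg_log2fc = c(1.0, -0.30, 0.26, 0.5),
                    p_adj = c(0.05, 0.01, 0.01, 0.001))
  expect_identical(select_de_genes(res, 0.05, 0.26), c("b", "d"))
  # boundary: p_adj = 0.05 excluded, |lfc| = 0.26 excluded
  expect_false("a" %in% select_de_genes(res, 0.05, 0.26))
  expect_false("c" %in% select_de_genes(res, 0.05, 0.26))
  expect_identical(select_de_genes(res, 0.05, 0.26, exclude = "d"), "b")

  set.seed(7)
  tab <- data.frame(gene = sprintf("g%03d", 1:300),
                    avg_log2fc = rnorm(300),
                    p_adj = runif(300)^1.5)
  excl <- sample(tab$gene, 30)
  expect_identical(select_de_genes(tab, 0.05, 0.26, excl),
                   oracle_select_de(tab, 0.05, 0.26, excl))
})

test_that("planted 2x effects are recovered at n=300 per group", {
  set.seed(8)
  n_genes <- 400; n <- 300
  mu <- rlnorm(n_genes, log(0.3), 1)
  # plant on genes expressed above the detection floor: a 2x effect on a
  # gene with mean ~0.01 counts is invisible at any n
  planted <- order(mu, decreasing = TRUE)[51:100]
  mu_b <- mu; mu_a <- mu; mu_a[planted] <- mu_a[planted] * 2
  a <- matrix(rnbinom(n_genes * n, size = 2, mu = mu_a), n_genes, n)
  b <- matrix(rnbinom(n_genes * n, size = 2, mu = mu_b), n_genes, n)
  m <- Matrix::Matrix(cbind(a, b), sparse = TRUE)
  rownames(m) <- sprintf("g%03d", 1:n_genes)
  colnames(m) <- sprintf("c%03d", 1:(2 * n))
  norm <- lognormalize(m)
  de <- wilcoxon_de(norm, colnames(m)[1:n], colnames(m)[n + 1:n])
  hit <- de$gene[de$p_adj < 0.05 & de$avg_log2fc > 0]
  recovered <- mean(sprintf("g%03d", planted) %in% hit)
  expect_gte(recovered, 0.9)
})

test_that("per-cell-type DE skips tiny groups and reports the rest", {
  ts <- cached_tiny_sim()
  sim <- ts$sim
  sub <- sim$cells[sim$cells$cell_type %in% c("endothelial", "B"), ]
  sub <- rbind(sub, within(sim$cells[1, ], cell_type <- "rare"))
  norm <- lognormalize(sim$counts[, sub$cell_id])
  de <- de_by_cell_type(norm, sub, genes = rownames(norm)[1:50])
  expect_true(length(de) >= 6)  # 2 types x 3 condition pairs
  expect_true(all(grepl("rare", attr(de, "skipped"))))
  expect_s3_class(de[[1]], "data.frame")
})
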