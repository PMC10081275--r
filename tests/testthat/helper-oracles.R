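# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately re-state each predicate as a per-record loop,
# independent of the vectorized implementation paths.

oracle_variant_filter <- function(tab, crit = filter_criteria()) {
  vapply(seq_len(nrow(tab)), function(r) {
    nc <- if (!is.null(tab$n_callers)) tab$n_callers[r]
          else length(strsplit(tab$callers[r], ",")[[1]])
    nc >= crit$min_callers &&
      tab$normal_cov[r] > crit$min_normal_cov &&
      tab$tumor_cov[r] > crit$min_tumor_cov &&
      tab$normal_vaf[r] < crit$max_normal_vaf &&
      tab$tumor_vaf[r] > crit$min_tumor_vaf
  }, logical(1))
}

oracle_cell_filter_union <- function(cells, mito_cut, doublet_rate,
                                     feat_cut) {
  fail <- rep(FALSE, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (cells$mito_pct[i] > mito_cut) fail[i] <- TRUE
    if (cells$gene_count[i] < feat_cut) fail[i] <- TRUE
  }
  # doublets: per-group sort-based top-k
  for (g in unique(paste(cells$replicate, cells$condition))) {
    idx <- which(paste(cells$replicate, cells$condition) == g)
    k <- floor(doublet_rate * length(idx) + 0.5)
    if (k > 0) {
      ord <- idx[order(-cells$umi_count[idx], cells$cell_id[idx])]
      fail[ord[seq_len(k)]] <- TRUE
    }
  }
  fail
}

oracle_gene_filter <- function(counts_dense, replicates, min_cells = 2,
                               min_umi = 2) {
  keep <- logical(nrow(counts_dense))
  for (g in seq_len(nrow(counts_dense))) {
    ok <- TRUE
    for (r in unique(replicates)) {
      n_qual <- sum(counts_dense[g, replicates == r] >= min_umi)
      if (n_qual < min_cells) { ok <- FALSE; break }
    }
    keep[g] <- ok
  }
  keep
}

oracle_classify <- function(ref_dense, alt_dense, min_positions = 2,
                            min_coverage = 20, min_alt = 5, min_vaf = 0.1) {
  vapply(seq_len(ncol(ref_dense)), function(j) {
    nq <- 0L
    for (i in seq_len(nrow(ref_dense))) {
      cov <- ref_dense[i, j] + alt_dense[i, j]
      if (cov == 0) next
      if (cov > min_coverage && alt_dense[i, j] > min_alt &&
          alt_dense[i, j] / cov > min_vaf) nq <- nq + 1L
    }
    nq >= min_positions
  }, logical(1))
}

oracle_select_de <- function(results, p_cut, lfc_cut, exclude = NULL) {
  out <- character(0)
  for (i in seq_len(nrow(results))) {
    if (results$p_adj[i] < p_cut && abs(results$avg_log2fc[i]) > lfc_cut)
      out <- c(out, results$gene[i])
  }
  setdiff(out, exclude)
}

# exact two-sided rank-sum p by enumeration of all group-A assignments
oracle_exact_ranksum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(r), nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

# literal transcription of the weighted running-sum ES definition
oracle_gsea_es <- function(scores, hits, weight = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; h <- hits[ord]
  nh <- sum(h); n <- length(s)
  denom <- sum(abs(s[h])^weight)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (h[i]) abs(s[i])^weight / denom else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# direct hypergeometric upper-tail mass summation
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# random candidate variant table exercising every threshold boundary
random_variant_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    n_callers = sample(1:4, n, TRUE),
    callers = "x",
    normal_cov = sample(c(28:32, 60), n, TRUE),
    tumor_cov = sample(c(28:32, 60), n, TRUE),
    normal_vaf = sample(c(0, 0.04, 0.05, 0.06, 0.2), n, TRUE),
    tumor_vaf = sample(c(0.04, 0.05, 0.06, 0.5, 1), n, TRUE),
    chrom = sample(c("chr1", "chrX"), n, TRUE),
    variant_type = "SNV",
    stringsAsFactors = FALSE
  )
}
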