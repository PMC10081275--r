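#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance: upper-tail hypergeometric `P(X >= k)` with
#' population `N` (universe), `K` successes (set within universe) and
#' `n_list` draws; q-values are BH-adjusted across the tested sets.
#' Query genes outside the universe are dropped with a warning; sets are
#' intersected with the universe.
#'
#' @param query Character vector of query genes (e.g. DE genes).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: the detected-gene background.
#' @return data.frame with `set_name`, `k`, `n_list`, `K`, `N`, `p_raw`,
#'   `q`.
#' @examples
#' ora_test(letters[1:5], list(s = letters[1:5]), letters[1:20])
#' @export
ora_test <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L)
    stop("empty universe", call. = FALSE)
  drop <- setdiff(query, universe)
  if (length(drop))
    warning(length(drop), " query gene(s) outside the universe dropped",
            call. = FALSE)
  query <- intersect(unique(query), universe)
  N <- length(universe)
  n_list <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    # upper tail P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n_list, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n_list = n_list, K = K, N = N,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_raw)
  out
}

#' Preranked gene set enrichment (weighted KS statistic)
#'
#' The GSEAPreranked statistic: walking down the ranked list, the running
#' sum gains `|score|^weight / sum(|score|^weight over hits)` at each set
#' member and loses `1 / (N - N_hits)` at each non-member; the enrichment
#' score (ES) is the extremum of the running sum (signed).  The null
#' permutes set membership uniformly over the ranked genes; NES divides ES
#' by the mean |null ES| of matching sign, and the permutation p-value is
#' `(1 + #{null ES at least as extreme in absolute value}) / (n_perm + 1)`.
#'
#' @param ranked Named numeric vector of scores (e.g. average log2 fold
#'   changes), or a two-column data.frame (gene, score).  Sorted
#'   internally in decreasing order.
#' @param gene_set Character vector of member symbols.
#' @param weight Score weighting exponent (1 = classic weighted GSEA).
#' @param n_perm Membership permutations for the null.
#' @param seed Integer seed for the permutation stream.
#' @return list of class `gsea_result`: `set_name` attr-free fields `es`,
#'   `nes`, `p_perm`, `n_perm`, `n_hits`, `running` (the running sum).
#' @export
gsea_preranked <- function(ranked, gene_set, weight = 1, n_perm = 1000L,
                           seed = 1L) {
  if (is.data.frame(ranked))
    ranked <- stats::setNames(ranked[[2]], ranked[[1]])
  if (any(!is.finite(ranked)))
    stop("scores must be finite", call. = FALSE)
  ranked <- sort(ranked, decreasing = TRUE)
  genes <- names(ranked)
  hits <- genes %in% gene_set
  n_hits <- sum(hits)
  if (n_hits == 0L)
    stop("no gene-set member present in the ranking", call. = FALSE)
  if (n_hits == length(genes))
    stop("gene set covers the whole ranking; miss penalty undefined",
         call. = FALSE)

  es_run <- running_es(ranked, hits, weight)
  es <- es_run$es

  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(length(genes))
    h[sample.int(length(genes), n_hits)] <- TRUE
    running_es(ranked, h, weight)$es
  }, numeric(1))

  # NES normalizes by the sign-matched null mean (the published GSEA
  # procedure); the permutation p counts all nulls at least as extreme in
  # |ES|, keeping p exchangeable (hence uniform under a random set)
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p_perm <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)

  structure(list(es = es, nes = nes, p_perm = p_perm, n_perm = n_perm,
                 n_hits = n_hits, running = es_run$running),
            class = "gsea_result")
}

# running-sum ES for a fixed hit indicator over a sorted score vector
running_es <- function(ranked, hits, weight) {
  n <- length(ranked)
  n_hits <- sum(hits)
  w <- abs(ranked)^weight
  inc <- numeric(n)
  hit_w <- w[hits]
  if (sum(hit_w) == 0) hit_w <- rep(1, n_hits)  # all-zero scores: flat hits
  inc[hits] <- hit_w / sum(hit_w)
  inc[!hits] <- -1 / (n - n_hits)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES %.3f, NES %.3f, permutation p %.4g (%d hits, %d perms)\n",
              x$es, x$nes, x$p_perm, x$n_hits, x$n_perm))
  invisible(x)
}

#' Sum of fold changes over a gene set
#'
#' The simple directional screening metric: the sum of average log2 fold
#' changes over every detected gene of the set (no p-value filter;
#' "detected" = present in the DE table's gene universe).  Positive values
#' mean the set skews up-regulated in group A of the comparison.
#'
#' @param de_results A [wilcoxon_de()] table.
#' @param gene_set Character vector of member symbols.
#' @return list with `sum_log2fc` and `n_genes_detected`.
#' @export
sum_fold_changes <- function(de_results, gene_set) {
  idx <- de_results$gene %in% gene_set
  list(sum_log2fc = sum(de_results$avg_log2fc[idx]),
       n_genes_detected = sum(idx))
}

#' Assemble a cell-type x comparison screening matrix
#'
#' Collapses a list of per-(cell type, comparison) DE tables into one
#' matrix of a chosen gene-set statistic: `sum_fc` (sum of fold changes),
#' `ora_q` (BH q of the overrepresentation test on the DE-gene list), or
#' `nes` (preranked GSEA normalized enrichment score).  Skipped
#' comparisons stay `NA`.
#'
#' @param de_tables Named list as produced by [de_by_cell_type()]
#'   (`"<type>|<A>_vs_<B>"` keys).
#' @param gene_set Character vector of member symbols.
#' @param metric One of `"sum_fc"`, `"ora_q"`, `"nes"`.
#' @param p_adj_cut,log2fc_cut DE-gene cuts for `ora_q`.
#' @param n_perm,seed Permutation settings for `nes`.
#' @return Numeric matrix, cell types x comparisons.
#' @export
screening_matrix <- function(de_tables, gene_set,
                             metric = c("sum_fc", "ora_q", "nes"),
                             p_adj_cut = 0.05, log2fc_cut = 0.26,
                             n_perm = 1000L, seed = 1L) {
  metric <- match.arg(metric)
  keys <- names(de_tables)
  parts <- strsplit(keys, "|", fixed = TRUE)
  types <- unique(vapply(parts, `[[`, "", 1L))
  comps <- unique(vapply(parts, `[[`, "", 2L))
  m <- matrix(NA_real_, length(types), length(comps),
              dimnames = list(types, comps))
  for (k in seq_along(keys)) {
    tab <- de_tables[[k]]
    if (is.null(tab)) next
    val <- switch(metric,
      sum_fc = sum_fold_changes(tab, gene_set)$sum_log2fc,
      ora_q = {
        degenes <- select_de_genes(tab, p_adj_cut, log2fc_cut)
        if (length(degenes) == 0) NA_real_
        else ora_test(degenes, list(set = gene_set), tab$gene)$q
      },
      nes = tryCatch(
        gsea_preranked(stats::setNames(tab$avg_log2fc, tab$gene),
                       gene_set, n_perm = n_perm, seed = seed)$nes,
        error = function(e) NA_real_))
    m[parts[[k]][1], parts[[k]][2]] <- val
  }
  m
}

#' Render a screening matrix as a heatmap
#'
#' @param m Matrix from [screening_matrix()].
#' @param path Output image path (`.png` or `.svg`); `NULL` plots to the
#'   active device.
#' @param main Plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_screening_matrix <- function(m, path = NULL, main = "gene-set screen") {
  open_dev <- !is.null(path)
  if (open_dev) {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 8, height = 6)
    else grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  mm <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  graphics::image(t(mm), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(25, "Blue-Red 3"))
  graphics::axis(1, at = seq(0, 1, length.out = ncol(mm)),
                 labels = colnames(mm), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(mm)),
                 labels = rownames(mm), las = 2, cex.axis = 0.7)
  invisible(path)
}
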