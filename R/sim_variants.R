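#' Simulate a somatic variant candidate table
#'
#' Draws a table of candidate somatic calls emulating consensus calling on
#' a highly clonal tumor line: tumor VAFs follow a clipped normal centred
#' at `clonal_vaf_mean`, a `frac_vaf1` subpopulation sits at VAF exactly 1
#' and is preferentially placed on a designated hemizygous chromosome, and
#' caller support / coverage / normal contamination are drawn so that a
#' known subset of records fails each filtering criterion.  The ground
#' truth pass/fail flag (`truth_pass`) applies the consensus filter
#' definition to the drawn fields.
#'
#' @param config A [sim_config()].
#' @return data.frame of variant records with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_type`, `callers`
#'   (comma-separated), `n_callers`, `normal_cov`, `tumor_cov`,
#'   `normal_vaf`, `tumor_vaf`, `gene`, `consequence`, `truth_pass`.
#' @examples
#' vt <- simulate_variant_table(sim_config(seed = 1, n_variants = 200))
#' median(vt$tumor_vaf)
#' @export
simulate_variant_table <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_variants
  set.seed(config$seed + 101L)

  chroms <- c(paste0("chr", 1:19), "chrX")
  chrom <- sample(chroms[1:19], n, replace = TRUE)
  pos <- sample.int(1.2e8, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  variant_type <- ifelse(stats::runif(n) < 0.002, "indel", "SNV")

  # clonal VAF, clipped to (0, 1]
  vaf <- stats::rnorm(n, config$clonal_vaf_mean, config$clonal_vaf_sd)
  vaf <- pmin(pmax(vaf, 0.01), 1)

  # VAF = 1 subpopulation, preferentially on the hemizygous chromosome
  n1 <- round(config$frac_vaf1 * n)
  if (n1 > 0) {
    idx1 <- sample.int(n, n1)
    vaf[idx1] <- 1
    on_hemi <- stats::runif(n1) < config$vaf1_chrom_prob
    chrom[idx1[on_hemi]] <- config$vaf1_chrom
  }

  caller_pool <- c("mutect", "strelka", "varscan", "pindel")
  n_callers <- sample(1:4, n, replace = TRUE,
                      prob = c(0.15, 0.35, 0.30, 0.20))
  callers <- vapply(n_callers, function(k)
    paste(sort(sample(caller_pool, k)), collapse = ","), "")

  # coverage mostly deep, with a planted shallow subset
  normal_cov <- stats::rnbinom(n, size = 10, mu = 70)
  tumor_cov <- stats::rnbinom(n, size = 10, mu = 70)
  shallow_n <- stats::runif(n) < 0.06
  shallow_t <- stats::runif(n) < 0.06
  normal_cov[shallow_n] <- sample(0:30, sum(shallow_n), replace = TRUE)
  tumor_cov[shallow_t] <- sample(0:30, sum(shallow_t), replace = TRUE)

  # normal VAF ~ 0 except a planted contaminated subset
  normal_vaf <- pmin(stats::rexp(n, rate = 200), 1)
  contam <- stats::runif(n) < 0.05
  normal_vaf[contam] <- stats::runif(sum(contam), 0.05, 0.4)

  gene_pool <- c(sprintf("Gene%04d", 1:200),
                 "Kras", "Trp53", "Kdm6a", "Atm", "Fat1")
  gene <- sample(gene_pool, n, replace = TRUE)
  consequence <- sample(c("missense", "synonymous", "stop_gained",
                          "splice_region"), n, replace = TRUE,
                        prob = c(0.55, 0.3, 0.05, 0.1))

  out <- data.frame(
    variant_id = sprintf("var%05d", seq_len(n)),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_type = variant_type, callers = callers, n_callers = n_callers,
    normal_cov = normal_cov, tumor_cov = tumor_cov,
    normal_vaf = normal_vaf, tumor_vaf = vaf,
    gene = gene, consequence = consequence,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$truth_pass <- out$n_callers >= 2 & out$normal_cov > 30 &
    out$tumor_cov > 30 & out$normal_vaf < 0.05 & out$tumor_vaf > 0.05
  out
}
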