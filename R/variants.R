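#' Consensus filtering criteria for somatic variant calls
#'
#' Thresholds applied with strict comparisons: kept variants were called
#' by at least `min_callers` callers, have normal and tumor coverage
#' strictly above `min_normal_cov` / `min_tumor_cov`, normal VAF strictly
#' below `max_normal_vaf`, and tumor VAF strictly above `min_tumor_vaf`.
#'
#' @param min_callers Minimum number of supporting callers (>=).
#' @param min_normal_cov,min_tumor_cov Coverage thresholds in reads (>).
#' @param max_normal_vaf Normal VAF ceiling as a fraction (<).
#' @param min_tumor_vaf Tumor VAF floor as a fraction (>).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(min_callers = 2L, min_normal_cov = 30,
                            min_tumor_cov = 30, max_normal_vaf = 0.05,
                            min_tumor_vaf = 0.05) {
  stopifnot(min_callers >= 0, min_normal_cov >= 0, min_tumor_cov >= 0,
            max_normal_vaf >= 0, min_tumor_vaf >= 0)
  structure(list(min_callers = min_callers,
                 min_normal_cov = min_normal_cov,
                 min_tumor_cov = min_tumor_cov,
                 max_normal_vaf = max_normal_vaf,
                 min_tumor_vaf = min_tumor_vaf),
            class = "filter_criteria")
}

required_variant_fields <- c("callers", "normal_cov", "tumor_cov",
                             "normal_vaf", "tumor_vaf")

# Auto-detect percent-scale VAF columns (max > 1.5) and rescale to fractions.
normalize_vaf_scale <- function(x, column) {
  if (length(x) && max(x, na.rm = TRUE) > 1.5) {
    message(column, " looks percent-scaled (max ", round(max(x), 2),
            "); dividing by 100")
    x <- x / 100
  }
  x
}

#' Filter candidate somatic variants by the consensus criteria
#'
#' Applies the five-clause consensus filter (caller support, normal and
#' tumor coverage, normal and tumor VAF; see [filter_criteria()]) and
#' reports, per criterion, how many candidates fail it - counted
#' independently, so one variant can contribute to several counts.
#'
#' @param candidates data.frame of variant records; requires columns
#'   `callers` (comma-separated caller labels, or an integer `n_callers`),
#'   `normal_cov`, `tumor_cov`, `normal_vaf`, `tumor_vaf`.  VAF columns
#'   may be fractions or percentages (auto-detected).
#' @param criteria A [filter_criteria()].
#' @return list with `kept` (data.frame), `rejected` (data.frame), and
#'   `rejection_counts` (named integer vector, one per criterion plus
#'   `any`).
#' @examples
#' vt <- simulate_variant_table(sim_config(seed = 1, n_variants = 100))
#' res <- filter_somatic_variants(vt)
#' res$rejection_counts
#' @export
filter_somatic_variants <- function(candidates, criteria = filter_criteria()) {
  need <- setdiff(required_variant_fields, names(candidates))
  if ("n_callers" %in% names(candidates))
    need <- setdiff(need, "callers")
  if (length(need))
    stop("candidate table is missing required field(s): ",
         paste(need, collapse = ", "), call. = FALSE)

  n_callers <- if ("n_callers" %in% names(candidates)) {
    as.integer(candidates$n_callers)
  } else {
    lengths(strsplit(as.character(candidates$callers), ","))
  }
  nvaf <- normalize_vaf_scale(candidates$normal_vaf, "normal_vaf")
  tvaf <- normalize_vaf_scale(candidates$tumor_vaf, "tumor_vaf")

  fail <- cbind(
    callers    = n_callers < criteria$min_callers,
    normal_cov = !(candidates$normal_cov > criteria$min_normal_cov),
    tumor_cov  = !(candidates$tumor_cov > criteria$min_tumor_cov),
    normal_vaf = !(nvaf < criteria$max_normal_vaf),
    tumor_vaf  = !(tvaf > criteria$min_tumor_vaf)
  )
  any_fail <- rowSums(fail) > 0
  counts <- c(as.integer(colSums(fail)), sum(any_fail))
  names(counts) <- c(colnames(fail), "any")
  list(kept = candidates[!any_fail, , drop = FALSE],
       rejected = candidates[any_fail, , drop = FALSE],
       rejection_counts = counts)
}

#' Summarize the clonality profile of a filtered variant set
#'
#' Computes the median tumor VAF (mean-of-central-pair for even n), a
#' binned VAF histogram, the count of variants at VAF exactly 1, and the
#' chromosome composition of that VAF = 1 subpopulation - the summary used
#' to establish that a tumor line is clonal (unimodal VAF near 0.5) with a
#' hemizygous / copy-loss subpopulation at VAF = 1.
#'
#' @param kept data.frame with `tumor_vaf` (fraction or percent,
#'   auto-detected), optionally `variant_type` and `chrom`.
#' @param snv_only Restrict to SNVs (requires `variant_type`).
#' @param breaks Histogram breaks on the VAF fraction scale.
#' @param tol Tolerance for VAF == 1 on the fraction scale.
#' @return list of class `vaf_summary`: `n_variants`, `median_vaf`,
#'   `histogram`, `n_vaf_one`, `chrom_fractions_at_vaf_one`.
#' @export
vaf_summary <- function(kept, snv_only = TRUE, breaks = seq(0, 1, 0.05),
                        tol = 1e-9) {
  if (nrow(kept) == 0L)
    stop("vaf_summary on an empty variant table", call. = FALSE)
  tab <- kept
  if (snv_only && "variant_type" %in% names(tab))
    tab <- tab[tab$variant_type == "SNV", , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no SNVs left after restricting to SNVs", call. = FALSE)
  vaf <- normalize_vaf_scale(tab$tumor_vaf, "tumor_vaf")
  at_one <- abs(vaf - 1) <= tol
  chrom_frac <- numeric(0)
  if (any(at_one) && "chrom" %in% names(tab)) {
    tt <- table(tab$chrom[at_one])
    chrom_frac <- as.numeric(tt) / sum(tt)
    names(chrom_frac) <- names(tt)
  }
  structure(list(
    n_variants = nrow(tab),
    median_vaf = stats::median(vaf),
    histogram = graphics::hist(vaf, breaks = breaks, plot = FALSE)$counts,
    n_vaf_one = sum(at_one),
    chrom_fractions_at_vaf_one = chrom_frac
  ), class = "vaf_summary")
}

#' @export
print.vaf_summary <- function(x, ...) {
  cat(sprintf("%d variants; median VAF %.4f; %d at VAF = 1\n",
              x$n_variants, x$median_vaf, x$n_vaf_one))
  invisible(x)
}

#' Mutation burden per megabase
#'
#' @param n_variants Number of (filtered) variants.
#' @param target_size_mb Size of the sequenced target space in megabases.
#'   The denominator is deliberately a parameter: exome variant counts are
#'   sometimes normalized by genome size, and the right choice depends on
#'   the capture design.
#' @return Mutations per Mb.
#' @examples
#' mutation_burden(10, 2)  # 5 mutations/Mb
#' @export
mutation_burden <- function(n_variants, target_size_mb) {
  if (target_size_mb <= 0)
    stop("target_size_mb must be positive", call. = FALSE)
  n_variants / target_size_mb
}

#' Intersect kept variants with a driver-gene list
#'
#' Matches kept variants against known driver genes, optionally mapping
#' human symbols to mouse homologs first; matching is case-sensitive after
#' mapping.
#'
#' @param kept data.frame with a `gene` column.
#' @param driver_genes Character vector of driver symbols (e.g. human).
#' @param homology_map Named character vector mapping input symbols to the
#'   annotation's symbols (`NULL` = identity).  Unmapped symbols are
#'   reported via a warning, not an error.
#' @return data.frame with one row per (gene, variant) match.
#' @export
driver_gene_intersect <- function(kept, driver_genes, homology_map = NULL) {
  if (length(driver_genes) == 0L)
    return(kept[0, , drop = FALSE])
  mapped <- driver_genes
  if (!is.null(homology_map)) {
    mapped <- unname(homology_map[driver_genes])
    unmapped <- driver_genes[is.na(mapped)]
    if (length(unmapped))
      warning("unmapped driver symbols: ", paste(unmapped, collapse = ", "),
              call. = FALSE)
    mapped <- mapped[!is.na(mapped)]
  }
  hits <- kept[kept$gene %in% mapped, , drop = FALSE]
  hits[order(hits$gene), , drop = FALSE]
}

#' Read a somatic variant table from TSV or VCF
#'
#' The TSV dialect needs named columns matching the `VariantRecord`
#' fields.  For `.vcf` input a minimal parser extracts CHROM/POS/REF/ALT
#' plus per-sample `AD`/`DP` FORMAT fields for samples named (or ordered)
#' normal, tumor, computing coverages and VAFs from allele depths.
#'
#' @param path Input file; `.vcf` triggers VCF parsing, anything else is
#'   read as TSV with a header.
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  if (!grepl("\\.vcf$", path, ignore.case = TRUE)) {
    return(utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = ""))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  rows <- strsplit(body[-1], "\t")
  samples <- header[-(1:9)]
  if (length(samples) < 2)
    stop("VCF must carry normal and tumor sample columns", call. = FALSE)
  normal_i <- if ("NORMAL" %in% toupper(samples))
    which(toupper(samples) == "NORMAL") else 1L
  tumor_i <- if ("TUMOR" %in% toupper(samples))
    which(toupper(samples) == "TUMOR") else 2L
  parse_sample <- function(fmt, val) {
    keys <- strsplit(fmt, ":")[[1]]
    vals <- strsplit(val, ":")[[1]]
    ad <- vals[match("AD", keys)]
    dp <- suppressWarnings(as.numeric(vals[match("DP", keys)]))
    alt_reads <- NA_real_
    if (!is.na(ad)) {
      parts <- suppressWarnings(as.numeric(strsplit(ad, ",")[[1]]))
      alt_reads <- parts[2]
      if (is.na(dp)) dp <- sum(parts, na.rm = TRUE)
    }
    c(cov = dp, vaf = if (!is.na(dp) && dp > 0) alt_reads / dp else 0)
  }
  rec <- lapply(rows, function(f) {
    nrm <- parse_sample(f[9], f[9 + normal_i])
    tmr <- parse_sample(f[9], f[9 + tumor_i])
    info <- f[8]
    callers <- sub(".*(^|;)CALLERS=([^;]*).*", "\\2",
                   if (grepl("CALLERS=", info)) info else "CALLERS=unknown")
    data.frame(chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
               variant_type = if (nchar(f[4]) == 1 && nchar(f[5]) == 1)
                 "SNV" else "indel",
               callers = callers,
               normal_cov = nrm[["cov"]], tumor_cov = tmr[["cov"]],
               normal_vaf = nrm[["vaf"]], tumor_vaf = tmr[["vaf"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rec)
}
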