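#' Average allele counts over the two reference mappings
#'
#' Reads of an F1 hybrid align more efficiently to the reference matching
#' the allele they carry, inflating that allele's count (reference mapping
#' bias). With counts obtained from mapping against both parental
#' references, the elementwise mean of the two mappings cancels the bias:
#' each allele is the reference allele in exactly one of the two mappings.
#' Averaged counts may be half-integers.
#'
#' @param counts data frame of per-SNV counts with columns `count_A_refA`,
#'   `count_B_refA`, `count_A_refB`, `count_B_refB` (see
#'   [simulate_counts()] / [read_counts_tsv()]).
#' @return `counts` with numeric columns `avg_A` and `avg_B` appended; the
#'   original mapping counts are preserved.
#' @export
average_dual_mapping <- function(counts) {
  need <- c("count_A_refA", "count_B_refA", "count_A_refB", "count_B_refB")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    stop("both reference mappings are required; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyNA(counts[need]))
    stop("both reference mappings are required; NA counts found",
         call. = FALSE)
  counts$avg_A <- (counts$count_A_refA + counts$count_A_refB) / 2
  counts$avg_B <- (counts$count_B_refA + counts$count_B_refB) / 2
  counts
}

#' Filter SNVs on validation status and read depth
#'
#' Retains an SNV only if it belongs to the validated strain-distinguishing
#' set and its total averaged read count (both alleles) reaches `min_reads`.
#' The depth threshold (8 by default) is the level at which known imprinted
#' genes are consistently detected, making shallower SNVs unreliable
#' reporters of allelic imbalance.
#'
#' @param counts averaged counts from [average_dual_mapping()].
#' @param snv_records optional data frame with columns `snv_id` and
#'   `validated` (e.g. from [read_snv_vcf()]); SNVs absent from it are
#'   treated as unvalidated. When `NULL`, all SNVs are taken as validated.
#' @param min_reads minimum total averaged reads at the SNV (inclusive).
#' @return the retained rows of `counts`; the dropped SNVs and the reason
#'   for each are attached as `attr(, "filter_log")`.
#' @export
filter_snvs <- function(counts, snv_records = NULL, min_reads = 8) {
  if (is.null(counts$avg_A) || is.null(counts$avg_B))
    stop("run average_dual_mapping() before filtering", call. = FALSE)
  validated <- if (is.null(snv_records)) rep(TRUE, nrow(counts)) else {
    stopifnot(all(c("snv_id", "validated") %in% names(snv_records)))
    v <- snv_records$validated[match(counts$snv_id, snv_records$snv_id)]
    !is.na(v) & v
  }
  deep <- counts$avg_A + counts$avg_B >= min_reads
  keep <- validated & deep
  dropped <- counts$snv_id[!keep]
  reason <- ifelse(!validated[!keep], "not_validated", "low_depth")
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(snv_id = dropped, reason = reason,
                                        stringsAsFactors = FALSE)
  out
}

#' Sum averaged allele counts over a gene's retained SNVs
#'
#' @param counts filtered, averaged counts (one sample; may contain many
#'   genes).
#' @return data frame with one row per gene: `gene_id`, `n_A`, `n_B`,
#'   `n_snvs_retained`.
#' @export
aggregate_genes <- function(counts) {
  if (nrow(counts) == 0L)
    return(data.frame(gene_id = character(0), n_A = numeric(0),
                      n_B = numeric(0), n_snvs_retained = integer(0)))
  g <- factor(counts$gene_id, levels = unique(counts$gene_id))
  data.frame(gene_id = levels(g),
             n_A = as.numeric(tapply(counts$avg_A, g, sum)),
             n_B = as.numeric(tapply(counts$avg_B, g, sum)),
             n_snvs_retained = as.integer(tabulate(g)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests whether the two alleles of a gene are equally represented among its
#' summed reads, i.e. a binomial success probability of 0.5. Averaged counts
#' can be half-integers, so both are first rounded half-to-even; the
#' two-sided p-value then sums all outcomes whose point probability does not
#' exceed that of the observed count (minimum-likelihood method, the
#' convention of [stats::binom.test()]), which at p = 0.5 equals the doubled
#' tail except at ties.
#'
#' @param n_A,n_B numeric vectors of allele-A and allele-B read counts
#'   (recycled to common length).
#' @return numeric vector of p-values in `(0, 1]`; `NA` where the rounded
#'   total is zero (such genes are not assayable).
#' @export
#' @examples
#' binomial_dae_test(8, 8)   # 1: perfectly balanced
#' binomial_dae_test(8, 0)   # 2 * 0.5^8
binomial_dae_test <- function(n_A, n_B) {
  k <- max(length(n_A), length(n_B))
  n_A <- rep_len(n_A, k); n_B <- rep_len(n_B, k)
  if (any(n_A < 0 | n_B < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  x <- round(n_A)
  n <- x + round(n_B)
  vapply(seq_len(k), function(i) {
    if (is.na(n[i]) || n[i] == 0) return(NA_real_)
    d <- dbinom(0:n[i], n[i], 0.5)
    # relative tolerance guards ties against floating-point noise
    min(1, sum(d[d <= d[x[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values, preserving input order. A thin,
#' validated wrapper around [stats::p.adjust()] so that the stratification
#' policy (adjustment within each cross direction x tissue analysis) has a
#' single point of application.
#'
#' @param p numeric vector of p-values in `(0, 1]` (NA allowed and
#'   propagated).
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Gene-level allele summary for one pooled sample
#'
#' The full per-sample analysis path: average the dual-reference mappings,
#' filter SNVs on validation and read depth, sum retained SNVs within genes,
#' test each assayable gene for allelic imbalance with the exact binomial
#' test, and adjust across the sample's assayable genes by
#' Benjamini-Hochberg. Genes present in the input but with no retained SNV
#' are reported as not assayable.
#'
#' @param counts per-SNV dual-mapping counts for a single cross direction
#'   and tissue (an error if mixed).
#' @param snv_records optional validated SNV set (see [filter_snvs()]).
#' @param min_reads SNV read-depth threshold (total averaged reads).
#' @param fdr_alpha recorded in the result's attributes for downstream use.
#' @return data frame with one row per gene: `gene_id`, `cross_direction`,
#'   `tissue`, `n_A`, `n_B`, `frac_A`, `n_snvs_retained`, `assayable`,
#'   `p_binom`, `q_bh`.
#' @export
gene_allele_summary <- function(counts, snv_records = NULL, min_reads = 8,
                                fdr_alpha = 0.05) {
  dir <- unique(counts$cross_direction)
  tis <- unique(counts$tissue)
  if (length(dir) != 1L || length(tis) != 1L)
    stop("counts must come from a single cross direction and tissue; ",
         "split the table first", call. = FALSE)
  avg <- average_dual_mapping(counts)
  kept <- filter_snvs(avg, snv_records, min_reads)
  agg <- aggregate_genes(kept)
  genes <- unique(counts$gene_id)
  i <- match(genes, agg$gene_id)
  out <- data.frame(gene_id = genes,
                    cross_direction = dir,
                    tissue = tis,
                    n_A = ifelse(is.na(i), 0, agg$n_A[i]),
                    n_B = ifelse(is.na(i), 0, agg$n_B[i]),
                    n_snvs_retained = ifelse(is.na(i), 0L,
                                             agg$n_snvs_retained[i]),
                    stringsAsFactors = FALSE)
  tot <- out$n_A + out$n_B
  out$frac_A <- ifelse(tot > 0, out$n_A / tot, NA_real_)
  out$assayable <- out$n_snvs_retained >= 1L & round(tot) > 0
  out$p_binom <- NA_real_
  out$p_binom[out$assayable] <- binomial_dae_test(out$n_A[out$assayable],
                                                  out$n_B[out$assayable])
  out$q_bh <- bh_adjust(out$p_binom)
  attr(out, "params") <- list(min_reads = min_reads, fdr_alpha = fdr_alpha,
                              rounding = "half_to_even")
  attr(out, "filter_log") <- attr(kept, "filter_log")
  out
}
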