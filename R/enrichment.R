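#' Enrichment of DAE QTLs in an external candidate gene set
#'
#' Tests whether a candidate gene list (e.g. genes implicated by behavioural
#' QTL mapping) is enriched for DAE QTLs relative to all assayable genes.
#' Candidates not in the assayable universe are dropped (and counted): a
#' gene without sufficient transcribed variation or expression cannot show
#' DAE regardless of its regulation. The 2x2 table (candidate vs
#' non-candidate x DAE vs not) is tested with a one-sided Fisher's exact
#' test in the enrichment direction.
#'
#' @param dae_set character vector of DAE QTL gene ids.
#' @param candidate_set character vector of candidate gene ids.
#' @param assayable_set character vector: the assayable gene universe.
#' @return an object of class `dae_enrichment`: a list with `k` (DAE genes
#'   among assayable candidates), `n` (assayable candidates), `K` (DAE genes
#'   overall), `N` (assayable genes), `prop_candidates`, `prop_overall`,
#'   `odds_ratio` (sample odds ratio, `NA` when undefined), `p_value`,
#'   `expected_overlap` (`n*K/N`), and `n_candidates_dropped`.
#' @export
enrichment_test <- function(dae_set, candidate_set, assayable_set) {
  if (length(assayable_set) == 0L)
    stop("assayable gene universe is empty", call. = FALSE)
  dae_set <- intersect(unique(dae_set), assayable_set)
  candidate_set <- unique(candidate_set)
  dropped <- sum(!candidate_set %in% assayable_set)
  candidate_set <- intersect(candidate_set, assayable_set)

  N <- length(assayable_set)
  K <- length(dae_set)
  n <- length(candidate_set)
  k <- length(intersect(dae_set, candidate_set))

  tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2,
                dimnames = list(candidate = c("yes", "no"),
                                dae = c("yes", "no")))
  p <- enrichment_pvalue(k, n, K, N)
  or <- if ((n - k) == 0 || (K - k) == 0) NA_real_
        else (k * (N - n - K + k)) / ((n - k) * (K - k))
  if (!is.na(or) && k == 0 && K == 0) or <- NA_real_
  structure(list(k = k, n = n, K = K, N = N,
                 prop_candidates = if (n > 0) k / n else NA_real_,
                 prop_overall = K / N,
                 odds_ratio = or, p_value = p,
                 expected_overlap = expected_overlap(n, K, N),
                 table = tab,
                 n_candidates_dropped = dropped),
            class = "dae_enrichment")
}

#' @export
print.dae_enrichment <- function(x, ...) {
  cat("DAE QTL enrichment (one-sided Fisher's exact test)\n")
  cat(sprintf("  candidates: %s (%d/%d) DAE; overall: %s (%d/%d)\n",
              format_percent(x$prop_candidates), x$k, x$n,
              format_percent(x$prop_overall), x$K, x$N))
  cat(sprintf("  odds ratio %s, p = %.3g; expected random overlap %.1f genes\n",
              ifelse(is.na(x$odds_ratio), "NA",
                     sprintf("%.2f", x$odds_ratio)),
              x$p_value, x$expected_overlap))
  if (x$n_candidates_dropped > 0)
    cat(sprintf("  (%d candidate genes not assayable, dropped)\n",
                x$n_candidates_dropped))
  invisible(x)
}

#' One-sided enrichment p-value for a 2x2 table
#'
#' Probability, under the hypergeometric null of Fisher's exact test, of
#' observing `k` or more successes among `n` draws from a universe of `N`
#' genes containing `K` successes. Computed as an explicit upper-tail sum of
#' binomial-coefficient products in log space; equals
#' `fisher.test(..., alternative = "greater")` and is fast enough to apply
#' to large batches of tables.
#'
#' @param k,n,K,N table margins (vectors, recycled): overlap, draw size,
#'   success count, universe size.
#' @return numeric vector of one-sided p-values in `(0, 1]`.
#' @export
enrichment_pvalue <- function(k, n, K, N) {
  m <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, m); n <- rep_len(n, m)
  K <- rep_len(K, m); N <- rep_len(N, m)
  if (any(n > N | K > N | k > pmin(n, K) | k < pmax(0, K + n - N)))
    stop("inconsistent 2x2 table margins", call. = FALSE)
  vapply(seq_len(m), function(i) {
    j <- k[i]:min(n[i], K[i])
    p <- sum(exp(lchoose(K[i], j) + lchoose(N[i] - K[i], n[i] - j) -
                   lchoose(N[i], n[i])))
    min(1, p)
  }, numeric(1))
}

#' Format a proportion as a percentage to one decimal place
#'
#' @param p proportion in `[0, 1]`.
#' @param digits decimal places.
#' @return character, e.g. `"4.4%"`.
#' @export
format_percent <- function(p, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), 100 * p)
}

#' Expected overlap of two gene sets under independence
#'
#' The number of genes expected in the intersection of two sets drawn
#' independently from a common universe: `n_setA * n_setB / n_universe`.
#'
#' @param n_setA,n_setB set sizes.
#' @param n_universe universe size (> 0).
#' @return expected overlap (real, not an integer).
#' @export
expected_overlap <- function(n_setA, n_setB, n_universe) {
  if (n_universe <= 0) stop("universe must be non-empty", call. = FALSE)
  if (n_setA > n_universe || n_setB > n_universe)
    stop("set sizes cannot exceed the universe", call. = FALSE)
  n_setA * n_setB / n_universe
}

#' Cross-tabulate DAE QTLs against an eQTL database
#'
#' Reproduces the bookkeeping of a comparison between DAE QTLs found in one
#' F1 cross and cis-eQTLs mapped in recombinant inbred lines: how many
#' database cis-eQTL genes were observable in the F1 data, how many of those
#' were confirmed as DAE QTLs, how many were not, and how many DAE QTLs were
#' never listed as cis-eQTLs (candidate novel cis effects). The comparison
#' universe is the set of genes observed in both data sets.
#'
#' @param dae_genes character vector of DAE QTL gene ids.
#' @param universe genes observed in the F1 data and available for
#'   comparison.
#' @param eqtl_genes genes listed as eQTLs (cis or trans) in the database.
#' @param cis_eqtl_genes genes listed as cis-eQTLs (a subset of
#'   `eqtl_genes`).
#' @param n_total_genes optional total number of genes in the database.
#' @return an object of class `dae_eqtl_comparison`: a list of counts
#'   `n_total_genes`, `n_eqtl`, `n_cis_eqtl`, `n_cis_observed`,
#'   `n_confirmed`, `n_unconfirmed`, `n_dae`, `n_dae_in_eqtl`,
#'   `n_novel_dae`, plus the `expected_overlap` of the cis-eQTL and DAE sets
#'   within the universe. The identities `n_confirmed + n_unconfirmed ==
#'   n_cis_observed` and `n_novel_dae == n_dae - n_confirmed` (within the
#'   universe) are asserted.
#' @export
eqtl_box_counts <- function(dae_genes, universe, eqtl_genes, cis_eqtl_genes,
                            n_total_genes = NULL) {
  universe <- unique(universe)
  dae <- intersect(unique(dae_genes), universe)
  eqtl <- unique(eqtl_genes)
  cis <- unique(cis_eqtl_genes)
  cis_obs <- intersect(cis, universe)
  confirmed <- intersect(cis_obs, dae)
  novel <- setdiff(dae, cis)

  out <- list(n_total_genes = if (is.null(n_total_genes)) NA_integer_
              else as.integer(n_total_genes),
              n_eqtl = length(eqtl),
              n_cis_eqtl = length(cis),
              n_universe = length(universe),
              n_cis_observed = length(cis_obs),
              n_confirmed = length(confirmed),
              n_unconfirmed = length(cis_obs) - length(confirmed),
              n_dae = length(dae),
              n_dae_in_eqtl = length(intersect(dae, eqtl)),
              n_novel_dae = length(novel),
              expected_overlap = expected_overlap(length(cis_obs),
                                                  length(dae),
                                                  length(universe)))
  stopifnot(out$n_confirmed + out$n_unconfirmed == out$n_cis_observed,
            out$n_novel_dae == out$n_dae - out$n_confirmed)
  class(out) <- "dae_eqtl_comparison"
  out
}

#' @export
print.dae_eqtl_comparison <- function(x, ...) {
  cat("DAE QTL vs cis-eQTL comparison\n")
  cat(sprintf("  cis-eQTLs observed in F1 data: %d (of %d listed)\n",
              x$n_cis_observed, x$n_cis_eqtl))
  cat(sprintf("  confirmed as DAE QTLs: %d; not confirmed: %d (%s)\n",
              x$n_confirmed, x$n_unconfirmed,
              format_percent(ifelse(x$n_cis_observed > 0,
                                    x$n_unconfirmed / x$n_cis_observed, NA),
                             0)))
  cat(sprintf("  DAE QTLs not listed as cis-eQTLs: %d of %d\n",
              x$n_novel_dae, x$n_dae))
  cat(sprintf("  expected random overlap: %.1f genes\n", x$expected_overlap))
  invisible(x)
}
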