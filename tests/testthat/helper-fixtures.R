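# small constructors used across test files

# wide-format counts table for hand-built cases
make_counts <- function(snv_id, gene_id, A_refA, B_refA, A_refB, B_refB,
                        direction = "AxB", tissue = "tissue1") {
  data.frame(snv_id = snv_id, gene_id = gene_id,
             chrom = "1", pos = seq_along(snv_id),
             cross_direction = direction, tissue = tissue,
             count_A_refA = A_refA, count_B_refA = B_refA,
             count_A_refB = A_refB, count_B_refB = B_refB,
             stringsAsFactors = FALSE)
}

# a gene_allele_summary-shaped row set for hand-built calling cases
make_summary <- function(gene_id, frac_A, q, assayable = TRUE,
                         direction = "AxB", tissue = "tissue1",
                         depth = 100) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, cross_direction = direction,
             tissue = tissue,
             n_A = frac_A * depth, n_B = (1 - frac_A) * depth,
             n_snvs_retained = ifelse(rep_len(assayable, n), 1L, 0L),
             frac_A = frac_A,
             assayable = rep_len(assayable, n),
             p_binom = q, q_bh = q,
             stringsAsFactors = FALSE)
}

# brute-force two-sided binomial p: sum of point probabilities not
# exceeding that of the observed count (independent of binomial_dae_test)
oracle_binom_p <- function(x, n) {
  d <- vapply(0:n, function(j) choose(n, j) * 0.5^n, numeric(1))
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# textbook BH step-up: q_i = min_{j >= rank(i)} m * p_(j) / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric oracle via stats::dhyper (independent of the
# lchoose-based implementation)
oracle_hyper_p <- function(k, n, K, N) {
  sum(dhyper(k:min(n, K), K, N - K, n))
}
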