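test_that("enrichment proportions reproduce worked candidate-gene
           examples", {
  # forebrain: 4 of 91 assayable candidates vs 51 of 2669 assayable genes
  mk <- function(k, n, K, N) {
    universe <- sprintf("g%04d", seq_len(N))
    dae <- c(universe[seq_len(k)],
             if (K > k) universe[(n + 1):(n + K - k)])
    cand <- universe[seq_len(n)]
    enrichment_test(dae, cand, universe)
  }
  e <- mk(4, 91, 51, 2669)
  expect_equal(e$k, 4); expect_equal(e$n, 91)
  expect_equal(e$K, 51); expect_equal(e$N, 2669)
  expect_equal(format_percent(e$prop_candidates), "4.4%")
  expect_equal(format_percent(e$prop_overall), "1.9%")

  # kidney: 13 of 61 candidates vs 203 of 2236 genes
  e2 <- mk(13, 61, 203, 2236)
  expect_equal(format_percent(e2$prop_candidates), "21.3%")
  expect_equal(format_percent(e2$prop_overall), "9.1%")
  expect_gt(e2$odds_ratio, 1)

  # no signal at all: p = 1, odds ratio undefined
  e0 <- mk(0, 10, 0, 100)
  expect_equal(e0$p_value, 1)
  expect_true(is.na(e0$odds_ratio))
})

test_that("candidates outside the assayable universe are dropped and
           counted", {
  universe <- c("a", "b", "c", "d")
  e <- enrichment_test(dae_set = c("a", "b"),
                       candidate_set = c("a", "x", "y"),
                       assayable_set = universe)
  expect_equal(e$n, 1)
  expect_equal(e$k, 1)
  expect_equal(e$n_candidates_dropped, 2)
  expect_error(enrichment_test("a", "a", character(0)), "empty")
})

test_that("one-sided enrichment p matches fisher.test and the
           hypergeometric tail oracle", {
  # spot-check the packaged tail sum against stats::fisher.test
  set.seed(1)
  for (i in 1:200) {
    N <- sample(5:200, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(0:N, 1)
    rng <- max(0, K + n - N):min(n, K)
    k <- rng[sample.int(length(rng), 1)]
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2)
    expect_equal(enrichment_pvalue(k, n, K, N),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # exhaustive oracle agreement on small tables
  for (N in 2:25) for (n in 1:(N - 1)) for (K in 0:N) {
    k <- max(0, K + n - N):min(n, K)
    expect_equal(enrichment_pvalue(k, n, K, N),
                 vapply(k, oracle_hyper_p, numeric(1), n = n, K = K, N = N),
                 tolerance = 1e-10)
  }
  expect_error(enrichment_pvalue(5, 4, 10, 20), "margins")
})

test_that("expected random overlap is the independence formula and is
           symmetric", {
  expect_equal(expected_overlap(10, 10, 100), 1)
  expect_equal(expected_overlap(0, 50, 100), 0)
  expect_equal(expected_overlap(653, 51, 2669), 653 * 51 / 2669)
  expect_equal(round(expected_overlap(653, 51, 2669), 2), 12.48)
  expect_equal(expected_overlap(17, 41, 97), expected_overlap(41, 17, 97))
  expect_error(expected_overlap(5, 5, 0), "universe")
  expect_error(expected_overlap(50, 5, 20), "exceed")
})

test_that("eQTL cross-tabulation bookkeeping is internally consistent", {
  # 653 assayable cis-eQTLs of which 17 confirmed leaves 636 unconfirmed
  universe <- sprintf("u%04d", 1:2000)
  cis <- universe[1:653]
  dae <- c(universe[1:17], universe[700:727])  # 17 confirmed + 28 novel
  eqtl <- universe[1:1500]
  box <- eqtl_box_counts(dae, universe, eqtl, cis)
  expect_equal(box$n_cis_observed, 653)
  expect_equal(box$n_confirmed, 17)
  expect_equal(box$n_unconfirmed, 636)
  expect_equal(box$n_novel_dae, 28)
  expect_equal(box$n_confirmed + box$n_unconfirmed, box$n_cis_observed)

  # disjoint and identical set edge cases
  d2 <- eqtl_box_counts(c("a", "b"), c("a", "b", "c", "z"),
                        c("c"), c("c"))
  expect_equal(d2$n_confirmed, 0)
  expect_equal(d2$n_novel_dae, 2)
  d3 <- eqtl_box_counts(c("a"), c("a", "b"), c("a"), c("a"))
  expect_equal(d3$n_unconfirmed, 0)
})

test_that("set accounting identities hold on random gene universes", {
  set.seed(99)
  for (i in 1:50) {
    N <- sample(20:300, 1)
    universe <- sprintf("g%03d", seq_len(N))
    dae <- sample(universe, sample(0:N, 1))
    cis <- sample(universe, sample(0:N, 1))
    eqtl <- union(cis, sample(universe, sample(0:N, 1)))
    box <- eqtl_box_counts(dae, universe, eqtl, cis)
    expect_equal(box$n_confirmed + box$n_unconfirmed, box$n_cis_observed)
    expect_equal(box$n_novel_dae + box$n_confirmed, box$n_dae)
    expect_lte(box$n_confirmed, min(box$n_cis_observed, box$n_dae))
  }
})
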