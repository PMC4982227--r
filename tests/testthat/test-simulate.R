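test_that("truth generation respects configured class fractions and seed", {
  cfg <- dae_sim_config(n_genes = 100, frac_cis = 0.1, frac_imprinted = 0.05,
                        frac_x_linked = 0.02, seed = 1)
  gt <- simulate_truth(cfg)
  expect_equal(nrow(gt$truth), 100)
  expect_equal(sum(grepl("^cis", gt$truth$reg_class)), 10)
  expect_equal(sum(grepl("^imprinted", gt$truth$reg_class)), 5)
  expect_equal(sum(gt$truth$chromosome == "X"), 2)
  expect_true(all(table(gt$snvs$gene_id) >= 1))
  expect_true(all(gt$truth$gene_id %in% gt$snvs$gene_id))
  # fold change is 1 exactly for biallelic genes
  expect_true(all((gt$truth$fold_change == 1) ==
                    (gt$truth$reg_class == "biallelic")))

  none <- simulate_truth(dae_sim_config(n_genes = 50, frac_cis = 0, seed = 2))
  expect_false(any(grepl("^cis", none$truth$reg_class)))

  gt2 <- simulate_truth(cfg)
  expect_identical(gt, gt2)
})

test_that("invalid configurations are rejected", {
  expect_error(dae_sim_config(frac_cis = 1.2), "fractions")
  expect_error(dae_sim_config(frac_cis = 0.6, frac_imprinted = 0.5), "<= 1")
  expect_error(dae_sim_config(depth_mean = 0), "depth_mean")
  expect_error(dae_sim_config(mapping_bias_beta = 1), "mapping_bias_beta")
  expect_error(dae_sim_config(cis_fold_change_range = c(0.5, 2)), "fold")
  expect_error(dae_sim_config(imprint_silencing = 0.3), "imprint_silencing")
})

test_that("true maternal fraction follows cross direction, class and tissue", {
  tr <- data.frame(
    gene_id = c("g_bi", "g_cisA", "g_impM", "g_x", "g_t2", "g_flip"),
    chromosome = c("autosome", "autosome", "autosome", "X", "autosome",
                   "autosome"),
    reg_class = c("biallelic", "cis_strainA", "imprinted_maternal",
                  "biallelic", "cis_strainA", "cis_strainA"),
    fold_change = c(1, 4, Inf, 1, 4, 4),
    tissue_pattern = c("both", "both", "both", "both", "tissue2_only",
                       "flipped"),
    stringsAsFactors = FALSE)
  fwd <- true_maternal_fraction(tr, "AxB", "tissue1")
  rev <- true_maternal_fraction(tr, "BxA", "tissue1")
  # biallelic: balanced either way
  expect_equal(fwd[1], 0.5); expect_equal(rev[1], 0.5)
  # 4-fold cis effect favouring strain A: fraction 4/5 of strain-A reads,
  # so the maternal fraction flips between reciprocal crosses
  expect_equal(fwd[2], 0.8); expect_equal(rev[2], 0.2)
  # fully silenced maternally expressed gene: maternal-only both ways
  expect_equal(fwd[3], 1); expect_equal(rev[3], 1)
  # X-linked male: maternal-only regardless of class
  expect_equal(fwd[4], 1); expect_equal(rev[4], 1)
  # cis effect inactive in tissue1
  expect_equal(fwd[5], 0.5)
  expect_equal(true_maternal_fraction(tr, "AxB", "tissue2")[5], 0.8)
  # flipped effect swaps the favoured strain in tissue2
  expect_equal(fwd[6], 0.8)
  expect_equal(true_maternal_fraction(tr, "AxB", "tissue2")[6], 0.2)
})

test_that("mapping-bias loss inflates single-reference fractions and
           averaging cancels it", {
  # null genes at fraction 0.5, beta = 0.2: mapping against strain A's
  # reference keeps all A reads but only 80% of B reads, so the expected
  # single-mapping strain-A fraction is 0.5 / (0.5 + 0.5 * 0.8) = 5/9
  cfg <- dae_sim_config(n_genes = 800, frac_cis = 0, frac_imprinted = 0,
                        frac_x_linked = 0, depth_mean = 200,
                        mapping_bias_beta = 0.2, seed = 11)
  gt <- simulate_truth(cfg)
  cts <- simulate_counts(gt$truth, gt$snvs, "AxB", "tissue1", cfg)
  single <- sum(cts$count_A_refA) / sum(cts$count_A_refA + cts$count_B_refA)
  expect_equal(single, 5 / 9, tolerance = 0.02)
  expect_gt(single, 0.5)
  avg <- average_dual_mapping(cts)
  expect_equal(sum(avg$avg_A) / sum(avg$avg_A + avg$avg_B), 0.5,
               tolerance = 0.005)
})

test_that("unbiased simulation recovers the true fraction and X-linked
           males emit no paternal reads", {
  cfg <- dae_sim_config(n_genes = 400, frac_x_linked = 0.1,
                        mapping_bias_beta = 0, depth_mean = 150, seed = 3)
  gt <- simulate_truth(cfg)
  cts <- simulate_counts(gt$truth, gt$snvs, "AxB", "tissue1", cfg)
  # beta = 0: both mappings report identical totals
  expect_identical(cts$count_A_refA, cts$count_A_refB)
  expect_identical(cts$count_B_refA, cts$count_B_refB)
  bi <- cts$gene_id %in%
    gt$truth$gene_id[gt$truth$reg_class == "biallelic" &
                       gt$truth$chromosome != "X"]
  f <- sum(cts$count_A_refA[bi]) /
    sum(cts$count_A_refA[bi] + cts$count_B_refA[bi])
  expect_equal(f, 0.5, tolerance = 0.01)
  # male X: the paternal (strain B in AxB) allele is absent
  x <- cts$gene_id %in% gt$truth$gene_id[gt$truth$chromosome == "X"]
  expect_true(any(x))
  expect_equal(sum(cts$count_B_refA[x]) + sum(cts$count_B_refB[x]), 0)
})

test_that("full experiment simulation is seed-deterministic", {
  cfg <- dae_sim_config(n_genes = 60, seed = 9)
  s1 <- simulate_dae_experiment(cfg)
  s2 <- simulate_dae_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  combos <- unique(s1$counts[c("cross_direction", "tissue")])
  expect_equal(nrow(combos), 4L)
})
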