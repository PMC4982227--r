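test_that("reciprocal-cross calling separates strain effects from
           imprinting", {
  fwd <- make_summary(c("g_ssA", "g_impM", "g_bi", "g_inc", "g_na", "g_ssB"),
                      frac_A = c(0.8, 1.0, 0.52, 0.9, 0.7, 0.2),
                      q = c(0.001, 0.01, 0.5, 0.001, 0.02, 0.003),
                      assayable = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                      direction = "AxB")
  rev <- make_summary(c("g_ssA", "g_impM", "g_bi", "g_inc", "g_na", "g_ssB"),
                      frac_A = c(0.8, 0.0, 0.48, 0.5, 0.7, 0.3),
                      q = c(0.002, 0.01, 0.7, 0.9, 0.02, 0.04),
                      direction = "BxA")
  cl <- dae_call(fwd, rev, alpha = 0.05)
  got <- setNames(cl$calls$category, cl$calls$gene_id)
  expect_equal(got[["g_ssA"]], "strain_specific_A")
  expect_equal(got[["g_ssB"]], "strain_specific_B")
  expect_equal(got[["g_impM"]], "imprinted_maternal")
  expect_equal(got[["g_bi"]], "biallelic")
  expect_equal(got[["g_inc"]], "inconsistent")
  expect_equal(got[["g_na"]], "not_assayable")
  eff <- setNames(cl$calls$effect, cl$calls$gene_id)
  expect_equal(eff[["g_ssA"]], 0.8)
  expect_equal(eff[["g_impM"]], 1.0)  # mean maternal fraction
  # paternal imprinting: significant with maternal allele under-represented
  fwd2 <- make_summary("g_impP", 0.05, 0.01, direction = "AxB")
  rev2 <- make_summary("g_impP", 0.95, 0.01, direction = "BxA")
  expect_equal(dae_call(fwd2, rev2)$calls$category, "imprinted_paternal")
  # argument order of the two crosses does not matter
  expect_equal(dae_call(rev, fwd)$calls, cl$calls)
})

test_that("calls on simulated data recover the simulated classes", {
  cfg <- dae_sim_config(n_genes = 1500, depth_mean = 200,
                        mapping_bias_beta = 0.1,
                        tissue_effect_spec = c(both = 1), seed = 31)
  sim <- simulate_dae_experiment(cfg, tissues = "tissue1")
  sel <- function(d) sim$counts[sim$counts$cross_direction == d, ]
  cl <- dae_call(gene_allele_summary(sel("AxB"), sim$snvs),
                 gene_allele_summary(sel("BxA"), sim$snvs))
  m <- merge(sim$truth, cl$calls, by = "gene_id")
  m <- m[m$chromosome != "X", ]  # X-linked genes are a separate control

  cis <- grepl("^cis", m$reg_class)
  correct_cis <- (m$reg_class == "cis_strainA" &
                    m$category == "strain_specific_A") |
                 (m$reg_class == "cis_strainB" &
                    m$category == "strain_specific_B")
  expect_gte(mean(correct_cis[cis]), 0.90)

  imp <- grepl("^imprinted", m$reg_class)
  expect_gte(mean((m$reg_class == m$category)[imp]), 0.95)

  # cis and imprinted calls are essentially never confused
  cis_as_imp <- cis & grepl("^imprinted", m$category)
  imp_as_cis <- imp & grepl("^strain_specific", m$category)
  expect_lte(mean(cis_as_imp | imp_as_cis), 0.01)
})

test_that("swapping the cross labels preserves strain calls and swaps
           imprinting origin", {
  cfg <- dae_sim_config(n_genes = 600, depth_mean = 200,
                        tissue_effect_spec = c(both = 1), seed = 13)
  sim <- simulate_dae_experiment(cfg, tissues = "tissue1")
  fwd <- gene_allele_summary(sim$counts[sim$counts$cross_direction == "AxB", ],
                             sim$snvs)
  rev <- gene_allele_summary(sim$counts[sim$counts$cross_direction == "BxA", ],
                             sim$snvs)
  cl <- dae_call(fwd, rev)
  # relabel: pretend AxB was BxA and vice versa
  fwd2 <- fwd; fwd2$cross_direction <- "BxA"
  rev2 <- rev; rev2$cross_direction <- "AxB"
  cl2 <- dae_call(rev2, fwd2)
  swap <- c(strain_specific_A = "strain_specific_A",
            strain_specific_B = "strain_specific_B",
            imprinted_maternal = "imprinted_paternal",
            imprinted_paternal = "imprinted_maternal",
            biallelic = "biallelic", inconsistent = "inconsistent",
            not_assayable = "not_assayable")
  i <- match(cl$calls$gene_id, cl2$calls$gene_id)
  expect_equal(unname(swap[cl$calls$category]), cl2$calls$category[i])
})

test_that("significant genes overlap between single crosses more than
           chance when cis effects are present", {
  cfg <- dae_sim_config(n_genes = 1000, depth_mean = 200,
                        tissue_effect_spec = c(both = 1), seed = 17)
  sim <- simulate_dae_experiment(cfg, tissues = "tissue1")
  fwd <- gene_allele_summary(sim$counts[sim$counts$cross_direction == "AxB", ],
                             sim$snvs)
  rev <- gene_allele_summary(sim$counts[sim$counts$cross_direction == "BxA", ],
                             sim$snvs)
  sig_f <- fwd$gene_id[fwd$assayable & fwd$q_bh <= 0.05]
  sig_r <- rev$gene_id[rev$assayable & rev$q_bh <= 0.05]
  universe <- intersect(fwd$gene_id[fwd$assayable],
                        rev$gene_id[rev$assayable])
  observed <- length(intersect(sig_f, sig_r))
  expected <- expected_overlap(length(intersect(sig_f, universe)),
                               length(intersect(sig_r, universe)),
                               length(universe))
  expect_gt(observed, expected)
})

test_that("X-linked male genes are flagged when paternal reads appear", {
  calls <- data.frame(gene_id = c("gx1", "gx2", "ga", "gx3"),
                      category = c("imprinted_maternal", "biallelic",
                                   "biallelic", "not_assayable"),
                      frac_A_fwd = c(1, 0.6, 0.5, NA),
                      frac_A_rev = c(0, 0.4, 0.5, NA),
                      q_fwd = c(0.001, 0.5, 0.9, NA),
                      q_rev = c(0.001, 0.5, 0.9, NA),
                      effect = c(1, NA, NA, NA), stringsAsFactors = FALSE)
  obj <- structure(list(calls = calls, alpha = 0.05, tissue = "tissue1"),
                   class = "dae_call")
  gm <- data.frame(gene_id = c("gx1", "gx2", "ga", "gx3"),
                   chrom = c("X", "X", "1", "X"), stringsAsFactors = FALSE)
  rep <- check_x_linked(obj, gm, tol = 0.05)
  # autosomal and unassayable genes are not evaluated
  expect_setequal(rep$gene_id, c("gx1", "gx2"))
  expect_true(rep$pass[rep$gene_id == "gx1"])   # zero paternal reads
  expect_false(rep$pass[rep$gene_id == "gx2"])  # paternal fraction 0.4
})
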