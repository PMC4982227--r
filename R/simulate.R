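#' Simulation configuration for a reciprocal F1 allele-specific expression study
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' The generator emulates a reciprocal F1 hybrid design: pooled male F1
#' samples from two cross directions (strain A dam x strain B sire, and the
#' reciprocal), two tissues, genes carrying one to several transcribed SNVs,
#' strain-specific cis effects, imprinting with full or partial silencing of
#' one parental allele, X-linked maternal-only expression in males, and a
#' reference-mapping read-loss process that dual-reference averaging must
#' cancel.
#'
#' @param n_genes number of genes to simulate.
#' @param snvs_per_gene integer vector `c(min, max)`; the number of
#'   transcribed SNVs per gene is drawn uniformly from this range.
#' @param depth_mean expected total read depth per gene per sample.
#' @param depth_dispersion negative-binomial size parameter for per-gene
#'   depth; `Inf` gives Poisson depth.
#' @param frac_cis fraction of genes carrying a strain-specific cis effect.
#' @param cis_fold_change_range `c(low, high)` multiplicative allelic fold
#'   change for cis genes (both >= 1), drawn uniformly.
#' @param frac_imprinted fraction of genes imprinted (split evenly between
#'   maternally and paternally expressed).
#' @param imprint_silencing expressed-allele fraction for imprinted genes, in
#'   `[0.5, 1]`; 1 means full silencing of the repressed allele.
#' @param frac_x_linked fraction of genes placed on chromosome X.
#' @param mapping_bias_beta probability in `[0, 1)` that a read carrying the
#'   allele not matching a given reference genome is lost when mapped against
#'   that reference.
#' @param tissue_effect_spec named numeric vector of proportions over
#'   `c("both", "tissue1_only", "tissue2_only", "flipped")` describing how
#'   cis effects distribute across the two tissues. `flipped` means the
#'   favoured strain swaps between tissues.
#' @param epsilon per-read allele flip probability (sequencing error);
#'   0 by default since counts are restricted to validated SNVs.
#' @param seed integer RNG seed; all randomness in the generator flows from
#'   it.
#'
#' @return an object of class `dae_sim_config` (a validated list).
#' @seealso [simulate_dae_experiment()], [simulate_truth()]
#' @export
#' @examples
#' cfg <- dae_sim_config(n_genes = 100, seed = 1)
dae_sim_config <- function(n_genes = 2000,
                           snvs_per_gene = c(1L, 6L),
                           depth_mean = 200,
                           depth_dispersion = 10,
                           frac_cis = 0.10,
                           cis_fold_change_range = c(4, 4),
                           frac_imprinted = 0.05,
                           imprint_silencing = 1.0,
                           frac_x_linked = 0.02,
                           mapping_bias_beta = 0.1,
                           tissue_effect_spec = c(both = 0.25,
                                                  tissue1_only = 0.35,
                                                  tissue2_only = 0.35,
                                                  flipped = 0.05),
                           epsilon = 0,
                           seed = 1L) {
  stopifnot(length(n_genes) == 1L, n_genes >= 1)
  fracs <- c(frac_cis = frac_cis, frac_imprinted = frac_imprinted,
             frac_x_linked = frac_x_linked)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (frac_cis + frac_imprinted + frac_x_linked > 1)
    stop("frac_cis + frac_imprinted + frac_x_linked must be <= 1",
         call. = FALSE)
  if (length(snvs_per_gene) != 2L || any(snvs_per_gene < 1) ||
      snvs_per_gene[1] > snvs_per_gene[2])
    stop("snvs_per_gene must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  if (depth_mean <= 0) stop("depth_mean must be > 0", call. = FALSE)
  if (depth_dispersion <= 0)
    stop("depth_dispersion must be > 0 (Inf for Poisson)", call. = FALSE)
  if (any(cis_fold_change_range < 1) ||
      cis_fold_change_range[1] > cis_fold_change_range[2])
    stop("cis fold changes must be >= 1 with low <= high", call. = FALSE)
  if (imprint_silencing < 0.5 || imprint_silencing > 1)
    stop("imprint_silencing must lie in [0.5, 1]", call. = FALSE)
  if (mapping_bias_beta < 0 || mapping_bias_beta >= 1)
    stop("mapping_bias_beta must lie in [0, 1)", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5)
    stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  patterns <- c("both", "tissue1_only", "tissue2_only", "flipped")
  if (is.null(names(tissue_effect_spec)) ||
      !all(names(tissue_effect_spec) %in% patterns) ||
      any(tissue_effect_spec < 0) || sum(tissue_effect_spec) <= 0)
    stop("tissue_effect_spec must be non-negative proportions named among ",
         paste(patterns, collapse = ", "), call. = FALSE)
  spec <- setNames(numeric(4), patterns)
  spec[names(tissue_effect_spec)] <- tissue_effect_spec
  spec <- spec / sum(spec)
  structure(list(n_genes = as.integer(n_genes),
                 snvs_per_gene = as.integer(snvs_per_gene),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 frac_cis = frac_cis,
                 cis_fold_change_range = cis_fold_change_range,
                 frac_imprinted = frac_imprinted,
                 imprint_silencing = imprint_silencing,
                 frac_x_linked = frac_x_linked,
                 mapping_bias_beta = mapping_bias_beta,
                 tissue_effect_spec = spec,
                 epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "dae_sim_config")
}

#' @export
print.dae_sim_config <- function(x, ...) {
  cat("DAE simulation configuration\n")
  cat(sprintf("  genes: %d (cis %.1f%%, imprinted %.1f%%, X-linked %.1f%%)\n",
              x$n_genes, 100 * x$frac_cis, 100 * x$frac_imprinted,
              100 * x$frac_x_linked))
  cat(sprintf("  depth: NB(mean %.0f, size %s); SNVs/gene %d-%d\n",
              x$depth_mean, format(x$depth_dispersion),
              x$snvs_per_gene[1], x$snvs_per_gene[2]))
  cat(sprintf("  cis fold change: %.2g-%.2g; imprint silencing %.2f\n",
              x$cis_fold_change_range[1], x$cis_fold_change_range[2],
              x$imprint_silencing))
  cat(sprintf("  mapping-bias beta: %.3f; seed: %d\n",
              x$mapping_bias_beta, x$seed))
  invisible(x)
}

# deterministic integer split of n_genes into the regulatory classes
.class_counts <- function(config) {
  n <- config$n_genes
  n_x <- round(config$frac_x_linked * n)
  n_cis <- round(config$frac_cis * n)
  n_imp <- round(config$frac_imprinted * n)
  c(x = n_x, cis = n_cis, imprinted = n_imp,
    biallelic = n - n_x - n_cis - n_imp)
}

#' Simulate ground-truth regulatory classes and the SNV map
#'
#' Assigns each gene a chromosome, a regulatory class (biallelic,
#' cis-regulated favouring strain A or B, maternally or paternally
#' imprinted), an allelic fold change, and a tissue pattern, then places
#' validated transcribed SNVs inside each gene body. Class counts are
#' deterministic roundings of the configured fractions; X-linked genes are a
#' separate group with biallelic regulatory class (in males their effective
#' maternal fraction is 1 through hemizygosity, whatever the class).
#'
#' Imprinted genes carry `fold_change = s/(1 - s)` where `s` is the
#' expressed-allele fraction (`Inf` for full silencing), so that
#' `fold_change = 1` holds exactly for biallelic genes.
#'
#' @param config a [dae_sim_config()] object. Calling this function seeds the
#'   RNG from `config$seed`, so two calls with the same config are identical.
#' @return a list with components `truth` (data frame: `gene_id`,
#'   `chromosome`, `reg_class`, `fold_change`, `tissue_pattern`), `snvs`
#'   (data frame: `snv_id`, `gene_id`, `chrom`, `pos`, `allele_A`,
#'   `allele_B`, `validated`), and `gene_models` (data frame: `gene_id`,
#'   `chrom`, `start`, `end`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "dae_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  cc <- .class_counts(config)
  gene_id <- sprintf("gene%05d", seq_len(n))

  chromosome <- rep("autosome", n)
  reg_class <- rep("biallelic", n)
  fold_change <- rep(1, n)
  idx <- seq_len(n)
  x_idx <- idx[seq_len(cc["x"])]
  chromosome[x_idx] <- "X"
  cis_idx <- idx[cc["x"] + seq_len(cc["cis"])]
  # alternate favoured strain so both directions are represented
  reg_class[cis_idx] <- rep_len(c("cis_strainA", "cis_strainB"),
                                length(cis_idx))
  fold_change[cis_idx] <- runif(length(cis_idx),
                                config$cis_fold_change_range[1],
                                config$cis_fold_change_range[2])
  imp_idx <- idx[cc["x"] + cc["cis"] + seq_len(cc["imprinted"])]
  reg_class[imp_idx] <- rep_len(c("imprinted_maternal", "imprinted_paternal"),
                                length(imp_idx))
  s <- config$imprint_silencing
  fold_change[imp_idx] <- if (s >= 1) Inf else s / (1 - s)

  tissue_pattern <- rep("both", n)
  if (length(cis_idx))
    tissue_pattern[cis_idx] <- sample(names(config$tissue_effect_spec),
                                      length(cis_idx), replace = TRUE,
                                      prob = config$tissue_effect_spec)

  truth <- data.frame(gene_id = gene_id, chromosome = chromosome,
                      reg_class = reg_class, fold_change = fold_change,
                      tissue_pattern = tissue_pattern,
                      stringsAsFactors = FALSE)

  # lay genes along chromosomes; autosomes cycled 1..19
  chrom <- ifelse(chromosome == "X", "X",
                  as.character(1L + (seq_len(n) - 1L) %% 19L))
  rank_on_chrom <- ave(seq_len(n), chrom, FUN = seq_along)
  start <- 1L + (rank_on_chrom - 1L) * 10000L
  end <- start + 4999L
  gene_models <- data.frame(gene_id = gene_id, chrom = chrom,
                            start = start, end = end,
                            stringsAsFactors = FALSE)

  k <- sample(seq(config$snvs_per_gene[1], config$snvs_per_gene[2]),
              n, replace = TRUE)
  gidx <- rep(seq_len(n), k)
  pos <- start[gidx] + unlist(lapply(seq_len(n), function(i)
    sort(sample.int(5000L, k[i]))), use.names = FALSE) - 1L
  bases <- c("A", "C", "G", "T")
  allele_A <- sample(bases, length(gidx), replace = TRUE)
  allele_B <- vapply(allele_A,
                     function(a) sample(setdiff(bases, a), 1L), "")
  snvs <- data.frame(snv_id = sprintf("snv%06d", seq_along(gidx)),
                     gene_id = gene_id[gidx],
                     chrom = chrom[gidx],
                     pos = pos,
                     allele_A = allele_A,
                     allele_B = unname(allele_B),
                     validated = TRUE,
                     stringsAsFactors = FALSE)
  list(truth = truth, snvs = snvs, gene_models = gene_models)
}

#' True maternal-allele fraction for a gene under a given cross and tissue
#'
#' Computes, from the ground-truth record, the expected fraction of reads
#' derived from the maternally inherited allele in a male F1 of the given
#' cross direction. `"AxB"` denotes strain A dam x strain B sire (maternal
#' allele is the strain-A allele); `"BxA"` the reciprocal. For a cis effect
#' the strain-A fraction `fc/(1+fc)` is fixed, so the maternal fraction flips
#' between reciprocal crosses; for an imprinted gene the maternal fraction is
#' fixed in both directions. X-linked genes in males are maternal-only
#' (fraction 1) regardless of class. Tissue patterns apply to cis effects
#' only: an inactive tissue reverts to 0.5 and `flipped` swaps the favoured
#' strain in tissue 2.
#'
#' @param truth data frame from [simulate_truth()] (or a subset of its rows).
#' @param cross_direction `"AxB"` or `"BxA"`.
#' @param tissue `"tissue1"` or `"tissue2"`.
#' @param sex only `"male"` is supported (the study design pools male F1s).
#' @return numeric vector of maternal-allele fractions in `[0, 1]`, one per
#'   row of `truth`.
#' @export
true_maternal_fraction <- function(truth, cross_direction = c("AxB", "BxA"),
                                   tissue = c("tissue1", "tissue2"),
                                   sex = "male") {
  cross_direction <- match.arg(cross_direction)
  tissue <- match.arg(tissue)
  stopifnot(identical(sex, "male"))
  frac_A <- true_strainA_fraction(truth, tissue)
  # X-linked male: only the maternal allele is present
  m <- if (cross_direction == "AxB") frac_A else 1 - frac_A
  imp <- grepl("^imprinted", truth$reg_class)
  if (any(imp)) {
    s <- truth$fold_change[imp] / (1 + truth$fold_change[imp])
    s[is.infinite(truth$fold_change[imp])] <- 1
    m[imp] <- ifelse(truth$reg_class[imp] == "imprinted_maternal", s, 1 - s)
  }
  m[truth$chromosome == "X"] <- 1
  m
}

# expected strain-A allele fraction, identical across cross directions for
# cis effects; imprinted genes are handled in true_maternal_fraction()
true_strainA_fraction <- function(truth, tissue = "tissue1") {
  fc <- truth$fold_change
  f <- rep(0.5, nrow(truth))
  a <- truth$reg_class == "cis_strainA"
  b <- truth$reg_class == "cis_strainB"
  f[a] <- fc[a] / (1 + fc[a])
  f[b] <- 1 / (1 + fc[b])
  off <- (tissue == "tissue1" & truth$tissue_pattern == "tissue2_only") |
         (tissue == "tissue2" & truth$tissue_pattern == "tissue1_only")
  f[off & (a | b)] <- 0.5
  flip <- tissue == "tissue2" & truth$tissue_pattern == "flipped" & (a | b)
  f[flip] <- 1 - f[flip]
  f
}

#' Simulate a dual-reference allele-count table for one sample
#'
#' Generates per-SNV read counts for one pooled sample (one cross direction
#' in one tissue) under both reference mappings. Per gene, total depth is
#' negative-binomial; reads distribute multinomially over the gene's SNVs
#' with equal weights (all SNVs of a gene share its allele fraction); each
#' read's allele is Bernoulli with the gene's true strain-A fraction. The
#' mapping-bias loss then acts independently for the two mappings: when
#' mapped against strain S's reference, each read carrying the other strain's
#' allele is retained with probability `1 - mapping_bias_beta`.
#'
#' The RNG is not reseeded here; use [simulate_dae_experiment()] for a fully
#' seeded multi-sample simulation.
#'
#' @param truth,snvs components returned by [simulate_truth()].
#' @param cross_direction `"AxB"` (strain A dam) or `"BxA"`.
#' @param tissue `"tissue1"` or `"tissue2"`.
#' @param config the [dae_sim_config()] used for `simulate_truth`.
#' @return data frame with one row per SNV: `snv_id`, `gene_id`, `chrom`,
#'   `pos`, `cross_direction`, `tissue`, and integer counts
#'   `count_A_refA`, `count_B_refA` (mapping against strain A's reference)
#'   and `count_A_refB`, `count_B_refB` (against strain B's).
#' @export
simulate_counts <- function(truth, snvs, cross_direction, tissue, config) {
  stopifnot(inherits(config, "dae_sim_config"))
  cross_direction <- match.arg(cross_direction, c("AxB", "BxA"))
  tissue <- match.arg(tissue, c("tissue1", "tissue2"))
  n <- nrow(truth)
  if (!all(snvs$gene_id %in% truth$gene_id))
    stop("snvs reference genes absent from truth", call. = FALSE)
  snvs <- snvs[order(match(snvs$gene_id, truth$gene_id)), , drop = FALSE]
  m_frac <- true_maternal_fraction(truth, cross_direction, tissue)
  frac_A <- if (cross_direction == "AxB") m_frac else 1 - m_frac

  depth <- if (is.infinite(config$depth_dispersion))
    rpois(n, config$depth_mean)
  else
    rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)

  k <- tabulate(match(snvs$gene_id, truth$gene_id), nbins = n)
  per_snv <- unlist(lapply(seq_len(n), function(i) {
    if (k[i] == 0L) return(integer(0))
    if (k[i] == 1L) return(depth[i])
    drop(rmultinom(1L, depth[i], rep(1 / k[i], k[i])))
  }), use.names = FALSE)
  gidx <- rep(seq_len(n), k)

  p <- frac_A[gidx]
  if (config$epsilon > 0)
    p <- p * (1 - config$epsilon) + (1 - p) * config$epsilon
  nA <- rbinom(length(per_snv), per_snv, p)
  nB <- per_snv - nA
  beta <- config$mapping_bias_beta
  data.frame(snv_id = snvs$snv_id,
             gene_id = snvs$gene_id,
             chrom = snvs$chrom,
             pos = snvs$pos,
             cross_direction = cross_direction,
             tissue = tissue,
             count_A_refA = as.integer(nA),
             count_B_refA = as.integer(rbinom(length(nB), nB, 1 - beta)),
             count_A_refB = as.integer(rbinom(length(nA), nA, 1 - beta)),
             count_B_refB = as.integer(nB),
             stringsAsFactors = FALSE)
}

#' Simulate a complete reciprocal-cross, two-tissue experiment
#'
#' Runs [simulate_truth()] and then [simulate_counts()] for every
#' combination of cross direction and tissue, with all randomness derived
#' from `config$seed`; identical configurations yield identical tables.
#'
#' @param config a [dae_sim_config()] object.
#' @param directions cross directions to simulate.
#' @param tissues tissues to simulate.
#' @return an object of class `dae_simulation`: a list with `truth`, `snvs`,
#'   `gene_models`, `counts` (row-bound per-sample tables), and `config`.
#' @export
#' @examples
#' sim <- simulate_dae_experiment(dae_sim_config(n_genes = 50, seed = 7))
#' head(sim$counts)
simulate_dae_experiment <- function(config,
                                    directions = c("AxB", "BxA"),
                                    tissues = c("tissue1", "tissue2")) {
  stopifnot(inherits(config, "dae_sim_config"))
  gt <- simulate_truth(config)
  combos <- expand.grid(direction = directions, tissue = tissues,
                        stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    simulate_counts(gt$truth, gt$snvs, combos$direction[i],
                    combos$tissue[i], config)))
  rownames(counts) <- NULL
  structure(list(truth = gt$truth, snvs = gt$snvs,
                 gene_models = gt$gene_models, counts = counts,
                 config = config),
            class = "dae_simulation")
}

#' @export
print.dae_simulation <- function(x, ...) {
  cat("Simulated reciprocal-cross DAE experiment\n")
  cat(sprintf("  %d genes, %d SNVs, %d count rows (%s x %s)\n",
              nrow(x$truth), nrow(x$snvs), nrow(x$counts),
              paste(unique(x$counts$cross_direction), collapse = "/"),
              paste(unique(x$counts$tissue), collapse = "/")))
  print(table(class = x$truth$reg_class))
  invisible(x)
}
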