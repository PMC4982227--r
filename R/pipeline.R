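#' Run the full DAE QTL analysis pipeline
#'
#' End-to-end orchestration: obtain per-SNV dual-mapping counts (either by
#' simulation or from input files), compute gene-level summaries per cross
#' direction and tissue, call DAE QTLs per tissue from the reciprocal cross
#' pair, run the X-linked maternal-only check, compare tissues, and
#' optionally test enrichment against candidate gene lists. All stage
#' outputs and a metadata record (package version, parameters, seed) are
#' written to `out_dir`; identical configuration and seed give identical
#' output files.
#'
#' Exactly one of `sim_config` and `input` must be supplied.
#'
#' @param sim_config a [dae_sim_config()] for a simulated run.
#' @param input a list with paths `counts` (TSV, see [read_counts_tsv()]),
#'   `snv_vcf` (see [read_snv_vcf()]), and `gene_models` (see
#'   [read_gene_models()]) for a run on real data.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param alpha per-cross FDR threshold.
#' @param min_reads SNV read-depth threshold.
#' @param candidate_genes optional character vector (or path) of candidate
#'   genes for enrichment against tissue-1 DAE QTLs.
#' @param x_tol tolerated paternal-allele fraction for the X check.
#' @return a list (class `dae_pipeline_result`) with `summaries` (per
#'   direction x tissue), `calls` (per tissue), `x_check` (per tissue),
#'   `tissue_comparison`, `enrichment` (or `NULL`), and `metadata`.
#' @export
run_dae_pipeline <- function(sim_config = NULL, input = NULL,
                             out_dir = NULL, alpha = 0.05, min_reads = 8,
                             candidate_genes = NULL, x_tol = 0.05) {
  if (is.null(sim_config) == is.null(input))
    stop("supply exactly one of sim_config or input", call. = FALSE)

  if (!is.null(sim_config)) {
    stopifnot(inherits(sim_config, "dae_sim_config"))
    sim <- simulate_dae_experiment(sim_config)
    counts <- sim$counts
    snvs <- sim$snvs
    gene_models <- sim$gene_models
  } else {
    stopifnot(all(c("counts", "snv_vcf", "gene_models") %in% names(input)))
    counts <- read_counts_tsv(input$counts)
    snvs <- read_snv_vcf(input$snv_vcf)
    gene_models <- read_gene_models(input$gene_models)
    sim <- NULL
  }

  combos <- unique(counts[c("cross_direction", "tissue")])
  summaries <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- counts$cross_direction == combos$cross_direction[i] &
           counts$tissue == combos$tissue[i]
    gene_allele_summary(counts[sel, , drop = FALSE], snvs,
                        min_reads = min_reads, fdr_alpha = alpha)
  })
  names(summaries) <- paste(combos$cross_direction, combos$tissue, sep = ".")

  tissues <- unique(combos$tissue)
  calls <- lapply(tissues, function(t) {
    fwd <- summaries[[paste("AxB", t, sep = ".")]]
    rev <- summaries[[paste("BxA", t, sep = ".")]]
    if (is.null(fwd) || is.null(rev))
      stop("tissue ", t, " lacks one of the reciprocal crosses",
           call. = FALSE)
    dae_call(fwd, rev, alpha = alpha)
  })
  names(calls) <- tissues

  x_check <- lapply(calls, check_x_linked, gene_models = gene_models,
                    tol = x_tol)

  tissue_cmp <- if (length(tissues) == 2L)
    compare_tissues(calls[[1]], calls[[2]]) else NULL

  enr <- NULL
  if (!is.null(candidate_genes)) {
    if (is.character(candidate_genes) && length(candidate_genes) == 1L &&
        file.exists(candidate_genes))
      candidate_genes <- read_gene_list(candidate_genes)
    enr <- lapply(calls, function(cl)
      enrichment_test(dae_qtl_genes(cl), candidate_genes,
                      assayable_genes(cl)))
  }

  metadata <- list(package = "daeqtl",
                   version = as.character(utils::packageVersion("daeqtl")),
                   alpha = alpha, min_reads = min_reads, x_tol = x_tol,
                   rounding = "half_to_even",
                   fdr_stratification = "per cross direction x tissue",
                   seed = if (!is.null(sim_config)) sim_config$seed else NA,
                   simulated = !is.null(sim_config))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sim)) {
      write_snv_vcf(snvs, file.path(out_dir, "snvs.vcf"))
      write_results(sim$truth, file.path(out_dir, "truth.tsv"),
                    params = list(seed = sim_config$seed))
      write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
    }
    for (nm in names(summaries))
      write_results(summaries[[nm]],
                    file.path(out_dir, paste0("summary_", nm, ".tsv")),
                    params = list(min_reads = min_reads, fdr_alpha = alpha))
    for (t in tissues) {
      write_results(calls[[t]], file.path(out_dir,
                                          paste0("calls_", t, ".tsv")))
      write_results(x_check[[t]],
                    file.path(out_dir, paste0("x_check_", t, ".tsv")),
                    params = list(tol = x_tol))
    }
    if (!is.null(tissue_cmp))
      write_results(tissue_cmp$comparison,
                    file.path(out_dir, "tissue_comparison.tsv"))
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(summaries = summaries, calls = calls, x_check = x_check,
                 tissue_comparison = tissue_cmp, enrichment = enr,
                 truth = if (!is.null(sim)) sim$truth else NULL,
                 metadata = metadata),
            class = "dae_pipeline_result")
}

#' @export
print.dae_pipeline_result <- function(x, ...) {
  cat("DAE QTL pipeline run\n")
  cat(sprintf("  samples analysed: %s\n",
              paste(names(x$summaries), collapse = ", ")))
  for (t in names(x$calls)) {
    cat(sprintf("-- %s --\n", t))
    print(x$calls[[t]])
  }
  if (!is.null(x$tissue_comparison)) print(x$tissue_comparison)
  invisible(x)
}
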