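#' Call DAE QTLs from a reciprocal cross pair
#'
#' Combines the gene-level summaries of the two reciprocal crosses of one
#' strain pair (one tissue) into per-gene calls. A gene significant at the
#' FDR threshold in both crosses with the strain-A fraction on the same side
#' of 0.5 is a strain-specific DAE QTL (a cis effect: the favoured allele
#' follows the strain). A gene significant in both crosses with opposite
#' strain direction is imprinted: because the maternal strain swaps between
#' reciprocal crosses, opposite strain direction is the same parental-origin
#' direction. Genes significant in neither cross are biallelic; genes
#' significant in exactly one are reported as inconsistent and never counted
#' as DAE QTLs.
#'
#' @param summary_fwd [gene_allele_summary()] for the forward cross
#'   (`"AxB"`: strain A dam x strain B sire).
#' @param summary_rev summary for the reciprocal cross (`"BxA"`).
#' @param alpha FDR threshold applied to the per-cross Benjamini-Hochberg
#'   q-values.
#' @return an object of class `dae_call`: a list with `calls` (data frame:
#'   `gene_id`, `category`, `frac_A_fwd`, `frac_A_rev`, `q_fwd`, `q_rev`,
#'   `effect`), `alpha`, and `tissue`. `effect` is the mean strain-A
#'   fraction over the two crosses for strain-specific calls and the mean
#'   maternal-allele fraction for imprinted calls.
#' @seealso [summary.dae_call()], [check_x_linked()]
#' @export
dae_call <- function(summary_fwd, summary_rev, alpha = 0.05) {
  if (unique(summary_fwd$cross_direction) == "BxA" &&
      unique(summary_rev$cross_direction) == "AxB") {
    tmp <- summary_fwd; summary_fwd <- summary_rev; summary_rev <- tmp
  }
  if (!identical(unique(summary_fwd$tissue), unique(summary_rev$tissue)))
    stop("the two summaries must come from the same tissue", call. = FALSE)
  genes <- union(summary_fwd$gene_id, summary_rev$gene_id)
  f <- summary_fwd[match(genes, summary_fwd$gene_id), ]
  r <- summary_rev[match(genes, summary_rev$gene_id), ]
  ass <- !is.na(f$assayable) & f$assayable &
         !is.na(r$assayable) & r$assayable

  sig_f <- ass & f$q_bh <= alpha
  sig_r <- ass & r$q_bh <= alpha
  # at exact balance the binomial p is 1, so a significant gene always has
  # frac_A off 0.5
  stopifnot(!any(sig_f & f$frac_A == 0.5), !any(sig_r & r$frac_A == 0.5))

  category <- rep("not_assayable", length(genes))
  category[ass] <- "biallelic"
  category[xor(sig_f, sig_r)] <- "inconsistent"
  both <- sig_f & sig_r
  up_f <- f$frac_A > 0.5
  up_r <- r$frac_A > 0.5
  category[both & up_f & up_r] <- "strain_specific_A"
  category[both & !up_f & !up_r] <- "strain_specific_B"
  # forward maternal allele is strain A; reverse maternal allele is strain B
  category[both & up_f & !up_r] <- "imprinted_maternal"
  category[both & !up_f & up_r] <- "imprinted_paternal"

  mat_f <- f$frac_A
  mat_r <- 1 - r$frac_A
  effect <- rep(NA_real_, length(genes))
  ss <- grepl("^strain_specific", category)
  effect[ss] <- (f$frac_A[ss] + r$frac_A[ss]) / 2
  im <- grepl("^imprinted", category)
  effect[im] <- (mat_f[im] + mat_r[im]) / 2

  calls <- data.frame(gene_id = genes, category = category,
                      frac_A_fwd = f$frac_A, frac_A_rev = r$frac_A,
                      q_fwd = f$q_bh, q_rev = r$q_bh,
                      effect = effect, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(calls = calls, alpha = alpha,
                 tissue = unique(summary_fwd$tissue)),
            class = "dae_call")
}

#' @export
print.dae_call <- function(x, ...) {
  cat(sprintf("DAE QTL calls (%s, FDR alpha = %g)\n", x$tissue, x$alpha))
  tab <- table(factor(x$calls$category,
                      levels = c("strain_specific_A", "strain_specific_B",
                                 "imprinted_maternal", "imprinted_paternal",
                                 "biallelic", "inconsistent",
                                 "not_assayable")))
  print(tab)
  n_ass <- sum(x$calls$category != "not_assayable")
  n_dae <- sum(grepl("^strain_specific", x$calls$category))
  if (n_ass > 0)
    cat(sprintf("%d / %d assayable genes (%.1f%%) are strain-specific DAE QTLs\n",
                n_dae, n_ass, 100 * n_dae / n_ass))
  invisible(x)
}

#' @export
summary.dae_call <- function(object, ...) {
  calls <- object$calls
  ass <- calls$category != "not_assayable"
  out <- list(alpha = object$alpha, tissue = object$tissue,
              n_genes = nrow(calls), n_assayable = sum(ass),
              counts = table(calls$category[ass]),
              dae_genes = calls$gene_id[grepl("^strain_specific",
                                              calls$category)],
              imprinted_genes = calls$gene_id[grepl("^imprinted",
                                                    calls$category)])
  class(out) <- "summary.dae_call"
  out
}

#' @export
print.summary.dae_call <- function(x, ...) {
  cat(sprintf("DAE QTL call summary (%s): %d genes, %d assayable\n",
              x$tissue, x$n_genes, x$n_assayable))
  print(x$counts)
  invisible(x)
}

#' Genes called as strain-specific DAE QTLs
#'
#' @param x a `dae_call` object.
#' @param include_imprinted also return imprinted genes.
#' @return character vector of gene ids.
#' @export
dae_qtl_genes <- function(x, include_imprinted = FALSE) {
  stopifnot(inherits(x, "dae_call"))
  pat <- if (include_imprinted) "^(strain_specific|imprinted)"
         else "^strain_specific"
  x$calls$gene_id[grepl(pat, x$calls$category)]
}

#' Genes assayable in both reciprocal crosses
#'
#' @param x a `dae_call` object.
#' @return character vector of gene ids with both summaries assayable.
#' @export
assayable_genes <- function(x) {
  stopifnot(inherits(x, "dae_call"))
  x$calls$gene_id[x$calls$category != "not_assayable"]
}

#' Check maternal-only expression of X-linked genes in males
#'
#' In male F1s the single X chromosome is maternally inherited, so every
#' assayable X-linked transcript should show only the maternal allele in
#' both reciprocal crosses — an internal positive control for the whole
#' pipeline. Flags X-linked genes whose paternal-allele fraction exceeds a
#' tolerance in either cross. Autosomal genes are not evaluated.
#'
#' @param call a `dae_call` object.
#' @param gene_models data frame with `gene_id` and `chrom` (chromosome
#'   `"X"` marks X-linked genes).
#' @param tol maximum tolerated paternal-allele fraction.
#' @return data frame with one row per assayable X-linked gene: `gene_id`,
#'   `pat_frac_fwd`, `pat_frac_rev`, `pass`.
#' @export
check_x_linked <- function(call, gene_models, tol = 0.05) {
  stopifnot(inherits(call, "dae_call"))
  chrom <- gene_models$chrom[match(call$calls$gene_id, gene_models$gene_id)]
  keep <- !is.na(chrom) & chrom == "X" &
          call$calls$category != "not_assayable"
  calls <- call$calls[keep, , drop = FALSE]
  # forward cross: dam is strain A, so the paternal allele is B
  pat_fwd <- 1 - calls$frac_A_fwd
  pat_rev <- calls$frac_A_rev
  data.frame(gene_id = calls$gene_id,
             pat_frac_fwd = pat_fwd, pat_frac_rev = pat_rev,
             pass = pat_fwd <= tol & pat_rev <= tol,
             stringsAsFactors = FALSE, row.names = NULL)
}
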