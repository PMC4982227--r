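#' Genes assayable in both tissues and both reciprocal crosses
#'
#' Tissue comparison is restricted to the co-assayable set: genes with at
#' least one retained SNV (validated, depth threshold met) in both tissues
#' and both cross directions, so that apparent tissue specificity cannot
#' arise merely from a gene being measurable in one tissue only.
#'
#' @param call_t1,call_t2 `dae_call` objects for the two tissues of the same
#'   strain pair.
#' @return character vector of co-assayable gene ids.
#' @export
co_assayable_genes <- function(call_t1, call_t2) {
  stopifnot(inherits(call_t1, "dae_call"), inherits(call_t2, "dae_call"))
  if (identical(call_t1$tissue, call_t2$tissue))
    stop("the two call sets must come from different tissues", call. = FALSE)
  intersect(assayable_genes(call_t1), assayable_genes(call_t2))
}

#' Classify tissue specificity of strain-specific DAE
#'
#' For each co-assayable gene, compares its calls in the two tissues:
#' strain-specific in both with the same favoured strain
#' (`shared_same_direction`), strain-specific in exactly one tissue
#' (`tissue1_specific` / `tissue2_specific`), strain-specific in both with
#' opposite favoured strains (`direction_flip`, a cis effect whose direction
#' is controlled by tissue-specific trans factors), or strain-specific in
#' neither (`none`). Imprinted genes are excluded from these categories and
#' reported separately, since tissue specificity here concerns
#' strain-specific cis effects.
#'
#' @param call_t1,call_t2 `dae_call` objects for tissues 1 and 2 of the same
#'   strain pair.
#' @return an object of class `dae_tissue_comparison`: a list with
#'   `comparison` (data frame: `gene_id`, `category_t1`, `category_t2`,
#'   `category`), `counts` (category tally over the co-assayable set),
#'   `imprinted` (gene ids imprinted in either tissue, excluded from the
#'   tally), and `co_assayable` (the gene universe).
#' @export
compare_tissues <- function(call_t1, call_t2) {
  genes <- co_assayable_genes(call_t1, call_t2)
  c1 <- call_t1$calls$category[match(genes, call_t1$calls$gene_id)]
  c2 <- call_t2$calls$category[match(genes, call_t2$calls$gene_id)]
  imp <- grepl("^imprinted", c1) | grepl("^imprinted", c2)

  category <- mapply(classify_tissue_pattern, c1, c2, USE.NAMES = FALSE)
  category[imp] <- "imprinted"
  keep <- !imp
  counts <- table(factor(category[keep],
                         levels = c("shared_same_direction",
                                    "tissue1_specific", "tissue2_specific",
                                    "direction_flip", "none")))
  structure(list(comparison = data.frame(gene_id = genes,
                                         category_t1 = c1, category_t2 = c2,
                                         category = category,
                                         stringsAsFactors = FALSE),
                 counts = counts,
                 imprinted = genes[imp],
                 co_assayable = genes),
            class = "dae_tissue_comparison")
}

#' Tissue-pattern category for one gene's pair of calls
#'
#' @param call_t1,call_t2 category strings from a `dae_call` for the two
#'   tissues (e.g. `"strain_specific_A"`, `"biallelic"`).
#' @return one of `"shared_same_direction"`, `"tissue1_specific"`,
#'   `"tissue2_specific"`, `"direction_flip"`, `"none"`.
#' @export
classify_tissue_pattern <- function(call_t1, call_t2) {
  ss1 <- grepl("^strain_specific", call_t1)
  ss2 <- grepl("^strain_specific", call_t2)
  if (ss1 && ss2) {
    if (call_t1 == call_t2) "shared_same_direction" else "direction_flip"
  } else if (ss1) "tissue1_specific"
  else if (ss2) "tissue2_specific"
  else "none"
}

#' @export
print.dae_tissue_comparison <- function(x, ...) {
  cat(sprintf("Tissue comparison over %d co-assayable genes (%d imprinted, excluded)\n",
              length(x$co_assayable), length(x$imprinted)))
  print(x$counts)
  invisible(x)
}
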