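#' Write a strain-distinguishing SNV set as a minimal VCF
#'
#' One biallelic record per SNV: `REF` is the strain-A allele (the B6-like
#' role in this design), `ALT` the strain-B allele. Validation status is
#' carried in the `FILTER` column (`PASS` / `unvalidated`).
#'
#' @param snvs data frame with `snv_id`, `chrom`, `pos`, `allele_A`,
#'   `allele_B`, `validated`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  header <- c("##fileformat=VCFv4.2",
              "##FILTER=<ID=unvalidated,Description=\"Not confirmed by exome sequencing or the known-variant database\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t.",
                  snvs$chrom, snvs$pos, snvs$snv_id,
                  snvs$allele_A, snvs$allele_B,
                  ifelse(snvs$validated, "PASS", "unvalidated"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a strain-distinguishing SNV set from a minimal VCF
#'
#' Parses a VCF v4.2 file of biallelic SNVs. Multi-allelic records
#' (comma-separated `ALT`) are rejected: a strain-distinguishing SNV in an
#' F1 of two inbred strains has exactly two alleles.
#'
#' @param path VCF file path.
#' @return data frame with `snv_id`, `chrom`, `pos` (1-based), `allele_A`
#'   (REF), `allele_B` (ALT), `validated` (`FILTER` is `PASS` or missing).
#' @export
read_snv_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(data.frame(snv_id = character(0), chrom = character(0),
                      pos = integer(0), allele_A = character(0),
                      allele_B = character(0), validated = logical(0)))
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt)
  if (any(bad))
    stop("multi-allelic record(s) at row(s) ",
         paste(which(bad), collapse = ", "),
         ": one ALT allele per line is required", call. = FALSE)
  if (anyNA(alt) || anyNA(fix[, "REF"]))
    stop("malformed record(s) at row(s) ",
         paste(which(is.na(alt) | is.na(fix[, "REF"])), collapse = ", "),
         call. = FALSE)
  same <- fix[, "REF"] == alt
  if (any(same))
    stop("REF and ALT alleles identical at row(s) ",
         paste(which(same), collapse = ", "), call. = FALSE)
  filt <- fix[, "FILTER"]
  data.frame(snv_id = unname(fix[, "ID"]),
             chrom = unname(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             allele_A = unname(fix[, "REF"]),
             allele_B = unname(fix[, "ALT"]),
             validated = is.na(filt) | filt %in% c("PASS", "."),
             stringsAsFactors = FALSE)
}

.count_cols <- c("snv_id", "gene_id", "chrom", "pos", "cross_direction",
                 "tissue", "map_ref", "count_alleleA", "count_alleleB")

#' Write per-SNV dual-mapping counts as TSV
#'
#' Long format, two rows per SNV: one for the counts obtained from mapping
#' against each strain's reference (`map_ref` = `A` or `B`). Columns:
#' `snv_id`, `gene_id`, `chrom`, `pos`, `cross_direction`, `tissue`,
#' `map_ref`, `count_alleleA`, `count_alleleB`.
#'
#' @param counts wide-format counts (as from [simulate_counts()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  base <- counts[c("snv_id", "gene_id", "chrom", "pos", "cross_direction",
                   "tissue")]
  long <- rbind(cbind(base, map_ref = "A",
                      count_alleleA = counts$count_A_refA,
                      count_alleleB = counts$count_B_refA),
                cbind(base, map_ref = "B",
                      count_alleleA = counts$count_A_refB,
                      count_alleleB = counts$count_B_refB))
  long <- long[order(match(long$snv_id, counts$snv_id),
                     long$cross_direction, long$tissue, long$map_ref), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-SNV dual-mapping counts from TSV
#'
#' Reads the long format written by [write_counts_tsv()] and pivots it back
#' to one row per SNV with both mappings' counts. Counts must be
#' non-negative integers; both mappings must be present for every SNV;
#' unknown columns are ignored with a warning.
#'
#' @param path TSV path.
#' @return wide-format counts data frame (see [simulate_counts()]).
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(long), .count_cols)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    long <- long[.count_cols[.count_cols %in% names(long)]]
  }
  missing <- setdiff(.count_cols, names(long))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cnt <- c(long$count_alleleA, long$count_alleleB)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)

  key <- paste(long$snv_id, long$cross_direction, long$tissue, sep = "\r")
  a <- long[long$map_ref == "A", , drop = FALSE]
  b <- long[long$map_ref == "B", , drop = FALSE]
  ka <- key[long$map_ref == "A"]
  kb <- key[long$map_ref == "B"]
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicated (snv, sample, mapping) rows", call. = FALSE)
  if (length(ka) != length(kb) || !all(sort(ka) == sort(kb)))
    stop("both reference mappings are required for every SNV", call. = FALSE)
  i <- match(ka, kb)
  out <- data.frame(snv_id = a$snv_id, gene_id = a$gene_id,
                    chrom = as.character(a$chrom), pos = a$pos,
                    cross_direction = a$cross_direction, tissue = a$tissue,
                    count_A_refA = a$count_alleleA,
                    count_B_refA = a$count_alleleB,
                    count_A_refB = b$count_alleleA[i],
                    count_B_refB = b$count_alleleB[i],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a gene list (one symbol per line)
#'
#' Symbols are whitespace-stripped and compared case-sensitively; blank
#' lines and `#` comments are skipped; duplicates are removed with a
#' warning.
#'
#' @param path text file path.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) {
    warning(sum(duplicated(x)), " duplicate gene symbol(s) removed",
            call. = FALSE)
    x <- unique(x)
  }
  x
}

#' Read gene models from a BED-like TSV
#'
#' Tab-separated with header: `gene_id`, `chrom`, `start`, `end`
#' (coordinates 1-based inclusive).
#'
#' @param path TSV path.
#' @return data frame of gene models.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(gm)))
    stop("gene model file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  gm$chrom <- as.character(gm$chrom)
  if (any(gm$start > gm$end) || any(gm$start < 1))
    stop("gene models must satisfy 1 <= start <= end", call. = FALSE)
  if (anyDuplicated(gm$gene_id))
    stop("duplicated gene_id in gene models", call. = FALSE)
  gm
}

#' Assign SNVs to genes by position
#'
#' An SNV is assigned to the gene whose interval (1-based inclusive, same
#' chromosome) contains it. SNVs matching no gene are excluded with a
#' message; an SNV inside overlapping genes is an error (each SNV must map
#' to exactly one gene).
#'
#' @param snvs data frame with `snv_id`, `chrom`, `pos`.
#' @param gene_models data frame from [read_gene_models()].
#' @return `snvs` with a `gene_id` column, unassigned SNVs removed.
#' @export
assign_snvs_to_genes <- function(snvs, gene_models) {
  hits <- lapply(seq_len(nrow(snvs)), function(i) {
    which(gene_models$chrom == snvs$chrom[i] &
            gene_models$start <= snvs$pos[i] &
            gene_models$end >= snvs$pos[i])
  })
  n_hit <- lengths(hits)
  if (any(n_hit > 1))
    stop("SNV(s) inside more than one gene: ",
         paste(snvs$snv_id[n_hit > 1], collapse = ", "), call. = FALSE)
  if (any(n_hit == 0))
    message(sum(n_hit == 0),
            " SNV(s) outside all gene models, excluded")
  keep <- n_hit == 1
  out <- snvs[keep, , drop = FALSE]
  out$gene_id <- gene_models$gene_id[unlist(hits[keep])]
  rownames(out) <- NULL
  out
}

#' Write an analysis result table as TSV with a provenance header
#'
#' Writes `#key=value` comment lines recording the thresholds used,
#' followed by the tab-separated table.
#'
#' @param x a data frame, or a `dae_call` object (its `calls` table is
#'   written and `alpha` recorded).
#' @param path output path.
#' @param params named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, params = list()) {
  if (inherits(x, "dae_call")) {
    params <- c(list(fdr_alpha = x$alpha, tissue = x$tissue), params)
    x <- x$calls
  }
  hdr <- sprintf("#%s=%s", names(params),
                 vapply(params, function(v) paste(format(v), collapse = ","),
                        ""))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path TSV path.
#' @return data frame; header parameters in `attr(, "params")`.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  params <- list()
  if (length(hdr)) {
    kv <- strsplit(sub("^#", "", lines[hdr]), "=", fixed = TRUE)
    params <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  }
  out <- utils::read.delim(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                        collapse = "\n"),
                           stringsAsFactors = FALSE)
  attr(out, "params") <- params
  out
}
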