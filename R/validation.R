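#' gDNA-normalized allele fraction from Sanger peak areas
#'
#' Quantitative Sanger sequencing reports the two alleles of a heterozygote
#' as electropherogram peak areas, but dye chemistry and local sequence
#' context bias the two signals. Genomic DNA from the same animal is a
#' built-in 50/50 control, so dividing the cDNA allele odds by the gDNA
#' allele odds cancels the instrument bias: this ratio-of-ratios is the
#' unique correction that maps an unbiased heterozygous cDNA to a fraction
#' of exactly 0.5. The corrected allele-A fraction is `r/(1+r)` with
#' `r = (cdna_A/cdna_B)/(gdna_A/gdna_B)`. A silenced allele (`cdna_B = 0`)
#' gives fraction 1; `cdna_A = 0` gives 0.
#'
#' The fraction is invariant to rescaling the cDNA pair and the gDNA pair by
#' independent positive constants.
#'
#' @param cdna_A,cdna_B cDNA peak areas for alleles A and B (non-negative;
#'   not both zero).
#' @param gdna_A,gdna_B gDNA peak areas (strictly positive; the animal is
#'   heterozygous).
#' @return numeric vector of corrected allele-A fractions in `[0, 1]`.
#' @export
#' @examples
#' sanger_corrected_fraction(80, 20, 50, 50)  # 0.8, a 4-fold imbalance
sanger_corrected_fraction <- function(cdna_A, cdna_B, gdna_A, gdna_B) {
  k <- max(length(cdna_A), length(cdna_B), length(gdna_A), length(gdna_B))
  cdna_A <- rep_len(cdna_A, k); cdna_B <- rep_len(cdna_B, k)
  gdna_A <- rep_len(gdna_A, k); gdna_B <- rep_len(gdna_B, k)
  if (any(gdna_A <= 0 | gdna_B <= 0))
    stop("gDNA peak areas must be strictly positive", call. = FALSE)
  if (any(cdna_A < 0 | cdna_B < 0))
    stop("cDNA peak areas must be non-negative", call. = FALSE)
  if (any(cdna_A == 0 & cdna_B == 0))
    stop("cDNA peak areas are both zero: fraction undefined", call. = FALSE)
  r <- (cdna_A / cdna_B) / (gdna_A / gdna_B)
  out <- r / (1 + r)
  out[cdna_B == 0] <- 1
  out[cdna_A == 0] <- 0
  out
}

#' One-group t-test of allele fractions against a null fraction
#'
#' Tests whether per-animal corrected allele fractions differ from balanced
#' expression (0.5 by default). Sidedness is exposed because reporting
#' conventions vary; the default is two-sided and the choice is recorded in
#' the result.
#'
#' @param fractions numeric vector of allele fractions (>= 2 values with
#'   nonzero variance).
#' @param mu0 null fraction.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return a list with `t`, `p`, `df`, `mean`, `alternative`.
#' @export
one_group_ttest <- function(fractions, mu0 = 0.5,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(fractions) < 2L)
    stop("at least two observations are required", call. = FALSE)
  if (sd(fractions) == 0)
    stop("fractions have zero variance: t statistic undefined",
         call. = FALSE)
  ht <- t.test(fractions, mu = mu0, alternative = alternative)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = unname(ht$estimate),
       alternative = alternative)
}

#' Relative expression from qPCR delta-Ct, with a two-group test
#'
#' Computes per-animal relative expression `2^(-dCt)` with
#' `dCt = Ct(target) - Ct(reference)` (beta-actin role), re-normalizes every
#' value to the mean of the baseline strain (so that baseline = 1), and
#' compares the two strains with Welch's two-sample t-test on the relative
#' values (optionally on `-dCt`, i.e. the log2 scale). Measurements with a
#' missing reference Ct are dropped with a message.
#'
#' @param measurements data frame with columns `strain`, `mouse_id`,
#'   `ct_target`, `ct_reference`; exactly two strains, each with >= 2 mice.
#' @param baseline_strain strain whose mean expression defines 1.
#' @param log_scale if `TRUE`, the t-test is run on `-dCt` instead of the
#'   linear relative values.
#' @return a list with `per_mouse` (data frame: `strain`, `mouse_id`,
#'   `delta_ct`, `rel_expr`), `fold` (mean non-baseline / mean baseline
#'   relative expression), `t`, `p`, and `scale`.
#' @export
qpcr_relative_expression <- function(measurements, baseline_strain,
                                     log_scale = FALSE) {
  need <- c("strain", "mouse_id", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(measurements)))
  drop <- is.na(measurements$ct_reference) | is.na(measurements$ct_target)
  if (any(drop)) {
    message(sum(drop), " measurement(s) dropped for missing Ct values")
    measurements <- measurements[!drop, , drop = FALSE]
  }
  strains <- unique(measurements$strain)
  if (length(strains) != 2L || !baseline_strain %in% strains)
    stop("exactly two strains required, one of them the baseline",
         call. = FALSE)
  dct <- measurements$ct_target - measurements$ct_reference
  rel <- 2^(-dct)
  base <- measurements$strain == baseline_strain
  if (sum(base) < 2L || sum(!base) < 2L)
    stop("each strain needs at least two mice", call. = FALSE)
  rel <- rel / mean(rel[base])
  y <- if (log_scale) -dct else rel
  if (sd(y[base]) == 0 && sd(y[!base]) == 0) {
    # degenerate but well-defined: no within-strain variation
    d <- mean(y[!base]) - mean(y[base])
    ht <- list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
               p.value = if (d == 0) 1 else 0)
  } else ht <- t.test(y[!base], y[base])
  list(per_mouse = data.frame(strain = measurements$strain,
                              mouse_id = measurements$mouse_id,
                              delta_ct = dct, rel_expr = rel,
                              stringsAsFactors = FALSE),
       fold = mean(rel[!base]) / mean(rel[base]),
       t = unname(ht$statistic), p = ht$p.value,
       scale = if (log_scale) "log2" else "linear")
}

#' Correlation between allele fractions measured by two methods
#'
#' Pearson correlation between paired allele-fraction estimates (e.g.
#' RNA-Seq vs corrected Sanger fractions for the same genes), with a
#' two-sided test.
#'
#' @param frac_x,frac_y equal-length numeric vectors, `n >= 3`, neither
#'   constant.
#' @return a list with `r`, `p`, `n`.
#' @export
method_correlation <- function(frac_x, frac_y) {
  if (length(frac_x) != length(frac_y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(frac_x) < 3L)
    stop("at least three pairs are required", call. = FALSE)
  if (sd(frac_x) == 0 || sd(frac_y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ht <- cor.test(frac_x, frac_y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(frac_x))
}
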