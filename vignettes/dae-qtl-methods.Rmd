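---
title: "Detecting DAE QTLs in reciprocal F1 hybrids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DAE QTLs in reciprocal F1 hybrids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(daeqtl)
```

## The biological question

In an F1 hybrid between two inbred mouse strains (call them strain A and
strain B), every gene is present as one A allele and one B allele in the
same nucleus, exposed to the same trans-acting environment. If the two
alleles are expressed at different levels — *differential allele
expression* (DAE) — the cause must act in *cis* (promoter/enhancer
variants, allele-specific epigenetic marks) or be a parent-of-origin
(imprinting) effect. Comparing the two *reciprocal* crosses, A-mother x
B-father (AxB) and B-mother x A-father (BxA), separates those two causes:

* a **cis-regulatory variant** travels with the *strain* allele — the same
  allele (say A) is overexpressed in both crosses;
* an **imprinted** gene follows the *parent* — the maternal (or paternal)
  allele is overexpressed in both crosses, so the over-expressed *strain*
  allele flips between the reciprocal directions.

A gene significantly imbalanced in both directions with consistent strain
direction is a **DAE QTL** (cis effect); consistent parental direction is
called **imprinted**; significance in only one direction is reported as
`inconsistent` and never counted as a DAE QTL.

## Allele counting model

RNA-Seq reads overlapping transcribed heterozygous SNVs are assigned to an
allele by the base they carry. Three corrections matter:

1. **Reference mapping bias.** Aligning against a single reference genome
   loses a fraction $\beta$ of reads carrying the non-reference allele
   (each mismatch costs alignment score). With true 50/50 expression the
   reference-allele fraction inflates to
   $0.5 / (0.5 + 0.5(1-\beta))$ — about 0.556 at $\beta = 0.2$. The fix is
   to align against **both** parental pseudo-references and average the two
   counts per allele elementwise: the A allele is undercounted in the
   B-reference mapping by the same factor the B allele is undercounted in
   the A-reference mapping, so the average is unbiased
   (`average_dual_mapping()`).
2. **SNV filtering.** Only validated SNVs with an averaged total depth of
   at least 8 reads are retained (`filter_snvs()`; threshold applied after
   averaging, attrition recorded in a filter log).
3. **Gene aggregation.** Counts are summed over a gene's retained SNVs
   (`aggregate_genes()`); genes with no retained SNV are `not_assayable`.

## Statistical test

Per gene and per (cross direction x tissue) sample, the allele counts
$(n_A, n_B)$ are compared with an **exact two-sided binomial test** of
$p = 0.5$ using the minimum-likelihood rule: the p-value is the sum of
$\mathrm{dbinom}(d; n, 0.5)$ over all outcomes whose likelihood is at most
that of the observed count (with a $1 + 10^{-7}$ relative tolerance, the
same convention as `binom.test`). Averaged counts can be half-integers and
are rounded half-to-even first. P-values are adjusted by Benjamini—Hochberg
**within each (direction x tissue) stratum**, and genes with adjusted
$q \le 0.05$ are significant. Stratified adjustment keeps each sample's FDR
interpretable and makes single-tissue analyses identical whether or not a
second tissue was assayed.

`dae_call()` then applies the reciprocal-consistency logic above, yielding
categories `strain_specific_A/B`, `imprinted_maternal/paternal`,
`inconsistent`, `biallelic`, `not_assayable`. The X chromosome in males is
a built-in control: males carry a maternal X only, so X-linked genes must
be maternally mono-allelic (`check_x_linked()`, tolerance 0.05 on the
paternal fraction).

## Tissue comparison

For genes assayable in both tissues, `compare_tissues()` partitions the
co-assayable autosomal calls into `shared_same_direction`,
`tissue1_specific`, `tissue2_specific`, `direction_flip`, and `none`;
imprinted genes are excluded from this strain-direction partition and
reported separately. The five categories plus the imprinted set exactly
partition the co-assayable set — an asserted identity, not a convention.

## Enrichment and eQTL comparison

`enrichment_test()` asks whether DAE QTLs are over-represented in a
candidate set (e.g. genes with known regulatory polymorphisms), restricted
to the assayable universe, with a one-sided Fisher's exact p. The tail
probability is computed directly in log space,
$\sum_{j \ge k} \exp[\ln\binom{K}{j} + \ln\binom{N-K}{n-j} -
\ln\binom{N}{n}]$, which is algebraically the `fisher.test`
`alternative = "greater"` p-value but vectorizes to millions of tables per
second (the test suite verifies agreement with `fisher.test` and with a
brute-force `dhyper` tail). The expected chance overlap under independence
is $nK/N$. `eqtl_box_counts()` does the set bookkeeping against an external
cis-eQTL list (confirmed / unconfirmed / novel), with the accounting
identities asserted.

## Low-throughput validation statistics

* **Quantitative Sanger**: peak areas are instrument-biased; dividing the
  cDNA allele odds by the same animal's gDNA odds (a built-in 50/50
  control) cancels the bias. `sanger_corrected_fraction()` returns
  $r/(1+r)$ with $r = (c_A/c_B)/(g_A/g_B)$; the result is invariant to
  independent rescaling of the cDNA and gDNA pairs. Per-animal fractions
  are tested against 0.5 with a one-group t-test (`one_group_ttest()`;
  sidedness is a parameter because reporting conventions differ, default
  two-sided).
* **qPCR**: `qpcr_relative_expression()` computes per-animal
  $\Delta C_t = C_t(\text{target}) - C_t(\text{reference})$, relative
  expression $2^{-\Delta C_t}$ renormalized to the baseline strain's mean,
  a between-strain fold change, and a Welch t-test (linear or log2 scale).
* **Cross-method agreement**: `method_correlation()` (Pearson).

## The generative simulator

`dae_sim_config()` / `simulate_dae_experiment()` generate full experiments
with known truth, which is how every pipeline claim is checked end to end.
Per gene: total depth is negative binomial (mean `depth_mean = 200`, size
`depth_dispersion = 10`; `Inf` gives Poisson), spread over the gene's SNVs
(1–6, uniform) by a multinomial, and each read's allele is Bernoulli with
the gene's true allele fraction. Both single-reference mappings are then
derived by independently thinning non-reference reads with probability
`mapping_bias_beta` (default 0.1).

Defaults mirror the study design: 2000 genes on chromosomes 1–19 plus X,
10% cis-regulated at 4-fold (allele fraction 0.8/0.2), 5% imprinted with
complete silencing of one parental allele, 2% X-linked controls, and a
tissue-activity mix for cis genes of 25% active in both tissues, 35% in
each single tissue, and 5% flipping direction — so two-tissue analyses
exercise every comparison category. Class counts are rounded
deterministically so a given configuration always yields the same truth
table, and all randomness flows from a single `seed`.

```{r}
cfg <- dae_sim_config(n_genes = 500, seed = 42)
res <- run_dae_pipeline(sim_config = cfg)
res$calls$tissue1
```

## Problem sizes and verification

The test suite checks, among others: exact agreement of the binomial p with
a brute-force pmf-summation oracle (all counts with total $\le 30$), BH
against the textbook step-up (1000 random vectors), the enrichment p
against `fisher.test` and a `dhyper` oracle (exhaustively, all 2x2 tables
with $N \le 60$), mapping-bias inflation and its cancellation at 2000
genes, a null strain-specific call rate $\le 1\%$ at 5000 genes, $\ge 90\%$
cis power and $\ge 95\%$ imprinting accuracy with $\le 1\%$ cis/imprinting
confusion at 5000 genes, 100% maternal-only X-linked controls without
mapping loss, and $\ge 95\%$ tissue-pattern recovery at 3000 genes.
`scripts/acceptance.R` recomputes the headline quantities from scratch at a
user-supplied seed.

## Limitations

The simulator models gene-level DAE only (no isoform-specific effects), a
single F1 animal pool per direction x tissue (no between-animal
overdispersion — counts are binomial, not beta-binomial, given the truth),
complete rather than partial imprinting by default (`imprint_silencing` is
tunable), and males only on the X (no female X-inactivation mosaicism).
Mapping bias is a single genome-wide $\beta$ rather than locus-specific.
These are deliberate scope choices: each would add realism but none changes
the logic of reciprocal-consistency calling that the package exists to
implement.
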