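## Expression normalization (TMM-FPKM) and per-gene covariates: tissue
## means, mean expression and the tissue-specificity index tau.

#' TMM normalization factors
#'
#' Per-sample trimmed-mean-of-M-values factors (reference sample chosen by
#' upper quartile, 30% trim on M and 5% on A, factors with geometric mean 1),
#' computed with edgeR. All-zero samples get an `NA` factor with a warning.
#'
#' @param counts Gene x sample count matrix (>= 2 samples).
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    warning("all-zero sample(s) excluded from TMM: ",
            paste(colnames(counts)[zero], collapse = ", "))
  f <- rep(NA_real_, ncol(counts))
  names(f) <- colnames(counts)
  if (sum(!zero) >= 2)
    f[!zero] <- edgeR::calcNormFactors(counts[, !zero, drop = FALSE],
                                       method = "TMM")
  f
}

#' TMM-FPKM expression matrix
#'
#' Counts per million on TMM-adjusted library sizes, divided by the gene
#' effective length in kilobases. Effective lengths of zero are remapped to
#' 0.01.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Per-sample TMM factors (default computed from `counts`).
#' @param effective_lengths Per-gene effective length in bp (vector), or a
#'   gene x sample matrix.
#' @return Gene x sample TMM-FPKM matrix (columns with `NA` factors are
#'   `NA`).
#' @export
tmm_fpkm <- function(counts, factors = tmm_factors(counts),
                     effective_lengths) {
  counts <- as.matrix(counts)
  if (is.matrix(effective_lengths)) {
    len <- effective_lengths
  } else {
    len <- matrix(effective_lengths, nrow(counts), ncol(counts))
  }
  if (any(len < 0)) stop("effective lengths must be non-negative")
  len[len == 0] <- 0.01
  lib <- colSums(counts) * factors
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  cpm / (len / 1e3)
}

#' Per-tissue mean expression
#'
#' @param expr Gene x sample matrix (e.g. TMM-FPKM).
#' @param sample_tissue Named vector mapping sample column to tissue.
#' @return Gene x tissue matrix of means.
#' @export
tissue_means <- function(expr, sample_tissue) {
  expr <- as.matrix(expr)
  tiss <- sample_tissue[colnames(expr)]
  if (any(is.na(tiss))) stop("tissue missing for some samples")
  levels <- unique(tiss)
  out <- vapply(levels, function(tt)
    rowMeans(expr[, tiss == tt, drop = FALSE], na.rm = TRUE),
    numeric(nrow(expr)))
  colnames(out) <- levels
  out
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / x_max) / (N - 1)` over per-tissue mean expression
#' values; 0 means uniform expression across tissues and 1 single-tissue
#' expression. Genes whose tissue means are all zero are excluded (`NA`).
#'
#' @param per_tissue_means Gene x tissue matrix (or a vector for one gene)
#'   of mean expression values, non-negative.
#' @return Numeric vector of tau values in `[0, 1]` (`NA` for all-zero
#'   genes).
#' @export
tau <- function(per_tissue_means) {
  x <- if (is.matrix(per_tissue_means)) per_tissue_means else
    matrix(per_tissue_means, nrow = 1)
  if (ncol(x) < 2) stop("tau needs at least 2 tissues")
  if (any(x < 0, na.rm = TRUE)) stop("expression means must be non-negative")
  mx <- apply(x, 1, max)
  out <- rowSums(1 - x / mx) / (ncol(x) - 1)
  out[mx == 0] <- NA_real_
  out
}

#' Per-gene expression summary: tissue means, mean expression and tau
#'
#' @param counts Gene x sample count matrix.
#' @param effective_lengths Per-gene effective lengths (bp).
#' @param sample_tissue Named vector mapping sample to tissue.
#' @return `data.frame`: `gene_id`, one column per tissue, then
#'   `mean_expression` (arithmetic mean of tissue means) and `tau`.
#' @export
expression_summary <- function(counts, effective_lengths, sample_tissue) {
  fpkm <- tmm_fpkm(counts, effective_lengths = effective_lengths)
  ok <- !is.na(colSums(fpkm))
  tm <- tissue_means(fpkm[, ok, drop = FALSE], sample_tissue)
  data.frame(gene_id = rownames(counts), tm,
             mean_expression = rowMeans(tm),
             tau = tau(tm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-to-one ortholog filter
#'
#' Keeps gene pairs where each gene of either species appears exactly once
#' in the intersection table (and, if a class column is present, the
#' orthology class is one-to-one).
#'
#' @param intersection_table `data.frame` with columns `geneA`, `geneB` and
#'   optionally `class` (pairs whose class contains `"many"` are dropped).
#' @return The filtered table.
#' @export
ortholog_filter <- function(intersection_table) {
  tb <- intersection_table
  if ("class" %in% names(tb)) tb <- tb[!grepl("many", tb$class), , drop = FALSE]
  a_once <- names(which(table(tb$geneA) == 1))
  b_once <- names(which(table(tb$geneB) == 1))
  tb[tb$geneA %in% a_once & tb$geneB %in% b_once, , drop = FALSE]
}

#' PCA of samples for expression QC
#'
#' Removes low-expression genes (fewer than `min_count` reads in fewer than
#' `min_samples` samples), transforms to `log2(CPM + 1)` and projects the
#' samples on the first two principal components.
#'
#' @param counts Gene x sample count matrix (>= 3 samples).
#' @param min_count,min_samples Low-expression filter: keep genes with at
#'   least `min_count` reads in at least `min_samples` samples.
#' @return List: `scores` (samples x 2), `variance_explained` (all
#'   components), `n_genes_used`.
#' @export
expression_pca_qc <- function(counts, min_count = 4, min_samples = 3) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("PCA QC needs at least 3 samples")
  keep <- rowSums(counts >= min_count) >= min_samples
  if (sum(keep) < 2) stop("too few expressed genes for PCA")
  cpm <- sweep(counts[keep, , drop = FALSE], 2, colSums(counts), "/") * 1e6
  lg <- t(log2(cpm + 1))
  pc <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE], variance_explained = ve,
       n_genes_used = sum(keep))
}
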