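## Degeneracy-based pN/pS estimation: per-site fold degeneracy, synonymous
## and nonsynonymous site counts, the variant-filter cascade, coverage-based
## masking and the p(S+1)-adjusted ratio.

## per-codon lookup: for each sense codon, the number of synonymous
## single-nucleotide mutants at each of its three positions (0..3)
codon_syn_mutants <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    out <- matrix(0L, length(SENSE_CODONS), 3,
                  dimnames = list(SENSE_CODONS, NULL))
    for (cod in SENSE_CODONS) {
      aa <- GENETIC_CODE_AA[[cod]]
      for (p in 1:3) {
        n <- 0L
        for (b in setdiff(NUC, substr(cod, p, p))) {
          mut <- cod
          substr(mut, p, p) <- b
          if (GENETIC_CODE_AA[[mut]] == aa) n <- n + 1L
        }
        out[cod, p] <- n
      }
    }
    cache <<- out
    cache
  }
})

#' Classify per-position codon degeneracy of a coding sequence
#'
#' A coding position is x-fold degenerate if exactly x of the four possible
#' nucleotides at that position (including the reference) encode the same
#' amino acid (universal code); positions fall in the classes f0, f2, f3,
#' f4. Positions in codons containing ambiguous bases are skipped (`NA`).
#'
#' @param cds_sequence Coding sequence (character scalar, length divisible
#'   by 3, no internal stop codon).
#' @return List: `fold` (per-position labels 0/2/3/4, `NA` for skipped),
#'   `syn_mutants` (per-position count of synonymous single-nucleotide
#'   mutants, = fold count - 1), and `profile` with `f0`, `f2`, `f3`, `f4`,
#'   `S_sites`, `N_sites`.
#' @export
classify_degeneracy <- function(cds_sequence) {
  cds_sequence <- toupper(cds_sequence)
  len <- nchar(cds_sequence)
  if (len %% 3 != 0) stop("CDS length must be divisible by 3")
  starts <- seq(1, len, by = 3)
  codons <- substring(cds_sequence, starts, starts + 2)
  n_cod <- length(codons)
  if (any(codons[-n_cod] %in% STOP_CODONS) ||
      (n_cod > 0 && codons[n_cod] %in% STOP_CODONS && n_cod == 1))
    stop("CDS contains an internal stop codon")
  ## a single trailing stop codon is tolerated and excluded from counting
  has_term_stop <- codons[n_cod] %in% STOP_CODONS
  counted <- if (has_term_stop) codons[-n_cod] else codons
  idx <- codon_index(counted)
  if (any(is.na(idx) & counted %in% STOP_CODONS))
    stop("CDS contains an internal stop codon")
  sm <- matrix(NA_integer_, length(counted), 3)
  known <- !is.na(idx)
  if (any(!known))
    message(sum(!known), " codon(s) with ambiguous bases skipped")
  sm[known, ] <- codon_syn_mutants()[idx[known], , drop = FALSE]
  syn_mutants <- as.vector(t(sm))
  fold <- ifelse(is.na(syn_mutants), NA_integer_,
                 ifelse(syn_mutants == 0L, 0L, syn_mutants + 1L))
  if (has_term_stop) {
    syn_mutants <- c(syn_mutants, rep(NA_real_, 3))
    fold <- c(fold, rep(NA_integer_, 3))
  }
  f <- table(factor(fold, levels = c(0, 2, 3, 4)))
  profile <- degeneracy_profile(f[["0"]], f[["2"]], f[["3"]], f[["4"]])
  list(fold = fold, syn_mutants = syn_mutants, profile = profile)
}

#' Degeneracy profile and site counts
#'
#' Synonymous and nonsynonymous site counts from fold-degeneracy class
#' counts: `S = 0*f0 + f2/3 + 2*f3/3 + f4` and
#' `N = f0 + 2*f2/3 + f3/3 + 0*f4`.
#'
#' @param f0,f2,f3,f4 Counts of 0-/2-/3-/4-fold degenerate coding positions.
#' @return List with the class counts and `S_sites`, `N_sites`.
#' @export
degeneracy_profile <- function(f0, f2, f3, f4) {
  list(f0 = f0, f2 = f2, f3 = f3, f4 = f4,
       S_sites = f2 / 3 + 2 * f3 / 3 + f4,
       N_sites = f0 + 2 * f2 / 3 + f3 / 3)
}

#' Synonymous and nonsynonymous site counts from a profile
#'
#' @param profile A profile from [classify_degeneracy()] or
#'   [degeneracy_profile()].
#' @return Named numeric vector `c(S_sites, N_sites)`.
#' @export
count_sites <- function(profile) {
  if (!is.null(profile$profile)) profile <- profile$profile
  c(S_sites = profile$f2 / 3 + 2 * profile$f3 / 3 + profile$f4,
    N_sites = profile$f0 + 2 * profile$f2 / 3 + profile$f3 / 3)
}

#' Variant-quality filter cascade
#'
#' Retains biallelic SNPs with `QUAL > 30`, at least one supporting read on
#' each strand (`SAF > 0`, `SAR > 0`), at least two reads centered on each
#' side (`RPL > 1`, `RPR > 1`), heterozygote allele balance within
#' `[0.3, 0.7]`, Hardy-Weinberg excess-heterozygote p-value above 1e-4, and
#' fewer missing genotypes than the threshold.
#'
#' @param variants Variant table (see [simulate_variants()] for the layout);
#'   genotype columns are named `sample_*`. A `hwe_p` column is used if
#'   present, otherwise the excess-heterozygote p-value is computed from the
#'   genotypes.
#' @param thresholds Named list overriding any of `qual` (30), `ab_min`
#'   (0.3), `ab_max` (0.7), `hwe_p` (1e-4), `max_missing` (5).
#' @return The filtered variant table; attribute `removed` tabulates drop
#'   reasons.
#' @export
site_filters <- function(variants, thresholds = list()) {
  th <- utils::modifyList(
    list(qual = 30, ab_min = 0.3, ab_max = 0.7, hwe_p = 1e-4, max_missing = 5),
    thresholds)
  gt_cols <- grep("^sample_", names(variants), value = TRUE)
  gts <- as.matrix(variants[, gt_cols, drop = FALSE])

  single_nuc <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% NUC & variants$alt %in% NUC & !grepl(",", variants$alt)
  hwe <- if ("hwe_p" %in% names(variants)) variants$hwe_p else
    apply(gts, 1, function(g) {
      hwe_excess_het_p(sum(g == "0/0"), sum(g %in% c("0/1", "1/0")),
                       sum(g == "1/1"))
    })
  n_missing <- rowSums(gts == "./." | gts == ".")

  checks <- cbind(
    biallelic_snp = single_nuc,
    qual = variants$qual > th$qual,
    strand = variants$saf > 0 & variants$sar > 0,
    read_pos = variants$rpl > 1 & variants$rpr > 1,
    allele_balance = variants$ab >= th$ab_min & variants$ab <= th$ab_max,
    hwe = hwe > th$hwe_p,
    missing = n_missing < th$max_missing
  )
  checks[is.na(checks)] <- FALSE
  keep <- rowSums(checks) == ncol(checks)
  removed <- colSums(!checks[!keep, , drop = FALSE])
  out <- variants[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "n_chromosomes") <- attr(variants, "n_chromosomes")
  out
}

## One-sided exact Hardy-Weinberg test for heterozygote EXCESS
## (Levene's conditional distribution of heterozygote counts).
hwe_excess_het_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- (max(n_a, n_b) - h) / 2
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hets >= n_ab])
}

#' Excessive-coverage intervals
#'
#' Merges adjacent sites whose total coverage is at least twice the mean
#' total coverage into half-open, 0-based intervals.
#'
#' @param total_coverage Numeric vector of per-site total coverage (site i
#'   of the vector is 0-based position i - 1).
#' @return A `data.frame` with `start`, `end` (0-based half-open).
#' @export
excessive_coverage_intervals <- function(total_coverage) {
  if (length(total_coverage) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  if (any(total_coverage < 0)) stop("coverage must be non-negative")
  thr <- 2 * mean(total_coverage)
  high <- total_coverage >= thr
  if (!any(high)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Per-sample coverage mask
#'
#' For each sample, sites with depth below one third or above 1.5 times the
#' sample-specific median are masked; on X-linked scaffolds the thresholds
#' are halved for males (female thresholds unchanged). The returned mask is
#' the union over samples.
#'
#' @param depths Site x sample numeric matrix of depths.
#' @param scaffold Per-site scaffold ids (length `nrow(depths)`).
#' @param sex_labels Named vector (`"M"`/`"F"`) for the sample columns.
#' @param x_scaffolds Scaffold ids treated as X-linked.
#' @return Logical vector: `TRUE` where the site is masked.
#' @export
per_sample_coverage_mask <- function(depths, scaffold, sex_labels,
                                     x_scaffolds = character(0)) {
  depths <- as.matrix(depths)
  stopifnot(length(scaffold) == nrow(depths))
  sex <- sex_labels[colnames(depths)]
  if (any(is.na(sex))) stop("sex label missing for some samples")
  on_x <- scaffold %in% x_scaffolds
  masked <- rep(FALSE, nrow(depths))
  for (j in seq_len(ncol(depths))) {
    med <- stats::median(depths[, j])
    if (med == 0) {
      warning("sample ", colnames(depths)[j], " has zero median depth; fully masked")
      masked <- masked | TRUE
      next
    }
    lo <- rep(med / 3, nrow(depths))
    hi <- rep(1.5 * med, nrow(depths))
    if (sex[[j]] == "M") {
      lo[on_x] <- lo[on_x] / 2
      hi[on_x] <- hi[on_x] / 2
    }
    masked <- masked | depths[, j] < lo | depths[, j] > hi
  }
  masked
}

#' Assign scaffolds to autosomes or the X chromosome by coverage
#'
#' Depths are normalized per sample by the sample median over windows; a
#' scaffold is labeled X when the ratio of mean normalized female to male
#' depth over its windows falls in `[1.7, 2.5]` (a numeric stand-in for
#' manual inspection of the coverage ratio plots).
#'
#' @param coverage_track A coverage track from [simulate_coverage()] or a
#'   `data.frame` with `scaffold` plus per-sample depth columns.
#' @param sex_labels Named `"M"`/`"F"` vector; defaults to the track's `sex`
#'   attribute.
#' @param ratio_window Female:male normalized coverage ratio interval
#'   labeled X.
#' @return Named character vector scaffold -> `"autosome"`/`"X"`.
#' @export
assign_sex_linked_scaffolds <- function(coverage_track,
                                        sex_labels = attr(coverage_track, "sex"),
                                        ratio_window = c(1.7, 2.5)) {
  if (is.null(sex_labels)) stop("sex labels required")
  samples <- names(sex_labels)
  if (!all(samples %in% names(coverage_track)))
    stop("depth columns missing for some samples")
  if (!any(sex_labels == "M") || !any(sex_labels == "F"))
    stop("need at least one male and one female sample")
  depths <- as.matrix(coverage_track[, samples, drop = FALSE])
  norm <- sweep(depths, 2, apply(depths, 2, stats::median), "/")
  f_mean <- rowMeans(norm[, sex_labels == "F", drop = FALSE])
  m_mean <- rowMeans(norm[, sex_labels == "M", drop = FALSE])
  sc <- unique(coverage_track$scaffold)
  out <- vapply(sc, function(s) {
    i <- coverage_track$scaffold == s
    fm <- mean(f_mean[i])
    mm <- mean(m_mean[i])
    if (mm == 0) {
      warning("scaffold ", s, " has zero male coverage; labeled X")
      return("X")
    }
    r <- fm / mm
    if (r >= ratio_window[1] && r <= ratio_window[2]) "X" else "autosome"
  }, character(1))
  stats::setNames(out, sc)
}

#' Remove SNPs overlapping repeat intervals
#'
#' @param variants Variant table with 1-based `pos` and `scaffold`.
#' @param repeat_bed `data.frame` with `scaffold`, `start`, `end` (0-based
#'   half-open, BED convention).
#' @return Filtered variant table.
#' @export
subtract_repeats <- function(variants, repeat_bed) {
  if (nrow(repeat_bed) > 0 && any(repeat_bed$end < repeat_bed$start))
    stop("malformed repeat interval (end < start)")
  if (nrow(variants) == 0 || nrow(repeat_bed) == 0) return(variants)
  pos0 <- variants$pos - 1L
  drop <- vapply(seq_len(nrow(variants)), function(i) {
    any(repeat_bed$scaffold == variants$scaffold[i] &
          repeat_bed$start <= pos0[i] & pos0[i] < repeat_bed$end)
  }, logical(1))
  keep_attrs(variants[!drop, , drop = FALSE], variants)
}

#' Minor allele frequency filter
#'
#' Retains variants whose minor-allele frequency among non-missing alleles
#' is at least the threshold.
#'
#' @param variants Variant table with genotype columns `sample_*`.
#' @param maf_threshold Minimum minor allele frequency (default 0.0625).
#' @return Filtered variant table.
#' @export
maf_filter <- function(variants, maf_threshold = 0.0625) {
  if (maf_threshold <= 0 || nrow(variants) == 0) return(variants)
  gt_cols <- grep("^sample_", names(variants), value = TRUE)
  gts <- as.matrix(variants[, gt_cols, drop = FALSE])
  maf <- apply(gts, 1, function(g) {
    alleles <- unlist(strsplit(g[g != "./." & g != "."], "[/|]"))
    if (length(alleles) == 0) return(0)
    f <- mean(alleles == "1")
    min(f, 1 - f)
  })
  keep_attrs(variants[maf >= maf_threshold, , drop = FALSE], variants)
}

keep_attrs <- function(new, old) {
  attr(new, "n_chromosomes") <- attr(old, "n_chromosomes")
  new
}

#' Classify a SNP as synonymous or nonsynonymous
#'
#' Compares the amino acids encoded by the reference and alternate codon,
#' with the other codon positions at their reference state. Stop-gain and
#' stop-loss changes count as nonsynonymous. For minus-strand genes the
#' alleles are complemented.
#'
#' @param cds CDS sequence in coding orientation.
#' @param pos 1-based SNP position within the CDS (coding orientation).
#' @param ref,alt Alleles as reported (genome strand).
#' @param strand `"+"` or `"-"`; on `"-"` the alleles are complemented.
#' @return `"synonymous"`, `"nonsynonymous"`, or `NA` if the codon contains
#'   an ambiguous base.
#' @export
classify_snp <- function(cds, pos, ref, alt, strand = "+") {
  cds <- toupper(cds)
  if (pos < 1 || pos > nchar(cds)) stop("SNP position outside CDS")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (strand == "-") {
    ref <- comp[[toupper(ref)]]
    alt <- comp[[toupper(alt)]]
  }
  codon_i <- (pos - 1) %/% 3 + 1
  off <- (pos - 1) %% 3 + 1
  cod <- substr(cds, (codon_i - 1) * 3 + 1, codon_i * 3)
  if (substr(cod, off, off) != toupper(ref))
    stop("reference allele does not match CDS at position ", pos)
  if (!all(strsplit(cod, "")[[1]] %in% NUC)) {
    message("SNP at position ", pos, " in ambiguous codon; skipped")
    return(NA_character_)
  }
  mut <- cod
  substr(mut, off, off) <- toupper(alt)
  if (identical(translate_codons(cod), translate_codons(mut)))
    "synonymous" else "nonsynonymous"
}

#' pN/pS with the p(S+1) pseudo-count
#'
#' `pN = n_nonsyn / N_sites`, `pS_adj = (n_syn + 1) / S_sites` (the
#' pseudo-count is added to the synonymous variant count so the ratio is
#' defined when no synonymous polymorphism is observed), and
#' `pnps = pN / pS_adj`.
#'
#' @param n_syn,n_nonsyn Synonymous / nonsynonymous SNP counts.
#' @param S_sites,N_sites Synonymous / nonsynonymous site counts.
#' @param gene_id Optional identifier carried through.
#' @return A one-row `data.frame`: `gene_id`, `n_syn`, `n_nonsyn`,
#'   `S_sites`, `N_sites`, `pN`, `pS_adj`, `pnps`.
#' @export
compute_pnps <- function(n_syn, n_nonsyn, S_sites, N_sites, gene_id = NA) {
  if (any(c(n_syn, n_nonsyn) < 0)) stop("counts must be non-negative")
  bad <- S_sites <= 0 | N_sites <= 0
  pN <- ifelse(bad, NA_real_, n_nonsyn / N_sites)
  pS_adj <- ifelse(bad, NA_real_, (n_syn + 1) / S_sites)
  data.frame(gene_id = gene_id, n_syn = n_syn, n_nonsyn = n_nonsyn,
             S_sites = S_sites, N_sites = N_sites,
             pN = pN, pS_adj = pS_adj, pnps = pN / pS_adj,
             stringsAsFactors = FALSE)
}

#' Mean pN/pS across two species' orthologs
#'
#' @param pnps_species1,pnps_species2 Named numeric vectors (gene id ->
#'   pnps).
#' @param require_both If `TRUE` (default) genes missing in either species
#'   get `NA`; otherwise the available value is used.
#' @return Named numeric vector over the union of gene ids.
#' @export
mean_ortholog_pnps <- function(pnps_species1, pnps_species2,
                               require_both = TRUE) {
  ids <- union(names(pnps_species1), names(pnps_species2))
  a <- pnps_species1[ids]
  b <- pnps_species2[ids]
  out <- (a + b) / 2
  if (!require_both) {
    only_a <- is.na(b) & !is.na(a)
    only_b <- is.na(a) & !is.na(b)
    out[only_a] <- a[only_a]
    out[only_b] <- b[only_b]
  }
  stats::setNames(as.numeric(out), ids)
}

#' Restrict degeneracy sites and SNPs to aligned intervals
#'
#' Both the per-position degeneracy labels and the SNPs are restricted to
#' the given (0-based, half-open) CDS intervals before pN/pS is computed,
#' mirroring the removal of manually trimmed alignment regions.
#'
#' @param fold Per-position fold labels (from [classify_degeneracy()]).
#' @param snps Variant table with 1-based CDS positions in `pos`.
#' @param intervals `data.frame` with `start`, `end` (0-based half-open CDS
#'   coordinates).
#' @return List: `fold` (labels outside the intervals set to `NA`), `snps`
#'   (rows outside removed), `profile` recomputed on the retained positions.
#' @export
restrict_to_aligned_intervals <- function(fold, snps, intervals) {
  if (nrow(intervals) > 0 && any(intervals$end < intervals$start))
    stop("malformed interval")
  pos0 <- seq_along(fold) - 1L
  inside <- rep(FALSE, length(fold))
  for (i in seq_len(nrow(intervals)))
    inside <- inside | (pos0 >= intervals$start[i] & pos0 < intervals$end[i])
  if (!any(inside)) {
    message("no positions overlap the aligned intervals; gene dropped")
    return(NULL)
  }
  fold_new <- ifelse(inside, fold, NA_integer_)
  f <- table(factor(fold_new, levels = c(0, 2, 3, 4)))
  snp_keep <- snps[(snps$pos - 1L) %in% pos0[inside], , drop = FALSE]
  list(fold = fold_new,
       snps = keep_attrs(snp_keep, snps),
       profile = degeneracy_profile(f[["0"]], f[["2"]], f[["3"]], f[["4"]]))
}

#' Per-gene pN/pS from a CDS and a variant table
#'
#' Convenience wrapper running the filter cascade (quality filters, repeat
#' subtraction, MAF filter), classifying each surviving SNP against the CDS
#' and computing the p(S+1)-adjusted pN/pS.
#'
#' @param cds CDS sequence (coding orientation).
#' @param variants Variant table with `pos` in CDS coordinates.
#' @param gene_id Identifier for the output row.
#' @param maf_threshold Minor allele frequency threshold.
#' @param repeat_bed Optional repeat intervals (BED convention).
#' @param aligned_intervals Optional aligned intervals (0-based half-open).
#' @param apply_site_filters Run [site_filters()] first (default `TRUE`).
#' @return One-row `data.frame` as from [compute_pnps()].
#' @export
gene_pnps <- function(cds, variants, gene_id = NA, maf_threshold = 0,
                      repeat_bed = NULL, aligned_intervals = NULL,
                      apply_site_filters = TRUE) {
  deg <- classify_degeneracy(cds)
  v <- variants
  if (apply_site_filters) v <- site_filters(v)
  if (!is.null(repeat_bed)) v <- subtract_repeats(v, repeat_bed)
  v <- maf_filter(v, maf_threshold)
  fold <- deg$fold
  profile <- deg$profile
  if (!is.null(aligned_intervals)) {
    r <- restrict_to_aligned_intervals(fold, v, aligned_intervals)
    if (is.null(r)) return(NULL)
    v <- r$snps
    profile <- r$profile
  }
  cls <- if (nrow(v) > 0)
    mapply(classify_snp, pos = v$pos, ref = v$ref, alt = v$alt,
           MoreArgs = list(cds = cds)) else character(0)
  compute_pnps(sum(cls == "synonymous", na.rm = TRUE),
               sum(cls == "nonsynonymous", na.rm = TRUE),
               profile$S_sites, profile$N_sites, gene_id = gene_id)
}
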