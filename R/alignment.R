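#' Codon alignment
#'
#' In-memory representation of an aligned set of coding sequences for one
#' gene. Sequences are stored both as codon strings and as an integer matrix
#' of sense-codon indices; gap codons (`"---"`), `"NNN"` and any codon
#' containing an ambiguous base are treated as missing data (`NA`).
#'
#' @param sequences Named character vector of nucleotide sequences (equal
#'   length, divisible by 3), or a list of such.
#' @param taxon_names Optional taxon names (defaults to `names(sequences)`).
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `sequences`, `n_codons` and `codon_idx` (taxa x codons integer matrix).
#' @export
codon_alignment <- function(sequences, taxon_names = names(sequences)) {
  sequences <- toupper(unlist(sequences))
  if (is.null(taxon_names)) stop("sequences must be named or taxon_names given")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) stop("all sequences must have the same length")
  if (lens[1] %% 3 != 0) stop("alignment length must be divisible by 3")
  n_codons <- unname(lens[1] / 3)
  starts <- seq(1, lens[1], by = 3)
  codon_idx <- matrix(unlist(lapply(sequences, function(s)
    codon_index(substring(s, starts, starts + 2)))),
    nrow = length(sequences), byrow = TRUE)
  ## reject stop codons outright (gaps/ambiguity are NA and allowed)
  cods <- unlist(lapply(sequences, function(s) substring(s, starts, starts + 2)))
  bad <- cods %in% STOP_CODONS
  if (any(bad)) stop("alignment contains stop codon(s): ", paste(unique(cods[bad]), collapse = ", "))
  rownames(codon_idx) <- taxon_names
  structure(
    list(taxa = unname(taxon_names), sequences = unname(sequences),
         n_codons = n_codons, codon_idx = codon_idx),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa x", x$n_codons, "codons\n")
  invisible(x)
}

#' Read a codon alignment from a FASTA file
#'
#' @param path Path to a FASTA file of aligned coding sequences.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(ss), names(ss)))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(stats::setNames(aln$sequences, aln$taxa))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Alignment length QC filter
#'
#' Genes whose trimmed alignment is shorter than 80% of the original
#' alignment length are excluded from selection analyses (boundary
#' inclusive: exactly 80% is kept).
#'
#' @param trimmed_length Length of the trimmed alignment (columns).
#' @param original_length Length of the original alignment.
#' @param min_fraction Minimum retained fraction (default 0.8).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_alignment_length <- function(trimmed_length, original_length,
                                    min_fraction = 0.8) {
  if (any(original_length <= 0)) stop("original_length must be positive")
  if (any(trimmed_length > original_length))
    stop("trimmed alignment longer than original")
  trimmed_length >= min_fraction * original_length
}

#' Minimum taxa per clade QC filter
#'
#' Alignments contributing fewer than `min_per_clade` sequences from either
#' of the two clades (families) are excluded.
#'
#' @param aln A [codon_alignment()].
#' @param clade_map Named character vector mapping taxon name to clade label
#'   (exactly two clades).
#' @param min_per_clade Minimum sequences required from each clade (default 7).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_min_taxa <- function(aln, clade_map, min_per_clade = 7) {
  unknown <- setdiff(aln$taxa, names(clade_map))
  if (length(unknown) > 0)
    stop("taxa missing from clade_map: ", paste(unknown, collapse = ", "))
  clades <- clade_map[aln$taxa]
  counts <- table(factor(clades, levels = unique(clade_map)))
  if (length(counts) < 2) return(FALSE)
  all(counts >= min_per_clade)
}
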