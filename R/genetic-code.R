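## Universal genetic code tables shared by the codon-model, simulation and
## polymorphism modules.  Everything is computed once at load time from the
## code itself; no lookup data ships with the package.

NUC <- c("T", "C", "A", "G")

## Standard (universal) genetic code, indexed by codon string.
GENETIC_CODE_AA <- local({
  aa <- c(
    "F", "F", "L", "L", "S", "S", "S", "S", "Y", "Y", "*", "*", "C", "C", "*", "W",
    "L", "L", "L", "L", "P", "P", "P", "P", "H", "H", "Q", "Q", "R", "R", "R", "R",
    "I", "I", "I", "M", "T", "T", "T", "T", "N", "N", "K", "K", "S", "S", "R", "R",
    "V", "V", "V", "V", "A", "A", "A", "A", "D", "D", "E", "E", "G", "G", "G", "G"
  )
  ## canonical pos3-fastest ordering: TTT, TTC, TTA, TTG, TCT, ...
  codons <- apply(expand.grid(p3 = NUC, p2 = NUC, p1 = NUC)[, 3:1], 1, paste0, collapse = "")
  names(aa) <- codons
  aa
})

STOP_CODONS <- names(GENETIC_CODE_AA)[GENETIC_CODE_AA == "*"]
SENSE_CODONS <- names(GENETIC_CODE_AA)[GENETIC_CODE_AA != "*"]
SENSE_AA <- GENETIC_CODE_AA[SENSE_CODONS]

#' Translate codons to amino acids (universal code)
#'
#' @param codons Character vector of codon strings (case-insensitive).
#' @return Character vector of one-letter amino acids, `"*"` for stop codons
#'   and `NA` for codons containing non-ACGT characters.
#' @export
translate_codons <- function(codons) {
  unname(GENETIC_CODE_AA[chartr("U", "T", toupper(codons))])
}

## Pairwise structure over the 61 sense codons used by the rate-matrix
## builder: number of differing positions, transition indicator (only
## meaningful for single-nucleotide changes) and synonymy.
codon_pair_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n <- length(SENSE_CODONS)
    mat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
    ndiff <- matrix(0L, n, n)
    for (p in 1:3) ndiff <- ndiff + outer(mat[, p], mat[, p], "!=")
    ## transition = purine<->purine or pyrimidine<->pyrimidine at the single
    ## differing position
    is_purine <- function(x) x %in% c("A", "G")
    ts <- matrix(FALSE, n, n)
    for (p in 1:3) {
      d <- outer(mat[, p], mat[, p], "!=")
      same_class <- outer(is_purine(mat[, p]), is_purine(mat[, p]), "==")
      ts <- ts | (d & same_class & ndiff == 1)
    }
    syn <- outer(SENSE_AA, SENSE_AA, "==")
    cache <<- list(ndiff = ndiff, ts = ts, syn = syn)
    cache
  }
})

#' Index sense codons
#'
#' Maps codon strings to their index in the canonical 61-codon ordering used
#' throughout the package. Stop codons, gap codons (`"---"`) and codons with
#' ambiguous bases map to `NA` (treated as missing data).
#'
#' @param codons Character vector of codon strings.
#' @return Integer vector of indices into [sense_codons()].
#' @export
codon_index <- function(codons) {
  match(toupper(codons), SENSE_CODONS)
}

#' The 61 sense codons in canonical order
#' @return Character vector of length 61.
#' @export
sense_codons <- function() SENSE_CODONS
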