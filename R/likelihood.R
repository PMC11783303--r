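## Phylogenetic likelihood under the mixture codon model.  The heavy lifting
## (Felsenstein pruning with per-class eigendecompositions) lives in C++;
## this file prepares trees and site patterns and mixes class likelihoods.

## Match a tree to an alignment: prune tips without sequence data, check the
## bijection, and return the postorder edge matrix + branch lengths + the
## tip row order expected by the C++ kernel.
prepare_tree <- function(tree, aln) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (length(intersect(tree$tip.label, aln$taxa)) < 2)
    stop("alignment taxa missing from tree: ",
         paste(setdiff(aln$taxa, tree$tip.label), collapse = ", "))
  extra <- setdiff(tree$tip.label, aln$taxa)
  if (length(extra) > 0) tree <- ape::drop.tip(tree, extra)
  if (!setequal(tree$tip.label, aln$taxa))
    stop("alignment taxa missing from tree: ",
         paste(setdiff(aln$taxa, tree$tip.label), collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree,
       edges = tree$edge,
       blen = tree$edge.length,
       tip_order = match(tree$tip.label, aln$taxa))
}

## Collapse alignment columns into unique site patterns.
## Returns tipstate (n_tips x n_patterns, 0 = missing) and pattern weights.
site_patterns <- function(aln, tip_order) {
  idx <- aln$codon_idx[tip_order, , drop = FALSE]
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(tipstate = idx[, first, drop = FALSE], weights = w,
       pattern_of_site = match(key, key[first]))
}

## Per-pattern, per-class log-likelihoods for a prepared instance.
## scale multiplies all branch lengths (one global tree-scale factor).
class_pattern_loglik <- function(prep, patterns, model, scale = 1) {
  Qs <- class_rate_matrices(model)
  .pruning_loglik(prep$edges, prep$blen * scale, patterns$tipstate, Qs, model$pi)
}

## Mix per-pattern class log-likelihoods with joint weights (log-sum-exp).
mix_loglik <- function(ll, weights, pattern_weights) {
  lw <- log(weights)
  m <- apply(ll, 1, max)
  site_ll <- m + log(as.vector(exp(ll - m) %*% weights))
  sum(site_ll * pattern_weights)
}

#' Log-likelihood of a codon alignment under a mixture codon model
#'
#' Total log-likelihood computed by Felsenstein pruning, mixing over the
#' omega x synonymous-rate classes of the model. Gap codons, `NNN` and
#' partially ambiguous codons are treated as missing data. Columns with
#' fewer than one unambiguous state contribute the likelihood of pure
#' missing data (effectively zero information).
#'
#' @param aln A [codon_alignment()].
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   substitutions per codon; tips must cover the alignment taxa.
#' @param model A [mixture_codon_model()].
#' @param scale Global multiplier applied to all branch lengths.
#' @return Total log-likelihood (scalar).
#' @export
alignment_loglik <- function(aln, tree, model, scale = 1) {
  validate_codon_model(model)
  prep <- prepare_tree(tree, aln)
  pat <- site_patterns(aln, prep$tip_order)
  ll <- class_pattern_loglik(prep, pat, model, scale)
  mix_loglik(ll, class_weights(model), pat$weights)
}

#' Log-likelihood of a single alignment column
#'
#' Likelihood of one codon column under the full (omega x synonymous-rate)
#' mixture, `L = sum_k sum_m p_k q_m L(column | Q(omega_k, s_m))`, computed
#' by post-order pruning. Columns that are entirely gaps/ambiguous have no
#' data and return 0 (log of the all-missing likelihood).
#'
#' @param aln_column Named character vector: one codon per taxon.
#' @param tree `ape::phylo` tree covering the taxa.
#' @param model A [mixture_codon_model()].
#' @param scale Global branch-length multiplier.
#' @return Log-likelihood of the column.
#' @export
site_log_likelihood <- function(aln_column, tree, model, scale = 1) {
  aln <- codon_alignment(aln_column)
  idx <- aln$codon_idx
  if (sum(!is.na(idx)) < 1) return(0)
  alignment_loglik(aln, tree, model, scale)
}
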