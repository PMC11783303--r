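## Independent oracles used by the test suite.  These deliberately avoid the
## package's computational path: transition matrices come from Matrix::expm
## and likelihoods from an explicit sum over all internal-node state
## assignments.

## Brute-force mixture log-likelihood for small trees (<= 4 taxa).
brute_force_loglik <- function(aln, tree, model, scale = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  K <- length(model$omega)
  M <- length(model$syn_rate)
  w <- as.vector(t(outer(model$p_omega, model$q_syn)))
  idx <- aln$codon_idx[match(tree$tip.label, aln$taxa), , drop = FALSE]
  root <- tree$edge[nrow(tree$edge), 1]
  internal <- sort(setdiff(unique(as.vector(tree$edge)), seq_len(ntip)))
  G <- as.matrix(do.call(expand.grid, rep(list(1:61), length(internal))))
  colnames(G) <- internal
  total <- 0
  for (site in seq_len(ncol(idx))) {
    site_lik <- 0
    ci <- 0
    for (k in seq_len(K)) {
      for (m in seq_len(M)) {
        ci <- ci + 1
        Q <- build_rate_matrix(model, model$omega[k], model$syn_rate[m])
        Ps <- lapply(tree$edge.length, function(t)
          as.matrix(Matrix::expm(Q * t * scale)))
        pr <- model$pi[G[, as.character(root)]]
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]
          chl <- tree$edge[e, 2]
          sp <- G[, as.character(par)]
          if (chl <= ntip) {
            sc <- idx[chl, site]
            if (!is.na(sc)) pr <- pr * Ps[[e]][cbind(sp, sc)]
          } else {
            pr <- pr * Ps[[e]][cbind(sp, G[, as.character(chl)])]
          }
        }
        site_lik <- site_lik + w[ci] * sum(pr)
      }
    }
    total <- total + log(site_lik)
  }
  total
}

## Brute-force count of synonymous single-nucleotide mutants of a CDS.
brute_force_syn_mutants <- function(cds) {
  cds <- toupper(cds)
  nucs <- c("T", "C", "A", "G")
  n <- 0L
  aa_of <- function(s) immusel::translate_codons(
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
  ref_aa <- aa_of(cds)
  for (pos in seq_len(nchar(cds))) {
    for (b in setdiff(nucs, substr(cds, pos, pos))) {
      mut <- cds
      substr(mut, pos, pos) <- b
      cod_i <- (pos - 1) %/% 3 + 1
      if (identical(aa_of(mut)[cod_i], ref_aa[cod_i])) n <- n + 1L
    }
  }
  n
}

## Random sense-codon CDS.
random_test_cds <- function(n_codons) {
  paste(sample(immusel::sense_codons(), n_codons, replace = TRUE),
        collapse = "")
}
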