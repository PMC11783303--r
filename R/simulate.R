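## Synthetic-data generators.  Every input the pipeline consumes can be
## produced here with the statistical structure the analysis assumes:
## codon alignments evolved under mixture models on two-clade trees, SNP
## tables with a target pN/pS, expression matrices with a target tau, and
## coverage tracks with sex-linked scaffolds.

#' Simulate a two-clade gene tree
#'
#' A pure-birth tree is grown within each clade and the two clades are
#' joined by a stem; branch lengths are in expected substitutions per codon.
#' The clade subtrees take 80% of the requested root-to-tip depth and each
#' stem the remaining 20%.
#'
#' @param n_taxa_per_clade Number of tips per clade (>= 2).
#' @param depth Expected substitutions per codon from root to tip (> 0).
#' @param seed Integer seed (the same seed reproduces the tree exactly).
#' @param clade_names Tip-label prefixes for the two clades.
#' @return An `ape::phylo` tree with `2 * n_taxa_per_clade` tips; tip labels
#'   are `<clade>_<nn>` so the clade of each tip is recoverable.
#' @export
simulate_tree <- function(n_taxa_per_clade, depth, seed = 1,
                          clade_names = c("cladeA", "cladeB")) {
  if (n_taxa_per_clade < 2) stop("n_taxa_per_clade must be >= 2")
  if (depth <= 0) stop("depth must be positive")
  withr::with_seed(seed, {
    clade_depth <- 0.8 * depth
    stem <- 0.2 * depth
    subtree <- function(prefix) {
      t <- ape::rphylo(n_taxa_per_clade, birth = 1, death = 0)
      ## rescale to the requested clade depth (rphylo trees are ultrametric)
      h <- max(ape::node.depth.edgelength(t))
      t$edge.length <- t$edge.length * clade_depth / h
      t$tip.label <- sprintf("%s_%02d", prefix, seq_len(n_taxa_per_clade))
      t
    }
    t1 <- subtree(clade_names[1])
    t2 <- subtree(clade_names[2])
    nwk <- function(t) sub(";\\s*$", "", ape::write.tree(t))
    tree <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                          nwk(t1), stem, nwk(t2), stem))
    tree
  })
}

#' Clade membership from simulated tip labels
#'
#' @param tree A tree from [simulate_tree()].
#' @return Named character vector mapping tip label to clade prefix.
#' @export
clade_map_from_tree <- function(tree) {
  stats::setNames(sub("_[0-9]+$", "", tree$tip.label), tree$tip.label)
}

## eigendecomposition of a reversible generator; returns A, Ainv, lambda so
## that P(t) = A %*% (exp(lambda * t) * Ainv)
reversible_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(A = e$vectors / sq, Ainv = t(e$vectors) * rep(sq, each = 61),
       lambda = e$values)
}

transition_matrix <- function(eg, t) {
  P <- eg$A %*% (exp(eg$lambda * t) * eg$Ainv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a codon alignment under a mixture codon model
#'
#' Each site draws an (omega, synonymous-rate) class from the mixture
#' weights, the root codon is drawn from the model frequencies, and
#' evolution proceeds along each branch with exact transition matrices
#' `expm(Q t)`. Simulated alignments contain neither stop codons nor gaps.
#'
#' @param tree `ape::phylo` tree with branch lengths in expected
#'   substitutions per codon.
#' @param model A [mixture_codon_model()].
#' @param n_codons Number of codon sites (>= 1).
#' @param seed Integer seed.
#' @return A list: `alignment` (a [codon_alignment()]), `site_class`
#'   (data frame with the true omega and synonymous-rate class per site).
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, seed = 1) {
  validate_codon_model(model)
  if (n_codons < 1) stop("n_codons must be >= 1")
  withr::with_seed(seed, {
    K <- length(model$omega)
    M <- length(model$syn_rate)
    w <- class_weights(model)
    cls <- sample.int(K * M, n_codons, replace = TRUE, prob = w)
    Qs <- class_rate_matrices(model)
    eigs <- lapply(seq_len(K * M), function(i) reversible_eigen(Qs[, , i], model$pi))

    tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nnode, n_codons)
    root <- ntip + 1L
    states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = model$pi)

    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      child <- integer(n_codons)
      for (ci in unique(cls)) {
        sites <- which(cls == ci)
        if (t_e == 0) { child[sites] <- states[par, sites]; next }
        P <- transition_matrix(eigs[[ci]], t_e)
        for (s in unique(states[par, sites])) {
          at <- sites[states[par, sites] == s]
          child[at] <- sample.int(61, length(at), replace = TRUE, prob = P[s, ])
        }
      }
      states[chl, ] <- child
    }

    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(s)
      paste(SENSE_CODONS[s], collapse = ""))
    aln <- codon_alignment(stats::setNames(seqs, tree$tip.label))
    k_of <- (cls - 1) %/% M + 1
    m_of <- (cls - 1) %% M + 1
    list(alignment = aln,
         site_class = data.frame(site = seq_len(n_codons),
                                 omega_class = k_of, omega = model$omega[k_of],
                                 syn_class = m_of, syn_rate = model$syn_rate[m_of]))
  })
}

#' Simulate within-species variants on a coding sequence
#'
#' A parametric stand-in for population-genetic variation: synonymous SNPs
#' are placed uniformly on the synonymous mutational opportunity of the CDS
#' and nonsynonymous SNPs on the nonsynonymous opportunity, with expected
#' counts `theta * S_sites` and `theta * target_pnps * N_sites` so that the
#' expected pN/pS (before the pseudo-count) equals the target. Minor allele
#' counts follow the neutral 1/i spectrum and genotypes are drawn by
#' permuting allele copies across chromosomes.
#'
#' @param cds_sequence Coding sequence (character scalar, length divisible
#'   by 3, no internal stop).
#' @param target_pnps Target pN/pS (>= 0).
#' @param n_diploids Number of diploid samples carrying genotypes.
#' @param theta Expected synonymous SNPs per synonymous site.
#' @param seed Integer seed.
#' @param scaffold Scaffold name written into the table.
#' @return A `data.frame` with columns `scaffold`, `pos` (1-based position
#'   in the CDS), `ref`, `alt`, `qual`, `saf`, `sar`, `rpl`, `rpr`, `ab`,
#'   `type` (truth: `syn`/`nonsyn`) and genotype columns `sample_1 ...`;
#'   attribute `n_chromosomes`.
#' @export
simulate_variants <- function(cds_sequence, target_pnps, n_diploids = 31,
                              theta = 0.01, seed = 1, scaffold = "chr1") {
  if (target_pnps < 0) stop("target_pnps must be >= 0")
  deg <- classify_degeneracy(cds_sequence)
  withr::with_seed(seed, {
    sm <- deg$syn_mutants
    sm[is.na(sm)] <- 0 # skipped positions carry no opportunity
    syn_opp <- sm / 3 # per-position synonymous opportunity
    nonsyn_opp <- ifelse(is.na(deg$syn_mutants), 0, (3 - sm) / 3)
    S <- deg$profile$S_sites
    N <- deg$profile$N_sites
    n_syn <- stats::rpois(1, theta * S)
    n_non <- stats::rpois(1, theta * target_pnps * N)

    nuc_at <- strsplit(toupper(cds_sequence), "")[[1]]
    pick_positions <- function(n, opp) {
      ok <- which(opp > 0)
      if (n == 0 || length(ok) == 0) return(integer(0))
      sample(ok, min(n, length(ok)), prob = opp[ok])
    }
    pos_syn <- pick_positions(n_syn, syn_opp)
    pos_non <- pick_positions(n_non, nonsyn_opp * !(seq_along(nonsyn_opp) %in% pos_syn))
    all_pos <- c(pos_syn, pos_non)
    types <- rep(c("syn", "nonsyn"), c(length(pos_syn), length(pos_non)))

    alt_for <- function(pos, want_syn) {
      codon_i <- (pos - 1) %/% 3 + 1
      off <- (pos - 1) %% 3 + 1
      cod <- paste(nuc_at[(codon_i - 1) * 3 + 1:3], collapse = "")
      aa <- translate_codons(cod)
      cands <- setdiff(NUC, nuc_at[pos])
      muts <- vapply(cands, function(b) {
        cc <- cod; substr(cc, off, off) <- b
        translate_codons(cc)
      }, character(1))
      keep <- if (want_syn) cands[muts == aa] else cands[muts != aa]
      if (length(keep) == 0) NA_character_ else sample(keep, 1)
    }
    alts <- mapply(alt_for, all_pos, types == "syn")
    ok <- !is.na(alts)
    all_pos <- all_pos[ok]; types <- types[ok]; alts <- alts[ok]

    nchrom <- 2L * n_diploids
    gt_rows <- lapply(seq_along(all_pos), function(i) {
      ## minor allele count from the neutral spectrum, folded to < 50%
      kmax <- max(1L, floor(nchrom / 2))
      k <- sample.int(kmax, 1, prob = 1 / seq_len(kmax))
      carriers <- sample.int(nchrom, k)
      copies <- tabulate((carriers - 1L) %/% 2L + 1L, nbins = n_diploids)
      c("0/0", "0/1", "1/1")[copies + 1L]
    })
    gts <- do.call(rbind, gt_rows)
    if (is.null(gts)) gts <- matrix(character(0), 0, n_diploids)
    colnames(gts) <- sprintf("sample_%d", seq_len(n_diploids))

    out <- data.frame(
      scaffold = rep(scaffold, length(all_pos)),
      pos = all_pos,
      ref = nuc_at[all_pos],
      alt = alts,
      qual = rep(60, length(all_pos)),
      saf = rep(4L, length(all_pos)), sar = rep(4L, length(all_pos)),
      rpl = rep(4L, length(all_pos)), rpr = rep(4L, length(all_pos)),
      ab = rep(0.5, length(all_pos)),
      type = types,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(gts, stringsAsFactors = FALSE))
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_chromosomes") <- nchrom
    out
  })
}

#' Write a variant table as VCF v4.2
#'
#' @param variants A variant table from [simulate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  gt_cols <- grep("^sample_", names(variants), value = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads on forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads on reverse strand\">",
    "##INFO=<ID=RPL,Number=1,Type=Integer,Description=\"Reads placed left\">",
    "##INFO=<ID=RPR,Number=1,Type=Integer,Description=\"Reads placed right\">",
    "##INFO=<ID=AB,Number=1,Type=Float,Description=\"Allele balance in hets\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt_cols), collapse = "\t")
  )
  info <- sprintf("SAF=%d;SAR=%d;RPL=%d;RPR=%d;AB=%g",
                  variants$saf, variants$sar, variants$rpl, variants$rpr,
                  variants$ab)
  body <- cbind(variants$scaffold, variants$pos, ".", variants$ref,
                variants$alt, variants$qual, "PASS", info, "GT",
                as.matrix(variants[, gt_cols, drop = FALSE]))
  lines <- c(header, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an expression count matrix with target tissue specificity
#'
#' Per-gene tissue-mean profiles are constructed so that the
#' tissue-specificity index tau computed on noiseless means equals the
#' target exactly (one maximal tissue, all others at `1 - tau`);
#' negative-binomial counts are drawn around means scaled by library size
#' and effective length.
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues (>= 2).
#' @param tau_target Vector (recycled) of per-gene tau targets in `[0, 1]`.
#' @param library_sizes Vector of per-sample library sizes; its length sets
#'   the number of samples, assigned to tissues round-robin.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); default 0.1.
#' @param mean_log_expression,sd_log_expression Log-normal parameters of the
#'   per-gene baseline expression level (FPKM scale).
#' @return List: `counts` (genes x samples), `effective_length` (per gene),
#'   `sample_tissue` (named vector), `true_tau`, `true_means`
#'   (genes x tissues, FPKM scale).
#' @export
simulate_expression <- function(n_genes, n_tissues = 10, tau_target = 0.5,
                                library_sizes = rep(2e6, 2 * n_tissues),
                                seed = 1, dispersion = 0.1,
                                mean_log_expression = log(30),
                                sd_log_expression = 1) {
  if (n_tissues < 2) stop("n_tissues must be >= 2")
  tau_target <- rep_len(tau_target, n_genes)
  if (any(tau_target < 0 | tau_target > 1)) stop("tau targets must be in [0, 1]")
  withr::with_seed(seed, {
    n_samples <- length(library_sizes)
    tissue_of <- rep_len(sprintf("tissue_%02d", seq_len(n_tissues)), n_samples)
    sample_names <- sprintf("s%02d_%s", seq_len(n_samples), tissue_of)

    level <- exp(stats::rnorm(n_genes, mean_log_expression, sd_log_expression))
    max_tissue <- sample.int(n_tissues, n_genes, replace = TRUE)
    prof <- matrix(rep(1 - tau_target, n_tissues), n_genes, n_tissues)
    prof[cbind(seq_len(n_genes), max_tissue)] <- 1
    true_means <- prof * level # FPKM-scale tissue means

    eff_len <- pmax(200, round(exp(stats::rnorm(n_genes, log(1500), 0.4))))
    mu <- true_means[, match(tissue_of, sprintf("tissue_%02d", seq_len(n_tissues)))]
    mu <- mu * (eff_len / 1e3) * rep(library_sizes / 1e6, each = n_genes)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      n_genes, n_samples,
      dimnames = list(sprintf("gene_%05d", seq_len(n_genes)), sample_names))
    colnames(true_means) <- sprintf("tissue_%02d", seq_len(n_tissues))
    rownames(true_means) <- rownames(counts)
    list(counts = counts,
         effective_length = stats::setNames(eff_len, rownames(counts)),
         sample_tissue = stats::setNames(tissue_of, sample_names),
         true_tau = stats::setNames(tau_target, rownames(counts)),
         true_means = true_means)
  })
}

#' Simulate a windowed coverage track with sex-linked scaffolds
#'
#' Per-sample read depths in 1-kb windows; scaffolds listed as X-linked get
#' half depth in males. A configurable fraction of windows receives a
#' coverage spike (for testing excessive-coverage filters).
#'
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param x_scaffold_ids Scaffolds simulated as X-linked.
#' @param n_males,n_females Number of samples of each sex (total >= 1).
#' @param mean_depth Mean autosomal per-sample depth.
#' @param seed Integer seed.
#' @param spike_rate Fraction of windows with a 4x coverage spike.
#' @param window Window size in bp (default 1000).
#' @return A `data.frame`: `scaffold`, `start`, `end` (0-based half-open)
#'   and one depth column per sample; attribute `sex` (named vector).
#' @export
simulate_coverage <- function(scaffold_lengths, x_scaffold_ids = character(0),
                              n_males = 6, n_females = 6, mean_depth = 30,
                              seed = 1, spike_rate = 0.01, window = 1000) {
  if (anyDuplicated(names(scaffold_lengths))) stop("scaffold ids must be unique")
  if (n_males + n_females < 1) stop("at least one sample required")
  withr::with_seed(seed, {
    samples <- c(sprintf("male_%02d", seq_len(n_males)),
                 sprintf("female_%02d", seq_len(n_females)))
    sex <- stats::setNames(rep(c("M", "F"), c(n_males, n_females)), samples)
    rows <- lapply(names(scaffold_lengths), function(sc) {
      nw <- max(1, floor(scaffold_lengths[[sc]] / window))
      start <- (seq_len(nw) - 1) * window
      data.frame(scaffold = sc, start = start, end = start + window,
                 stringsAsFactors = FALSE)
    })
    track <- do.call(rbind, rows)
    n <- nrow(track)
    spike <- stats::runif(n) < spike_rate
    depth <- sapply(samples, function(sm) {
      mu <- rep(mean_depth, n)
      if (sex[[sm]] == "M") mu[track$scaffold %in% x_scaffold_ids] <- mean_depth / 2
      mu[spike] <- mu[spike] * 4
      stats::rnbinom(n, mu = mu, size = 20)
    })
    out <- cbind(track, as.data.frame(depth))
    attr(out, "sex") <- sex
    attr(out, "spike") <- spike
    out
  })
}
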