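## Shared fixtures for the calibration and acceptance tests.
## Study-scale conditions: two clades of 15 taxa, 300 codons per gene,
## 0.5 expected substitutions per codon root-to-tip.

study_tree <- function(seed = 3) simulate_tree(15, 0.5, seed = seed)

## purifying/neutral mixture with no omega > 1 class
null_codon_model <- function() {
  mixture_codon_model(omega = c(0.1, 0.8, 1.0), p_omega = c(0.65, 0.25, 0.10))
}

## episodic positive selection: omega3 = 5 on 10% of sites
positive_codon_model <- function(omega3 = 5, weight = 0.1) {
  mixture_codon_model(omega = c(0.1, 0.9, omega3),
                      p_omega = c(0.6, 0.4 - weight, weight))
}

## null model with multinucleotide (double/triple-hit) substitutions
mh_null_codon_model <- function() {
  mixture_codon_model(omega = c(0.1, 0.8, 1.0), p_omega = c(0.65, 0.25, 0.10),
                      delta = 0.25, psi = 0.05)
}

## run the gene-wide test battery on n genes simulated under `model`
calibration_batch <- function(model, n_genes, tree, n_codons = 300,
                              variants = c("base", "S", "S_MH"),
                              seed_base = 1000, maxit = 12, null_maxit = 10) {
  rows <- lapply(seq_len(n_genes), function(i) {
    sim <- simulate_codon_alignment(tree, model, n_codons,
                                    seed = seed_base + i)
    gene_selection_tests(sim$alignment, tree, gene_id = paste0("g", i),
                         variants = variants, include_paml = FALSE,
                         include_global = FALSE, seed = seed_base + i,
                         maxit = maxit, null_maxit = null_maxit)
  })
  do.call(rbind, rows)
}

## Published-style Table of positive-selection counts (control vs immune)
## used as input data for the contingency statistics.
table2_counts <- data.frame(
  model = c("paml_nominal", "paml_fdr", "busted_nominal", "busted_fdr",
            "modelavg_nominal", "modelavg_fdr"),
  k_control = c(142, 138, 201, 218, 89, 20),
  n_control = 1005,
  k_immune = c(307, 305, 356, 363, 127, 37),
  n_immune = 977,
  stringsAsFactors = FALSE
)
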