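test_that("simulated trees have the requested shape, depth and determinism", {
  t1 <- simulate_tree(2, 0.1, seed = 4)
  expect_equal(length(t1$tip.label), 4)
  cm <- clade_map_from_tree(t1)
  expect_equal(as.vector(table(cm)[c("cladeA", "cladeB")]), c(2L, 2L))

  t2 <- simulate_tree(15, 0.5, seed = 4)
  expect_equal(length(t2$tip.label), 30)
  expect_true(all(t2$edge.length > 0))
  depth <- max(ape::node.depth.edgelength(t2))
  expect_equal(depth, 0.5, tolerance = 1e-9)

  expect_identical(ape::write.tree(simulate_tree(5, 0.3, seed = 11)),
                   ape::write.tree(simulate_tree(5, 0.3, seed = 11)))
  expect_false(identical(ape::write.tree(simulate_tree(5, 0.3, seed = 11)),
                         ape::write.tree(simulate_tree(5, 0.3, seed = 12))))
  expect_error(simulate_tree(1, 0.5), "n_taxa_per_clade")
  expect_error(simulate_tree(3, 0), "positive")
})

test_that("alignment simulation respects the mixture and contains no stops or gaps", {
  mdl <- mixture_codon_model()
  tree <- simulate_tree(3, 0.4, seed = 2)
  sim <- simulate_codon_alignment(tree, mdl, 50, seed = 3)
  aln <- sim$alignment
  expect_equal(aln$n_codons, 50)
  expect_false(any(is.na(aln$codon_idx))) # no gaps, no ambiguity
  expect_equal(nrow(sim$site_class), 50)
  expect_true(all(sim$site_class$omega %in% mdl$omega))

  ## all branch lengths zero -> identical sequences
  tree0 <- tree; tree0$edge.length[] <- 0
  sim0 <- simulate_codon_alignment(tree0, mdl, 30, seed = 5)
  expect_equal(length(unique(sim0$alignment$sequences)), 1)

  ## determinism
  expect_identical(simulate_codon_alignment(tree, mdl, 20, seed = 7)$alignment,
                   simulate_codon_alignment(tree, mdl, 20, seed = 7)$alignment)
})

test_that("long simulations recover the codon frequencies", {
  pi <- as.vector(stats::rgamma(61, 3)); pi <- pi / sum(pi)
  mdl <- mixture_codon_model(pi = pi, omega = 1, p_omega = 1)
  tree <- simulate_tree(2, 0.2, seed = 21)
  sim <- simulate_codon_alignment(tree, mdl, 50000, seed = 22)
  idx <- as.vector(sim$alignment$codon_idx)
  obs <- tabulate(idx, 61) / length(idx)
  se <- sqrt(pi * (1 - pi) / length(idx))
  ## tips are correlated through the tree, so allow inflated sampling error
  expect_true(all(abs(obs - pi) < 3 * se * sqrt(length(sim$alignment$taxa))))
})

test_that("double-hit substitutions appear when delta > 0", {
  mk <- function(delta) mixture_codon_model(omega = 1, p_omega = 1, delta = delta)
  tree <- simulate_tree(2, 0.25, seed = 31)
  pair_multi_diff <- function(aln) {
    a <- aln$codon_idx[1, ]; b <- aln$codon_idx[2, ] # sister taxa in clade A
    nd <- immusel:::codon_pair_tables()$ndiff
    sum(nd[cbind(a, b)] >= 2)
  }
  n_mh <- vapply(1:6, function(i) pair_multi_diff(
    simulate_codon_alignment(tree, mk(0.25), 400, seed = 40 + i)$alignment),
    numeric(1))
  n_0 <- vapply(1:6, function(i) pair_multi_diff(
    simulate_codon_alignment(tree, mk(0), 400, seed = 40 + i)$alignment),
    numeric(1))
  expect_gt(mean(n_mh), mean(n_0))
})

test_that("variant simulation writes VCF that round-trips", {
  cds <- random_test_cds(80)
  v <- simulate_variants(cds, target_pnps = 0.5, n_diploids = 8,
                         theta = 0.1, seed = 14)
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  vr <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(vr@fix), nrow(v))
  expect_equal(as.integer(vr@fix[, "POS"]), v$pos)
  expect_equal(unname(vr@fix[, "REF"]), v$ref)
  ## identical seed -> identical VCF body
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_variants(cds, 0.5, 8, 0.1, seed = 14), f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})

test_that("expression simulation hits tau targets exactly on noiseless means", {
  sim1 <- simulate_expression(10, n_tissues = 10, tau_target = 1,
                              library_sizes = rep(1e6, 10), seed = 3)
  expect_true(all(rowSums(sim1$true_means > 0) == 1))
  sim0 <- simulate_expression(10, n_tissues = 10, tau_target = 0,
                              library_sizes = rep(1e6, 10), seed = 3)
  expect_true(all(apply(sim0$true_means, 1, function(x) diff(range(x))) == 0))
  tt <- seq(0.05, 0.95, length.out = 20)
  simt <- simulate_expression(20, n_tissues = 10, tau_target = tt,
                              library_sizes = rep(1e6, 10), seed = 3)
  expect_equal(unname(tau(simt$true_means)), tt, tolerance = 1e-12)
  expect_error(simulate_expression(5, tau_target = 1.2), "\\[0, 1\\]")
  expect_error(simulate_expression(5, n_tissues = 1), "n_tissues")
})

test_that("coverage simulation encodes sex linkage and spikes", {
  lens <- stats::setNames(rep(30000, 6), sprintf("s%d", 1:6))
  cov <- simulate_coverage(lens, x_scaffold_ids = "s1", n_males = 5,
                           n_females = 5, mean_depth = 40, seed = 2,
                           spike_rate = 0.1)
  sex <- attr(cov, "sex")
  m <- rowMeans(cov[, names(sex)[sex == "M"]])
  f <- rowMeans(cov[, names(sex)[sex == "F"]])
  on_x <- cov$scaffold == "s1"
  spike <- attr(cov, "spike")
  expect_equal(mean(f[!on_x & !spike]) / mean(m[!on_x & !spike]), 1,
               tolerance = 0.1)
  expect_equal(mean(f[on_x & !spike]) / mean(m[on_x & !spike]), 2,
               tolerance = 0.25)
  ## spiked windows carry at least twice the mean total coverage
  total <- rowSums(cov[, names(sex)])
  expect_true(all(total[spike] >= 2 * mean(total)))
  expect_gt(sum(spike), 0)
  expect_error(simulate_coverage(lens, n_males = 0, n_females = 0), "at least one")
})
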