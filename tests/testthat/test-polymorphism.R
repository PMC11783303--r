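test_that("degeneracy classification matches hand enumeration of codons", {
  g <- classify_degeneracy("GGG") # Gly: third position 4-fold
  expect_equal(g$fold, c(0L, 0L, 4L))
  expect_equal(unname(count_sites(g)), c(1, 2))

  w <- classify_degeneracy("TGG") # Trp: no synonymous mutants at all
  expect_equal(w$fold, c(0L, 0L, 0L))
  expect_equal(unname(count_sites(w)["S_sites"]), 0)

  i <- classify_degeneracy("ATA") # Ile: third position 3-fold
  expect_equal(i$fold[3], 3L)
  expect_equal(unname(count_sites(i)["S_sites"]), 2 / 3)

  expect_error(classify_degeneracy("ATGTAACCC"), "stop")
  expect_error(classify_degeneracy("ATGA"), "divisible")
  expect_message(classify_degeneracy("ATGANA"), "ambiguous")
})

test_that("S_sites equals brute-force synonymous mutant counting", {
  set.seed(31)
  for (rep in 1:25) {
    cds <- random_test_cds(sample(3:30, 1))
    deg <- classify_degeneracy(cds)
    expect_equal(deg$profile$S_sites, brute_force_syn_mutants(cds) / 3)
    ## exact partition of counted positions
    expect_equal(deg$profile$S_sites + deg$profile$N_sites, nchar(cds))
  }
})

test_that("site count formulas are the stated linear combinations", {
  expect_equal(unname(count_sites(degeneracy_profile(10, 0, 0, 5))), c(5, 10))
  expect_equal(unname(count_sites(degeneracy_profile(0, 3, 0, 0))), c(1, 2))
  expect_equal(unname(count_sites(degeneracy_profile(0, 0, 3, 0))), c(2, 1))
})

make_variant_row <- function(pos = 5, qual = 60, saf = 4, sar = 4, rpl = 4,
                             rpr = 4, ab = 0.5, gts = rep("0/1", 8),
                             ref = "A", alt = "G", hwe_p = 0.5) {
  out <- data.frame(scaffold = "s1", pos = pos, ref = ref, alt = alt,
                    qual = qual, saf = saf, sar = sar, rpl = rpl, rpr = rpr,
                    ab = ab, hwe_p = hwe_p, stringsAsFactors = FALSE)
  gtm <- matrix(gts, nrow = 1)
  colnames(gtm) <- sprintf("sample_%d", seq_along(gts))
  cbind(out, as.data.frame(gtm, stringsAsFactors = FALSE))
}

test_that("the variant filter cascade applies every stated rule", {
  rows <- list(
    pass1 = make_variant_row(pos = 1),
    qual  = make_variant_row(pos = 2, qual = 29),
    qual_eq = make_variant_row(pos = 3, qual = 30), # strict inequality
    saf   = make_variant_row(pos = 4, saf = 0),
    sar   = make_variant_row(pos = 5, sar = 0),
    rpl   = make_variant_row(pos = 6, rpl = 1), # needs > 1
    rpr   = make_variant_row(pos = 7, rpr = 1),
    ab_lo = make_variant_row(pos = 8, ab = 0.29),
    ab_hi = make_variant_row(pos = 9, ab = 0.71),
    ab_ok = make_variant_row(pos = 10, ab = 0.5),
    hwe   = make_variant_row(pos = 11, hwe_p = 5e-5),
    miss  = make_variant_row(pos = 12, gts = c(rep("./.", 5), rep("0/1", 3))),
    multi = make_variant_row(pos = 13, alt = "G,T")
  )
  v <- do.call(rbind, rows)
  out <- site_filters(v, thresholds = list(max_missing = 5))
  expect_setequal(out$pos, c(1, 10))
  expect_equal(nrow(out), 2)
})

test_that("excess-heterozygote filtering uses the genotypes when no hwe_p given", {
  v <- rbind(make_variant_row(pos = 1, gts = rep("0/1", 24)),  # all het
             make_variant_row(pos = 2, gts = c(rep("0/0", 12), rep("0/1", 6),
                                               rep("1/1", 6))))
  v$hwe_p <- NULL
  out <- site_filters(v)
  expect_equal(out$pos, 2) # complete heterozygosity is an excess-het signal
  ## the exact one-sided p is monotone in heterozygote excess
  expect_lt(immusel:::hwe_excess_het_p(0, 24, 0),
            immusel:::hwe_excess_het_p(6, 12, 6))
})

test_that("excessive-coverage intervals follow the 2x-mean rule, half-open", {
  expect_equal(nrow(excessive_coverage_intervals(rep(7, 10))), 0)
  one <- excessive_coverage_intervals(c(1, 1, 50, 1))
  expect_equal(one, data.frame(start = 2L, end = 3L))
  expect_equal(nrow(excessive_coverage_intervals(c(10, 10, 25, 25, 10, 30))), 0)
  expect_equal(nrow(excessive_coverage_intervals(c(10, 40, 40, 10))), 0)
  expect_equal(nrow(excessive_coverage_intervals(c(10, 60, 60, 10))), 0)
  expect_equal(excessive_coverage_intervals(c(0, 80, 80, 0)),
               data.frame(start = 1L, end = 3L))
  expect_equal(nrow(excessive_coverage_intervals(numeric(0))), 0)
})

test_that("per-sample coverage mask applies halved thresholds for males on X", {
  depths <- cbind(m = c(30, 30, 30, 9, 50, 30),
                  f = c(30, 30, 30, 30, 30, 30))
  scaf <- c("a", "a", "a", "a", "a", "x")
  sex <- c(m = "M", f = "F")
  mask <- per_sample_coverage_mask(depths, scaf, sex, x_scaffolds = "x")
  ## site 4: 9 < 30/3 is FALSE (9 < 10 TRUE) -> masked; site 5: 50 > 45 masked
  expect_equal(which(mask), c(4, 5, 6))
  ## site 6 on X for the male: thresholds halved -> 30 > 1.5*30/2 = 22.5 masked

  depths2 <- cbind(m = c(16, 15, 15, 15, 15, 15), f = rep(30, 6))
  mask2 <- per_sample_coverage_mask(depths2, scaf, sex, x_scaffolds = "x")
  ## male median 15; on X bounds become [2.5, 11.25] -> site 6 (15) masked
  expect_true(mask2[6])
  expect_false(any(mask2[1:5]))
})

test_that("X scaffolds are recovered from simulated coverage ratios", {
  lens <- stats::setNames(rep(50000, 30), sprintf("scf%02d", 1:30))
  xids <- sprintf("scf%02d", 1:5)
  cov <- simulate_coverage(lens, xids, n_males = 6, n_females = 6,
                           mean_depth = 30, seed = 9, spike_rate = 0)
  lab <- assign_sex_linked_scaffolds(cov)
  expect_true(all(lab[xids] == "X"))
  expect_true(all(lab[setdiff(names(lens), xids)] == "autosome"))
})

test_that("repeat subtraction uses half-open BED intervals", {
  v <- do.call(rbind, lapply(c(10, 15, 20), function(p) make_variant_row(pos = p)))
  bed <- data.frame(scaffold = "s1", start = 9, end = 15)
  out <- subtract_repeats(v, bed)
  ## SNP pos 10 -> 0-based 9 = interval start: dropped; pos 15 -> 14 < 15: dropped
  ## pos 20 kept; and a SNP exactly at end coordinate is kept:
  expect_equal(out$pos, 20)
  v2 <- make_variant_row(pos = 16) # 0-based 15 == end -> outside
  expect_equal(nrow(subtract_repeats(v2, bed)), 1)
  expect_error(subtract_repeats(v, data.frame(scaffold = "s1", start = 5, end = 2)),
               "malformed")
})

test_that("MAF filter thresholds on the folded allele frequency", {
  gts31 <- function(minor) c(rep("0/1", minor), rep("0/0", 31 - minor))
  v3 <- make_variant_row(gts = gts31(3))  # 3/62 ~ 0.048
  v4 <- make_variant_row(gts = gts31(4))  # 4/62 ~ 0.0645
  expect_equal(nrow(maf_filter(v3, 0.0625)), 0)
  expect_equal(nrow(maf_filter(v4, 0.0625)), 1)
  expect_equal(nrow(maf_filter(v3, 0)), 1) # threshold 0 is the identity
})

test_that("SNP classification matches the code table and handles strand", {
  expect_equal(classify_snp("AAA", 3, "A", "G"), "synonymous")   # Lys AAA/AAG
  expect_equal(classify_snp("AAA", 1, "A", "C"), "nonsynonymous") # Gln
  expect_equal(classify_snp("TGC", 1, "T", "A"), "nonsynonymous") # stop-ish/other
  ## minus strand: genome alleles are complements of the CDS alleles
  expect_equal(classify_snp("AAA", 3, "T", "C", strand = "-"),
               classify_snp("AAA", 3, "A", "G"))
  expect_error(classify_snp("AAA", 2, "G", "C"), "does not match")
  expect_message(out <- classify_snp("ANA", 2, "N", "C"), "ambiguous")
  expect_true(is.na(out))
})

test_that("pN/pS uses the p(S+1) pseudo-count", {
  r <- compute_pnps(0, 0, 100, 300)
  expect_equal(r$pnps, 0)
  r2 <- compute_pnps(0, 5, 100, 300)
  expect_equal(r2$pN, 5 / 300)
  expect_equal(r2$pS_adj, 1 / 100)
  expect_equal(r2$pnps, 5 / 3)
  expect_true(is.na(compute_pnps(1, 1, 0, 10)$pnps))
})

test_that("mean ortholog pN/pS averages shared genes and respects require_both", {
  a <- c(g1 = 0.2, g2 = 0.4)
  b <- c(g1 = 0.4, g3 = 0.6)
  m <- mean_ortholog_pnps(a, b)
  expect_equal(unname(m["g1"]), 0.3)
  expect_true(is.na(m["g2"]))
  m2 <- mean_ortholog_pnps(a, b, require_both = FALSE)
  expect_equal(unname(m2["g2"]), 0.4)
  expect_equal(unname(m2["g3"]), 0.6)
})

test_that("aligned-interval restriction filters sites and SNPs together", {
  cds <- strrep("GGG", 10) # 30 positions
  deg <- classify_degeneracy(cds)
  v <- rbind(make_variant_row(pos = 3, ref = "G"),
             make_variant_row(pos = 25, ref = "G"))
  full <- restrict_to_aligned_intervals(deg$fold, v,
                                        data.frame(start = 0, end = 30))
  expect_equal(full$profile$S_sites, deg$profile$S_sites)
  expect_equal(nrow(full$snps), 2)

  half <- restrict_to_aligned_intervals(deg$fold, v,
                                        data.frame(start = 0, end = 15))
  expect_equal(half$profile$S_sites + half$profile$N_sites, 15)
  expect_equal(half$snps$pos, 3)
  expect_message(
    expect_null(restrict_to_aligned_intervals(deg$fold, v,
                                              data.frame(start = 0, end = 0))),
    "dropped")
})

test_that("simulated variant tables recover the target pN/pS on average", {
  set.seed(5)
  ratios <- vapply(1:60, function(i) {
    cds <- random_test_cds(120)
    v <- simulate_variants(cds, target_pnps = 1, n_diploids = 16,
                           theta = 0.25, seed = i)
    deg <- classify_degeneracy(cds)
    n_syn <- sum(v$type == "syn")
    n_non <- sum(v$type == "nonsyn")
    (n_non / deg$profile$N_sites) / (n_syn / deg$profile$S_sites)
  }, numeric(1))
  expect_lt(abs(mean(ratios, na.rm = TRUE) - 1), 0.2)

  ## no nonsynonymous SNPs at target 0; identical tables for identical seed
  cds <- random_test_cds(60)
  v0 <- simulate_variants(cds, 0, n_diploids = 8, theta = 0.3, seed = 2)
  expect_true(all(v0$type == "syn"))
  expect_identical(simulate_variants(cds, 0.5, 8, 0.3, seed = 3),
                   simulate_variants(cds, 0.5, 8, 0.3, seed = 3))
})
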