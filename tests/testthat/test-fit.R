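## Fitting tests run at reduced scale (8-10 taxa, 100-150 codons); the
## calibration properties at the study scale live in test-acceptance.R.

fit_tree <- simulate_tree(5, 0.45, seed = 51)

test_that("constrained fits never beat unconstrained ones (nesting)", {
  mdl <- mixture_codon_model(omega = c(0.1, 0.7, 1), p_omega = c(0.5, 0.3, 0.2))
  sim <- simulate_codon_alignment(fit_tree, mdl, 120, seed = 52)
  for (v in c("base", "S")) {
    tst <- busted_like_test(sim$alignment, fit_tree, v, maxit = 15)
    expect_lte(tst$fit_null$log_likelihood,
               tst$fit_alt$log_likelihood + 1e-6)
    expect_gte(tst$LRT, 0)
    expect_true(tst$p >= 0 && tst$p <= 1)
  }
})

test_that("identical sequences give LRT 0 and p 1", {
  aln <- codon_alignment(stats::setNames(rep(strrep("ATGAAACCCGGG", 10), 10),
                                         fit_tree$tip.label))
  tst <- busted_like_test(aln, fit_tree, "base", maxit = 10)
  expect_equal(tst$LRT, 0, tolerance = 1e-4)
  expect_equal(tst$p, 1, tolerance = 1e-4)
  ## chi-squared(2 df) reference point
  expect_equal(stats::pchisq(5.99, 2, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
})

test_that("a strong positive-selection class is detected and estimated above 1", {
  mdl_pos <- mixture_codon_model(omega = c(0.1, 0.9, 5),
                                 p_omega = c(0.6, 0.3, 0.1))
  hits <- 0
  lrts <- numeric(4)
  for (i in 1:4) {
    sim <- simulate_codon_alignment(fit_tree, mdl_pos, 150, seed = 60 + i)
    tst <- busted_like_test(sim$alignment, fit_tree, "base", maxit = 15)
    if (tst$fit_alt$params$omega[3] > 1) hits <- hits + 1
    lrts[i] <- tst$LRT
  }
  expect_gte(hits, 3)
  expect_gt(mean(lrts), stats::qchisq(0.95, 2)) # strong signal on average
})

test_that("data with omega capped at 1 yield near-zero gene-wide LRTs", {
  mdl_null <- mixture_codon_model(omega = c(0.1, 1, 1),
                                  p_omega = c(0.6, 0.2, 0.2))
  lrts <- vapply(1:3, function(i) {
    sim <- simulate_codon_alignment(fit_tree, mdl_null, 150, seed = 70 + i)
    busted_like_test(sim$alignment, fit_tree, "base", maxit = 15)$LRT
  }, numeric(1))
  expect_lt(median(lrts), stats::qchisq(0.95, 2))
})

test_that("M2a nests M1a and the PAML-style test is well-formed", {
  mdl <- mixture_codon_model(omega = c(0.15, 0.8, 1), p_omega = c(0.6, 0.2, 0.2))
  sim <- simulate_codon_alignment(fit_tree, mdl, 120, seed = 81)
  tst <- m1a_m2a_test(sim$alignment, fit_tree, maxit = 15)
  expect_gte(tst$fit_m2a$log_likelihood, tst$fit_m1a$log_likelihood - 1e-6)
  expect_gte(tst$LRT, 0)
  expect_true(tst$fit_m2a$params$omega[3] >= 1)
})

test_that("single-omega estimates recover the simulated dN/dS", {
  oms <- vapply(1:5, function(i) {
    sim <- simulate_codon_alignment(
      fit_tree, mixture_codon_model(omega = 0.2, p_omega = 1), 200,
      seed = 90 + i)
    fit_global_omega(sim$alignment, fit_tree, maxit = 25)$omega
  }, numeric(1))
  expect_gt(median(oms), 0.12)
  expect_lt(median(oms), 0.3)
  expect_true(all(oms >= 0))

  ## zero variation is flagged unidentifiable
  flat <- codon_alignment(stats::setNames(rep(strrep("ATG", 30), 10),
                                          fit_tree$tip.label))
  gf <- fit_global_omega(flat, fit_tree)
  expect_false(gf$identifiable)
  expect_true(is.na(gf$omega))
})

test_that("AIC is consistent with the likelihood and parameter count", {
  mdl <- mixture_codon_model()
  sim <- simulate_codon_alignment(fit_tree, mdl, 80, seed = 99)
  f <- fit_model(sim$alignment, fit_tree, "base", maxit = 12)
  expect_equal(f$AIC, 2 * f$n_free_params - 2 * f$log_likelihood)
})

test_that("model-averaged p follows Akaike-weight arithmetic", {
  eq <- model_averaged_p(aic = c(10, 10, 10), p = c(0.01, 0.02, 0.03))
  expect_equal(eq$p, 0.02)
  expect_equal(sum(eq$weights), 1)

  dom <- model_averaged_p(aic = c(100, 150, 150), p = c(0.2, 0.9, 0.9))
  w1 <- 1 / (1 + 2 * exp(-25))
  expect_equal(dom$p, w1 * 0.2 + (1 - w1) * 0.9, tolerance = 1e-8)
  expect_equal(dom$p, 0.2, tolerance = 1e-8)

  single <- model_averaged_p(aic = c(100, 90, 80), p = c(0.5, 0.1, 0.9),
                             converged = c(TRUE, FALSE, FALSE))
  expect_equal(single$p, 0.5)
  none <- model_averaged_p(aic = 1, p = 0.1, converged = FALSE)
  expect_true(is.na(none$p))
})

test_that("BH correction reproduces the step-up computation", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$flag))
  expect_equal(bh_fdr(rep(1, 5))$q, rep(1, 5))
  expect_equal(bh_fdr(0.07)$q, 0.07)
  expect_true(bh_fdr(0.07)$flag)  # q < 0.2
  expect_equal(length(bh_fdr(numeric(0))$q), 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
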