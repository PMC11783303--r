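test_that("covariate transforms and Z-scoring follow the analysis plan", {
  tb <- data.frame(dnds = c(0.04, 0.25, 1), tau = c(0, 1, 0.5),
                   mean_expression = c(10, 100, 1000),
                   ppi_count = c(1, 10, 100), seq_length = c(1000, 1000, 1000),
                   pnps = c(0.1, 0.2, 0.3))
  out <- transform_covariates(tb)
  expect_equal(out$sqrt_dnds, sqrt(tb$dnds))
  expect_equal(out$asinsqrt_tau, c(0, pi / 2, asin(sqrt(0.5))))
  expect_equal(out$log10_seq_length, rep(3, 3))
  for (cn in grep("_z$", names(out), value = TRUE)) {
    z <- out[[cn]]
    if (all(is.finite(z)) && stats::sd(z) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-9)
      expect_equal(stats::sd(z), 1, tolerance = 1e-9)
    }
  }
  expect_error(transform_covariates(data.frame(dnds = -1)), "negative")
})

test_that("two-proportion G test reproduces independent binomial arithmetic", {
  ## equal proportions -> G = 0, p = 1
  eq <- two_by_two_lrt(10, 100, 20, 200)
  expect_equal(eq$G, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)

  ## oracle equivalence: direct maximization of the two binomial likelihoods
  ## on a grid of small tables
  oracle <- function(k1, n1, k2, n2) {
    lbin <- function(k, n, p) stats::dbinom(k, n, p, log = TRUE)
    2 * (lbin(k1, n1, k1 / n1) + lbin(k2, n2, k2 / n2) -
           lbin(k1, n1, (k1 + k2) / (n1 + n2)) -
           lbin(k2, n2, (k1 + k2) / (n1 + n2)))
  }
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(two_by_two_lrt(k1, n1, k2, n2)$G,
                 max(0, oracle(k1, n1, k2, n2)), tolerance = 1e-10)
  }
  expect_error(two_by_two_lrt(5, 0, 1, 10), "positive")
  expect_error(two_by_two_lrt(11, 10, 1, 10), "0 <= k <= n")
})

test_that("binomial GLM recovers a known category effect with calibrated LR tests", {
  sim_one <- function(seed, beta = 1) {
    withr::with_seed(seed, {
      n <- 500
      cat2 <- rep(c("control", "treat"), each = n)
      p <- stats::plogis(-2 + beta * (cat2 == "treat"))
      data.frame(positive = rbinom(2 * n, 1, p), category = cat2)
    })
  }
  hits <- vapply(1:20, function(s) {
    fit <- fit_binomial_glm(sim_one(s), positive ~ category)
    abs(stats::coef(fit$model)[["categorytreat"]] - 1) <= 0.35
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## null covariate: LR test approximately uniform (checked via rejection rate)
  rej <- vapply(1:200, function(s) {
    d <- sim_one(s, beta = 0.8)
    d$z <- withr::with_seed(s + 1e4, rnorm(nrow(d)))
    fit <- fit_binomial_glm(d, positive ~ category + z)
    fit$terms$p[fit$terms$term == "z"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  expect_error(fit_binomial_glm(data.frame(positive = c(0, 1), category = "a"),
                                positive ~ category), "single level")
})

test_that("linear model type-3 F tests behave on identical and shifted groups", {
  set.seed(9)
  base <- rnorm(200)
  d_same <- data.frame(sqrt_dnds = c(base, base),
                       category = rep(c("a", "b"), each = 200))
  f_same <- fit_linear_model(d_same, sqrt_dnds ~ category)
  expect_lt(f_same$terms$statistic[1], 1e-20)
  expect_equal(stats::df.residual(f_same$model), 400 - 2)

  pow <- vapply(1:30, function(s) {
    withr::with_seed(s, {
      d <- data.frame(sqrt_dnds = c(rnorm(200, 0, 0.25), rnorm(200, 0.1, 0.25)),
                      category = rep(c("a", "b"), each = 200))
    })
    fit_linear_model(d, sqrt_dnds ~ category)$terms$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.9)
})

test_that("Monte Carlo Dunnett adjustment matches known reference points", {
  set.seed(15)
  n <- 120
  d <- data.frame(
    y = rnorm(4 * n),
    category = factor(rep(c("control", "g1", "g2", "g3"), each = n)))
  d$y[d$category == "g2"] <- d$y[d$category == "g2"] + 0.5
  fit <- stats::lm(y ~ category, data = d)
  dn <- dunnett_vs_control(fit, "control", seed = 42)

  ## ordering: unadjusted <= adjusted <= Bonferroni
  expect_true(all(dn$p_unadjusted <= dn$p_adjusted + 1e-12))
  expect_true(all(dn$p_adjusted <= pmin(1, 3 * dn$p_unadjusted) + 0.003))

  ## cross-check against multcomp's Dunnett contrasts
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(category = "Dunnett")))
  expect_equal(unname(dn$p_adjusted),
               unname(as.vector(mc$test$pvalues)), tolerance = 0.01)

  ## single comparison: adjusted equals unadjusted within MC error
  d2 <- d[d$category %in% c("control", "g1"), ]
  d2$category <- droplevels(factor(d2$category))
  dn2 <- dunnett_vs_control(stats::lm(y ~ category, data = d2), "control",
                            seed = 7)
  expect_equal(dn2$p_adjusted, dn2$p_unadjusted, tolerance = 0.005)
})

test_that("Dunnett adjustment matches the independence closed form on orthogonal contrasts", {
  ## three independent two-group comparisons sharing a control are not
  ## orthogonal, so construct the independent case directly: identity
  ## correlation via a diagonal design
  set.seed(33)
  ## simulate three independent z statistics by a regression with orthogonal
  ## predictors
  n <- 600
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- rnorm(n) + 0.12 * X[, 2]
  d <- data.frame(y, X)
  fit <- stats::lm(y ~ x1 + x2 + x3, data = d)
  cf <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit))[-1])
  p_un <- 2 * stats::pt(abs(cf / se), stats::df.residual(fit), lower.tail = FALSE)
  ## what dunnett-style max-|T| adjustment should give under independence
  closed <- 1 - (1 - p_un)^3
  ## reuse the internal machinery through a fake factor is awkward; instead
  ## verify with the same MC approach on an identity correlation
  R <- diag(3)
  draws <- withr::with_seed(5, {
    Z <- matrix(rnorm(2e5 * 3), 2e5)
    s <- sqrt(stats::rchisq(2e5, stats::df.residual(fit)) / stats::df.residual(fit))
    apply(abs(Z / s), 1, max)
  })
  p_mc <- vapply(abs(cf / se), function(t0) mean(draws >= t0), numeric(1))
  expect_equal(unname(p_mc), unname(closed), tolerance = 0.01)
})

test_that("Kruskal-Wallis/Dunn agrees with the rank-sum identity on two groups", {
  set.seed(19)
  x <- c(rnorm(40), rnorm(40, 0.6))
  g <- rep(c("control", "treat"), each = 40)
  res <- kruskal_dunn(x, g, "control")
  ## KW chi2 (1 df) equals the square of the Dunn z for two groups
  expect_equal(unname(res$kw_statistic), unname(res$dunn$z^2), tolerance = 1e-9)
  expect_equal(res$dunn$p_bh, res$dunn$p) # single comparison: BH is identity

  ## constant data: statistic 0
  resc <- kruskal_dunn(rep(1, 20), rep(c("a", "b"), 10), "a")
  expect_equal(unname(resc$kw_statistic), 0)

  ## identical distributions: p roughly uniform (rejection rate near 5%)
  rej <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      xx <- rnorm(60)
      gg <- sample(rep(c("control", "b", "c"), 20))
    })
    kruskal_dunn(xx, gg, "control")$kw_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.1)
})

test_that("partial Spearman correlations behave as rank-based partials", {
  set.seed(23)
  x <- rnorm(100)
  expect_equal(partial_spearman(x, x)$r_s, 1)

  ## invariance to monotone transforms
  y <- x + rnorm(100, 0, 0.5)
  z <- data.frame(z = rnorm(100))
  a <- partial_spearman(x, y, z)
  b <- partial_spearman(exp(x), y^3 + 5 * y, z)
  ## y^3+5y is monotone; exp monotone
  expect_equal(a$r_s, b$r_s, tolerance = 1e-12)

  ## conditional independence: mean r_s near 0
  rs <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      zz <- rnorm(60)
      xx <- zz + rnorm(60)
      yy <- zz + rnorm(60)
    })
    partial_spearman(xx, yy, data.frame(z = zz))$r_s
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("proportion ratio range reproduces printed-style summaries", {
  counts <- data.frame(k_control = c(10, 10), n_control = c(100, 100),
                       k_immune = c(10, 10), n_immune = c(100, 100))
  expect_equal(unname(proportion_ratio_range(counts)), c(1, 1))
  one <- data.frame(k_control = 10, n_control = 100, k_immune = 17,
                    n_immune = 100)
  rr <- proportion_ratio_range(one)
  expect_equal(unname(rr[1]), unname(rr[2]))
  expect_error(proportion_ratio_range(
    data.frame(k_control = 0, n_control = 10, k_immune = 5, n_immune = 10)),
    "zero control")
})
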