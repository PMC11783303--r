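## Category-level statistics: covariate transforms, contingency
## likelihood-ratio tests, binomial/linear models with type-3 term tests,
## Dunnett contrasts against the control category, Kruskal-Wallis with
## Dunn's post hoc test, and partial Spearman correlations.

#' Transform and Z-score gene covariates
#'
#' Applies the analysis transforms — square root for dN/dS, log10 for mean
#' expression, PPI count and sequence length, arcsine-square-root for tau —
#' and Z-scores each continuous predictor over its non-missing rows
#' (suffix `_z`).
#'
#' @param table Gene covariate `data.frame`; recognized raw columns are
#'   `dnds`, `pnps`, `mean_expression`, `tau`, `ppi_count`, `seq_length`
#'   (missing columns are skipped).
#' @return The table with added transformed and Z-scored columns
#'   (`sqrt_dnds`, `log10_mean_expression`, `asinsqrt_tau`, ... and `*_z`).
#' @export
transform_covariates <- function(table) {
  zscore <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  if ("dnds" %in% names(table)) {
    if (any(table$dnds < 0, na.rm = TRUE)) stop("negative dN/dS")
    table$sqrt_dnds <- sqrt(table$dnds)
  }
  for (cn in c("mean_expression", "ppi_count", "seq_length")) {
    if (cn %in% names(table))
      table[[paste0("log10_", cn)]] <- log10(table[[cn]])
  }
  if ("tau" %in% names(table)) {
    if (any(table$tau < 0 | table$tau > 1, na.rm = TRUE))
      stop("tau outside [0, 1]")
    table$asinsqrt_tau <- asin(sqrt(table$tau))
  }
  predictors <- intersect(
    c("pnps", "log10_mean_expression", "asinsqrt_tau", "log10_ppi_count",
      "log10_seq_length"), names(table))
  for (cn in predictors) table[[paste0(cn, "_z")]] <- zscore(table[[cn]])
  table
}

#' Two-proportion likelihood-ratio (G) test
#'
#' `G = 2 * (log-likelihood of the saturated two-proportion binomial model -
#' log-likelihood of the pooled model)`, compared against chi-squared with
#' 1 df.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `G`, `df` (1) and `p`.
#' @export
two_by_two_lrt <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts must satisfy 0 <= k <= n")
  ll <- function(k, n, p) {
    out <- 0
    if (k > 0) out <- out + k * log(p)
    if (n - k > 0) out <- out + (n - k) * log(1 - p)
    out
  }
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  G <- 2 * (ll(k1, n1, p1) + ll(k2, n2, p2) - ll(k1, n1, pp) - ll(k2, n2, pp))
  G <- max(0, G)
  list(G = G, df = 1, p = stats::pchisq(G, 1, lower.tail = FALSE))
}

## Shared machinery: fit a model and compute type-3 term tests via drop1.
term_tests <- function(model, test) {
  d1 <- stats::drop1(model, test = test)
  d1 <- d1[-1, , drop = FALSE] # drop the <none> row
  stat_col <- if (test == "LRT") "LRT" else "F value"
  p_col <- grep("^Pr", names(d1), value = TRUE)[1]
  data.frame(term = rownames(d1),
             statistic = d1[[stat_col]],
             df = d1$Df,
             p = d1[[p_col]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Binomial GLM for positive selection with type-3 LR tests
#'
#' Logistic regression of the positive-selection flag on gene category and
#' optional covariates; each term is tested by a likelihood-ratio test of
#' the full model against the model with that term dropped.
#'
#' @param table Gene covariate table (rows with missing model variables are
#'   dropped listwise).
#' @param formula Model formula, e.g. `positive ~ category + pnps_z`.
#' @return List of class `category_model`: `model` (the glm fit), `terms`
#'   (term, LR chi-squared, df, p), `n`, `separation` flag (term p-values
#'   are set to `NA` when complete separation is detected).
#' @export
fit_binomial_glm <- function(table, formula) {
  mf <- stats::model.frame(formula, data = table, na.action = stats::na.omit)
  fac <- vapply(mf, is.factor, logical(1)) |
    vapply(mf, is.character, logical(1))
  for (v in names(mf)[fac]) {
    if (length(unique(mf[[v]])) < 2)
      stop("factor '", v, "' has a single level after listwise deletion")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    do.call(stats::glm, list(formula = formula, family = stats::binomial(),
                             data = mf)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  terms <- term_tests(fit, "LRT")
  if (warned) terms$p <- NA_real_
  structure(list(model = fit, terms = terms, n = nrow(mf),
                 separation = warned, kind = "binomial"),
            class = "category_model")
}

#' Linear model for (transformed) dN/dS with type-3 F tests
#'
#' Ordinary least squares with marginal (type-3) F tests per term.
#'
#' @inheritParams fit_binomial_glm
#' @param formula Model formula, e.g. `sqrt_dnds ~ category + pnps_z`.
#' @return A `category_model` list: `model`, `terms`, `n`, `rank_deficient`.
#' @export
fit_linear_model <- function(table, formula) {
  mf <- stats::model.frame(formula, data = table, na.action = stats::na.omit)
  fit <- do.call(stats::lm, list(formula = formula, data = mf))
  rank_deficient <- fit$rank < ncol(stats::model.matrix(fit))
  terms <- term_tests(fit, "F")
  structure(list(model = fit, terms = terms, n = nrow(mf),
                 rank_deficient = rank_deficient, kind = "linear"),
            class = "category_model")
}

#' @export
print.category_model <- function(x, ...) {
  cat("Category model (", x$kind, "), n = ", x$n, "\n", sep = "")
  print(x$terms, digits = 4)
  invisible(x)
}

#' Dunnett contrasts of each category against the control
#'
#' Simultaneous comparisons of every non-control category level against the
#' control, adjusted for multiplicity as `P(max_j |T_j| >= |t_obs|)` under
#' the joint normal (GLM) or t (linear model) null with the correlation
#' structure of the contrast estimates, evaluated by Monte Carlo with a
#' fixed seed (default 200,000 draws, adjusted p-values accurate to about
#' +/- 0.002).
#'
#' @param fit A `category_model` from [fit_binomial_glm()] /
#'   [fit_linear_model()], or a bare `glm`/`lm`.
#' @param control_level Control level of the category factor.
#' @param factor_name Name of the category factor (default `"category"`).
#' @param seed Integer seed for the Monte Carlo draws.
#' @param nsim Number of Monte Carlo draws.
#' @return `data.frame`: `category`, `estimate` (link scale), `se`, `t`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunnett_vs_control <- function(fit, control_level, factor_name = "category",
                               seed = 1, nsim = 2e5) {
  model <- if (inherits(fit, "category_model")) fit$model else fit
  data <- stats::model.frame(model)
  if (!factor_name %in% names(data))
    stop("factor '", factor_name, "' not in the model frame")
  f <- factor(data[[factor_name]])
  if (!control_level %in% levels(f)) stop("control level not present")
  data[[factor_name]] <- stats::relevel(f, ref = control_level)
  model <- stats::update(model, data = data)

  cf <- stats::coef(model)
  V <- stats::vcov(model)
  idx <- grep(paste0("^", factor_name), names(cf))
  if (length(idx) < 1) stop("no category contrasts to test")
  est <- cf[idx]
  se <- sqrt(diag(V)[idx])
  tval <- est / se
  R <- stats::cov2cor(V[idx, idx, drop = FALSE])

  is_lm <- inherits(model, "lm") && !inherits(model, "glm")
  df_resid <- if (is_lm) model$df.residual else Inf
  L <- chol(R)
  draws <- withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(nsim * length(idx)), nsim) %*% L
    if (is.finite(df_resid)) {
      s <- sqrt(stats::rchisq(nsim, df_resid) / df_resid)
      Z <- Z / s
    }
    do.call(pmax, lapply(seq_len(ncol(Z)), function(j) abs(Z[, j])))
  })
  p_adj <- vapply(abs(tval), function(t0) mean(draws >= t0), numeric(1))
  p_un <- if (is.finite(df_resid))
    2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  else 2 * stats::pnorm(abs(tval), lower.tail = FALSE)
  data.frame(category = sub(paste0("^", factor_name), "", names(cf)[idx]),
             estimate = unname(est), se = unname(se), t = unname(tval),
             p_unadjusted = unname(p_un), p_adjusted = unname(p_adj),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Dunn's post hoc contrasts against a control
#'
#' Tie-corrected Kruskal-Wallis test over all groups, followed by Dunn's
#' z-tests of each category against the control with Benjamini-Hochberg
#' correction over that comparison family.
#'
#' @param values Numeric response.
#' @param categories Group labels (same length).
#' @param control_level Control group label.
#' @return List: `kw_statistic`, `kw_df`, `kw_p`, `dunn` (`data.frame` with
#'   `category`, `z`, `p`, `p_bh`).
#' @export
kruskal_dunn <- function(values, categories, control_level) {
  ok <- !is.na(values) & !is.na(categories)
  values <- values[ok]
  categories <- as.character(categories[ok])
  groups <- unique(categories)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!control_level %in% groups) stop("control level not present")
  others <- setdiff(groups, control_level)
  if (length(unique(values)) == 1) {
    return(list(kw_statistic = 0, kw_df = length(groups) - 1, kw_p = 1,
                dunn = data.frame(category = others, z = 0, p = 1, p_bh = 1,
                                  stringsAsFactors = FALSE)))
  }
  kw <- stats::kruskal.test(values, factor(categories))

  N <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, categories, mean)
  n_g <- table(categories)
  z <- vapply(others, function(g) {
    (rbar[[g]] - rbar[[control_level]]) /
      sqrt(sigma2_base * (1 / n_g[[g]] + 1 / n_g[[control_level]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(kw_statistic = unname(kw$statistic), kw_df = unname(kw$parameter),
       kw_p = kw$p.value,
       dunn = data.frame(category = others, z = unname(z), p = unname(p),
                         p_bh = stats::p.adjust(p, "BH"),
                         stringsAsFactors = FALSE))
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables, residualizes the ranks of `x` and `y` on
#' the control ranks by linear regression, and correlates the residuals;
#' the p-value uses the t approximation with `n - 2 - n_controls` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors.
#' @param controls Optional `data.frame`/matrix of control variables.
#' @return List with `r_s`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(controls)) {
    controls <- as.data.frame(controls)
    keep <- keep & stats::complete.cases(controls)
    controls <- controls[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(controls)) 0 else ncol(controls)
  if (n <= k + 2) stop("too few observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(r_s = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (k > 0) {
    rc <- as.data.frame(lapply(controls, rank))
    rx <- stats::resid(stats::lm(rx ~ ., data = rc))
    ry <- stats::resid(stats::lm(ry ~ ., data = rc))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r_s = r, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE), n = n)
}

#' Range of immune:control positive-selection proportion ratios
#'
#' For each row of counts, the ratio of the immune to the control proportion
#' of genes with signatures of positive selection; returns the minimum and
#' maximum ratio rounded to one decimal.
#'
#' @param counts `data.frame` with columns `k_control`, `n_control`,
#'   `k_immune`, `n_immune` (one row per model/threshold).
#' @return Named numeric vector `c(min_ratio, max_ratio)`.
#' @export
proportion_ratio_range <- function(counts) {
  p_c <- counts$k_control / counts$n_control
  p_i <- counts$k_immune / counts$n_immune
  if (any(p_c == 0)) stop("zero control proportion")
  ratio <- p_i / p_c
  c(min_ratio = round(min(ratio), 1), max_ratio = round(max(ratio), 1))
}
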