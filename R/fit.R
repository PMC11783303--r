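## Maximum-likelihood fitting of the mixture codon models and the gene-wide
## tests for episodic positive selection.
##
## Parameterization (all unconstrained):
##   kappa, scale, omega increments, delta, psi on the log scale; ordering of
##   omega classes enforced by downward logistic factors from the largest
##   class; synonymous-rate classes as two free log-rates with the third
##   fixed at 1 and the whole set renormalized to weighted mean 1; mixture
##   weights by stick-breaking logits.  The omega-class weights are profiled
##   out of the outer optimization by an inner EM pass, which markedly
##   reduces the outer dimension.

variant_spec <- function(variant, constrained = FALSE) {
  variant <- match.arg(variant, c("base", "S", "S_MH", "m1a", "m2a", "global"))
  vs <- switch(variant,
    base  = list(K = 3, has_S = FALSE, has_MH = FALSE,
                 omega_mode = if (constrained) "busted_null" else "busted_alt"),
    S     = list(K = 3, has_S = TRUE, has_MH = FALSE,
                 omega_mode = if (constrained) "busted_null" else "busted_alt"),
    S_MH  = list(K = 3, has_S = TRUE, has_MH = TRUE,
                 omega_mode = if (constrained) "busted_null" else "busted_alt"),
    m1a   = list(K = 2, has_S = FALSE, has_MH = FALSE, omega_mode = "m1a"),
    m2a   = list(K = 3, has_S = FALSE, has_MH = FALSE, omega_mode = "m2a"),
    global = list(K = 1, has_S = FALSE, has_MH = FALSE, omega_mode = "global")
  )
  vs$variant <- variant
  vs$M <- if (vs$has_S) 3L else 1L
  ## in the unconstrained fits the synonymous-rate weights can be profiled
  ## out by EM together with the omega weights (the likelihood is invariant
  ## to a joint rescaling of syn rates, omegas and the tree scale, so the
  ## mean-one normalization can be applied after the fit); the constrained
  ## fit caps the largest omega at 1 *on the mean-one scale*, which couples
  ## the weights to the rate matrices, so there they stay in the outer
  ## optimization
  vs$profile_q <- vs$has_S && !constrained
  vs
}

stick_inverse <- function(w) {
  k <- length(w)
  logits <- numeric(k - 1)
  rest <- 1
  for (i in seq_len(k - 1)) {
    logits[i] <- stats::qlogis(min(max(w[i] / rest, 1e-8), 1 - 1e-8))
    rest <- rest - w[i]
  }
  logits
}

stick_weights <- function(logits) {
  k <- length(logits) + 1
  w <- numeric(k)
  rest <- 1
  for (i in seq_along(logits)) {
    w[i] <- rest * stats::plogis(logits[i])
    rest <- rest - w[i]
  }
  w[k] <- rest
  w
}

n_theta <- function(vs) {
  2 + switch(vs$omega_mode,
             busted_alt = 3, busted_null = 2, m1a = 1, m2a = 2, global = 1) +
    (if (vs$has_S) (if (vs$profile_q) 2 else 4) else 0) +
    (if (vs$has_MH) 2 else 0)
}

decode_theta <- function(theta, vs) {
  kappa <- exp(theta[1])
  scale <- exp(theta[2])
  j <- 3
  omega <- switch(vs$omega_mode,
    busted_alt = {
      w3 <- exp(theta[j]); w2 <- w3 * stats::plogis(theta[j + 1])
      w1 <- w2 * stats::plogis(theta[j + 2]); j <- j + 3
      c(w1, w2, w3)
    },
    busted_null = {
      w2 <- stats::plogis(theta[j]); w1 <- w2 * stats::plogis(theta[j + 1])
      j <- j + 2
      c(w1, w2, 1)
    },
    m1a = { o <- stats::plogis(theta[j]); j <- j + 1; c(o, 1) },
    m2a = {
      o0 <- stats::plogis(theta[j]); o2 <- 1 + exp(theta[j + 1]); j <- j + 2
      c(o0, 1, o2)
    },
    global = { o <- exp(theta[j]); j <- j + 1; o }
  )
  if (vs$has_S) {
    s_raw <- c(exp(theta[j]), exp(theta[j + 1]), 1)
    if (vs$profile_q) {
      q <- NULL # profiled by EM; s_raw left unnormalized
      j <- j + 2
    } else {
      q <- stick_weights(theta[c(j + 2, j + 3)])
      s_raw <- s_raw / sum(q * s_raw)
      j <- j + 4
    }
  } else {
    s_raw <- 1; q <- 1
  }
  if (vs$has_MH) {
    delta <- exp(theta[j]); psi <- exp(theta[j + 1])
  } else {
    delta <- 0; psi <- 0
  }
  list(kappa = kappa, scale = scale, omega = omega,
       syn_rate = s_raw, q_syn = q, delta = delta, psi = psi)
}

## encode decoded (mean-one scale) parameters into the theta layout of a
## target variant spec; used for warm starts between nested fits
encode_params <- function(par, vs) {
  clamp01 <- function(x) min(max(x, 1e-6), 1 - 1e-6)
  th <- c(log(par$kappa), log(par$scale))
  om <- par$omega
  th <- c(th, switch(vs$omega_mode,
    busted_alt = c(log(max(om[3], 1e-6)),
                   stats::qlogis(clamp01(om[2] / om[3])),
                   stats::qlogis(clamp01(om[1] / max(om[2], 1e-8)))),
    busted_null = {
      w2 <- clamp01(min(om[2], 0.999))
      c(stats::qlogis(w2), stats::qlogis(clamp01(om[1] / w2)))
    },
    m1a = stats::qlogis(clamp01(om[1])),
    m2a = c(stats::qlogis(clamp01(om[1])), log(max(om[3] - 1, 1e-4))),
    global = log(max(om[1], 1e-6))
  ))
  if (vs$has_S) {
    s <- par$syn_rate
    th <- c(th, log(s[1] / s[3]), log(s[2] / s[3]))
    if (!vs$profile_q) th <- c(th, stick_inverse(par$q_syn))
  }
  if (vs$has_MH)
    th <- c(th, log(max(par$delta, 1e-5)), log(max(par$psi, 1e-5)))
  th
}

## box bounds for the encoded parameters keep the optimizer away from the
## numerically degenerate corners (e.g. killing a rate class by driving the
## tree scale to zero)
theta_bounds <- function(vs) {
  lo <- c(-3, -6)  # log kappa, log scale
  hi <- c(3, 4)
  om <- switch(vs$omega_mode,
    busted_alt = list(c(-7, -12, -12), c(5.5, 12, 12)),
    busted_null = list(c(-12, -12), c(12, 12)),
    m1a = list(-12, 12),
    m2a = list(c(-12, -9), c(12, 4)),
    global = list(-7, 3))
  lo <- c(lo, om[[1]]); hi <- c(hi, om[[2]])
  if (vs$has_S) {
    lo <- c(lo, -4, -4); hi <- c(hi, 4, 4)
    if (!vs$profile_q) { lo <- c(lo, -12, -12); hi <- c(hi, 12, 12) }
  }
  if (vs$has_MH) { lo <- c(lo, -11, -11); hi <- c(hi, 2.5, 2.5) }
  list(lower = lo, upper = hi)
}

default_start <- function(vs, kappa = 2, scale = 1, omega3 = 1.3) {
  th <- c(log(kappa), log(scale))
  th <- c(th, switch(vs$omega_mode,
    busted_alt = c(log(omega3), stats::qlogis(0.4), stats::qlogis(0.2)),
    busted_null = c(stats::qlogis(0.6), stats::qlogis(0.2)),
    m1a = stats::qlogis(0.2),
    m2a = c(stats::qlogis(0.2), log(0.5)),
    global = log(0.4)
  ))
  if (vs$has_S) {
    th <- c(th, log(0.7), log(1.2))
    if (!vs$profile_q) th <- c(th, 0, 0)
  }
  if (vs$has_MH) th <- c(th, log(0.05), log(0.05))
  th
}

## EM profile over the omega-class weights given per-pattern per-omega-class
## log-likelihoods (already collapsed over synonymous-rate classes).
profile_omega_weights <- function(llk, wpat, p0 = NULL,
                                  tol = 1e-8, maxiter = 500) {
  K <- ncol(llk)
  if (K == 1) return(list(p = 1, loglik = sum(wpat * llk[, 1])))
  mx <- apply(llk, 1, max)
  L <- exp(llk - mx)
  p <- if (is.null(p0) || length(p0) != K) rep(1 / K, K) else pmax(p0, 1e-8)
  p <- p / sum(p)
  last <- -Inf
  for (it in seq_len(maxiter)) {
    denom <- as.vector(L %*% p)
    ll <- sum(wpat * (log(denom) + mx))
    p <- as.vector(crossprod(L, wpat / denom)) * p / sum(wpat)
    p <- pmax(p, 0); p <- p / sum(p)
    if (is.finite(ll) && ll - last < tol && it > 2) { last <- ll; break }
    last <- ll
  }
  list(p = p, loglik = last)
}

## EM profile over product-form weights p (omega classes) x q (syn-rate
## classes), given per-pattern log-likelihoods for all K*M classes in
## m-fastest order.
profile_product_weights <- function(ll, wpat, K, M, p0 = NULL, q0 = NULL,
                                    tol = 1e-8, maxiter = 500) {
  mx <- apply(ll, 1, max)
  L <- exp(ll - mx)
  p <- if (is.null(p0) || length(p0) != K) rep(1 / K, K) else pmax(p0, 1e-8)
  q <- if (is.null(q0) || length(q0) != M) rep(1 / M, M) else pmax(q0, 1e-8)
  p <- p / sum(p); q <- q / sum(q)
  sumw <- sum(wpat)
  last <- -Inf
  for (it in seq_len(maxiter)) {
    W <- as.vector(t(outer(p, q))) # class order: m fastest within k
    denom <- as.vector(L %*% W)
    ll_tot <- sum(wpat * (log(denom) + mx))
    r_km <- as.vector(crossprod(L, wpat / denom)) * W # summed responsibilities
    rm_mat <- matrix(r_km, nrow = M) # rows m, cols k
    p <- pmax(colSums(rm_mat), 0); p <- p / sum(p)
    q <- pmax(rowSums(rm_mat), 0); q <- q / sum(q)
    if (is.finite(ll_tot) && ll_tot - last < tol && it > 2) {
      last <- ll_tot
      break
    }
    last <- ll_tot
  }
  list(p = p, q = q, loglik = last)
}

## Objective closure for one fit: returns negative profile log-likelihood.
## Per-class likelihood columns are cached on their defining parameters so
## that the forward-difference gradient only recomputes the classes an
## individual parameter actually touches.
make_objective <- function(prep, pat, pi, vs) {
  M <- vs$M
  K <- vs$K
  env <- new.env(parent = emptyenv())
  env$p_warm <- NULL
  env$q_warm <- NULL
  env$cache <- new.env(hash = TRUE, parent = emptyenv())
  class_column <- function(kappa, delta, psi, om, sm, scale) {
    key <- paste(signif(c(kappa, delta, psi, om, sm, scale), 14),
                 collapse = "|")
    hit <- env$cache[[key]]
    if (!is.null(hit)) return(hit)
    Q <- build_rate_matrix_raw(kappa, pi, delta, psi, om, sm)
    col <- .pruning_loglik(prep$edges, prep$blen * scale, pat$tipstate,
                           array(Q, c(61, 61, 1)), pi)[, 1]
    env$cache_n <- (env$cache_n %||% 0L) + 1L
    if (env$cache_n > 1000L) {
      env$cache <- new.env(hash = TRUE, parent = emptyenv())
      env$cache_n <- 0L
    }
    assign(key, col, envir = env$cache)
    col
  }
  fn <- function(theta) {
    par <- decode_theta(theta, vs)
    ll <- tryCatch({
      out <- matrix(0, length(pat$weights), K * M)
      for (k in seq_len(K)) {
        for (m in seq_len(M)) {
          out[, (k - 1) * M + m] <- class_column(
            par$kappa, par$delta, par$psi,
            par$omega[k], par$syn_rate[m], par$scale)
        }
      }
      out
    }, error = function(e) NULL)
    if (is.null(ll) || any(!is.finite(ll))) return(1e10)
    if (isTRUE(vs$profile_q)) {
      pr <- profile_product_weights(ll, pat$weights, K, M,
                                    env$p_warm, env$q_warm)
      env$q_warm <- pr$q
    } else if (M > 1) {
      lq <- log(pmax(par$q_syn, 1e-300))
      llk <- vapply(seq_len(K), function(k) {
        cols <- (k - 1) * M + seq_len(M)
        block <- sweep(ll[, cols, drop = FALSE], 2, lq, "+")
        mb <- apply(block, 1, max)
        mb + log(rowSums(exp(block - mb)))
      }, numeric(nrow(ll)))
      pr <- profile_omega_weights(llk, pat$weights, env$p_warm)
    } else {
      pr <- profile_omega_weights(ll, pat$weights, env$p_warm)
    }
    env$p_warm <- pr$p
    if (!is.finite(pr$loglik)) return(1e10)
    -pr$loglik
  }
  list(fn = fn, env = env)
}

## Forward-difference gradient reusing the last objective value when the
## optimizer evaluates fn and gr at the same point.
make_grad <- function(fn) {
  cache <- new.env(parent = emptyenv())
  wrapped <- function(x) {
    f <- fn(x)
    cache$x <- x; cache$f <- f
    f
  }
  grad <- function(x) {
    f0 <- if (!is.null(cache$x) && identical(cache$x, x)) cache$f else fn(x)
    vapply(seq_along(x), function(i) {
      h <- 1e-5 * max(1, abs(x[i]))
      xi <- x; xi[i] <- xi[i] + h
      (fn(xi) - f0) / h
    }, numeric(1))
  }
  list(fn = wrapped, gr = grad)
}

#' Fit a mixture codon model by maximum likelihood
#'
#' Maximizes the alignment log-likelihood over kappa, the omega classes and
#' their weights, the synonymous-rate classes and weights (variants `"S"`
#' and `"S_MH"`), the multi-hit rates delta and psi (variant `"S_MH"`) and a
#' single global tree-scale factor. Codon frequencies are fixed at the F3x4
#' empirical frequencies of the alignment. The constrained ("null") fit caps
#' the largest omega class at 1.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` gene tree with branch lengths.
#' @param variant One of `"base"` (omega mixture only), `"S"` (adds
#'   synonymous-rate variation), `"S_MH"` (adds multi-hit substitutions),
#'   `"m1a"`, `"m2a"` (PAML-style site models) or `"global"` (single omega).
#' @param constrained If `TRUE`, cap the largest omega class at 1 (the null
#'   hypothesis of the gene-wide test). Ignored for `m1a`/`m2a`/`global`.
#' @param n_restarts Number of deterministic optimization starts; jittered
#'   starts are derived from `seed`. The best fit is returned.
#' @param seed Integer seed controlling the multi-start jitter.
#' @param init Optional starting values: a fit result or encoded theta used
#'   as the first start (warm start).
#' @param maxit Maximum BFGS iterations per start.
#' @return A `codon_fit` object: `log_likelihood`, `n_free_params`, `AIC`,
#'   `params` (kappa, omega, p_omega, syn_rate, q_syn, delta, psi, scale),
#'   `converged`, `n_restarts_used`, plus the encoded optimum `theta`.
#' @export
fit_model <- function(aln, tree, variant = c("base", "S", "S_MH", "m1a", "m2a", "global"),
                      constrained = FALSE, n_restarts = 3, seed = 1,
                      init = NULL, maxit = 80) {
  variant <- match.arg(variant)
  vs <- variant_spec(variant, constrained)
  prep <- prepare_tree(tree, aln)
  pat <- site_patterns(aln, prep$tip_order)
  pi <- f3x4_frequencies(aln)
  obj <- make_objective(prep, pat, pi, vs)

  ## first start: warm init when supplied, otherwise the default; further
  ## restarts are deterministic jitters derived from the seed
  starts <- list()
  if (!is.null(init)) {
    th0 <- if (is.list(init)) init$theta else init
    if (length(th0) == n_theta(vs)) starts[[1]] <- th0
  }
  if (length(starts) == 0) starts[[1]] <- default_start(vs)
  n_more <- max(0, n_restarts - 1)
  if (n_more > 0) {
    if (!is.null(init)) {
      starts[[2]] <- default_start(vs)
      n_more <- n_more - 1
    }
    if (n_more > 0) {
      jitter <- withr::with_seed(seed,
        replicate(n_more, stats::rnorm(n_theta(vs), 0, 0.7), simplify = FALSE))
      starts <- c(starts, lapply(jitter, function(z) default_start(vs) + z))
    }
  }

  bounds <- theta_bounds(vs)
  clip <- function(th) pmin(pmax(th, bounds$lower + 1e-6), bounds$upper - 1e-6)
  best <- NULL
  used <- 0
  for (th0 in starts) {
    used <- used + 1
    g <- make_grad(obj$fn)
    res <- tryCatch(
      stats::optim(clip(th0), g$fn, g$gr, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = maxit, factr = 5e8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(log_likelihood = NA_real_, converged = FALSE,
                          variant = variant, constrained = constrained,
                          n_restarts_used = used),
                     class = "codon_fit"))
  }

  par <- decode_theta(best$par, vs)
  ## recover the profiled weights at the optimum
  obj$fn(best$par)
  p_hat <- obj$env$p_warm
  if (is.null(p_hat)) p_hat <- rep(1 / vs$K, vs$K)
  q_hat <- if (isTRUE(vs$profile_q)) obj$env$q_warm else par$q_syn
  syn <- par$syn_rate
  omega <- par$omega
  scale <- par$scale
  if (isTRUE(vs$profile_q)) {
    ## apply the mean-one normalization: (s, omega, scale) -> (s/c, omega/c,
    ## scale*c) leaves the likelihood unchanged
    cc <- sum(q_hat * syn)
    syn <- syn / cc
    omega <- omega / cc
    scale <- scale * cc
  }
  k_free <- n_theta(vs) + (vs$K - 1) +
    (if (isTRUE(vs$profile_q)) vs$M - 1 else 0)
  ll <- -best$value
  structure(list(
    log_likelihood = ll,
    n_free_params = k_free,
    AIC = 2 * k_free - 2 * ll,
    params = list(kappa = par$kappa, pi = pi, omega = omega,
                  p_omega = p_hat, syn_rate = syn,
                  q_syn = q_hat, delta = par$delta, psi = par$psi,
                  scale = scale),
    converged = best$convergence == 0,
    n_restarts_used = used,
    variant = variant, constrained = constrained,
    theta = best$par
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit (", x$variant,
      if (isTRUE(x$constrained)) ", constrained" else "", ")\n", sep = "")
  cat("  logL:", format(x$log_likelihood, digits = 8),
      " AIC:", format(x$AIC, digits = 8),
      " converged:", x$converged, "\n")
  if (!is.null(x$params)) {
    cat("  omega:", paste(format(x$params$omega, digits = 3), collapse = ", "),
        " weights:", paste(format(x$params$p_omega, digits = 3), collapse = ", "), "\n")
  }
  invisible(x)
}

## Embed a constrained solution as a starting point for the unconstrained
## parameterization (and vice versa) so nesting holds numerically.  Both
## work on the decoded, mean-one-scale estimates.
embed_null_in_alt <- function(fit_null) {
  par <- fit_null$params
  par$omega[3] <- 1 + 1e-4
  encode_params(par, variant_spec(fit_null$variant, constrained = FALSE))
}

embed_alt_in_null <- function(fit_alt) {
  par <- fit_alt$params
  if (length(par$syn_rate) == 1 && fit_alt$variant != "base") return(NULL)
  encode_params(par, variant_spec(fit_alt$variant, constrained = TRUE))
}

#' Gene-wide likelihood-ratio test for episodic positive selection
#'
#' Fits the unconstrained model (largest omega class free) and the
#' constrained null (largest omega class capped at 1) for one model variant
#' and compares them by a likelihood-ratio test with p-values from the
#' chi-squared distribution with 2 degrees of freedom (conservative at the
#' boundary).
#'
#' @inheritParams fit_model
#' @param variant `"base"`, `"S"` or `"S_MH"`.
#' @param null_maxit Iteration cap for the constrained fit (it starts from
#'   the capped unconstrained optimum, so it typically needs fewer steps).
#' @return List with elements `LRT`, `p`, `fit_alt`, `fit_null`.
#' @export
busted_like_test <- function(aln, tree, variant = c("base", "S", "S_MH"),
                             n_restarts = 1, seed = 1, init = NULL,
                             maxit = 80, null_maxit = maxit) {
  variant <- match.arg(variant)
  fit_alt <- fit_model(aln, tree, variant, constrained = FALSE,
                       n_restarts = n_restarts, seed = seed, init = init,
                       maxit = maxit)
  fit_null <- fit_model(aln, tree, variant, constrained = TRUE,
                        n_restarts = 1, seed = seed,
                        init = if (!is.null(fit_alt$theta)) embed_alt_in_null(fit_alt) else NULL,
                        maxit = null_maxit)
  ## guarantee nesting numerically: the null optimum is feasible under the
  ## alternative, so refit the alternative from it if needed
  if (!is.na(fit_null$log_likelihood) && !is.na(fit_alt$log_likelihood) &&
      fit_null$log_likelihood > fit_alt$log_likelihood + 1e-3) {
    refit <- fit_model(aln, tree, variant, constrained = FALSE,
                       n_restarts = 1, seed = seed,
                       init = embed_null_in_alt(fit_null), maxit = maxit)
    if (!is.na(refit$log_likelihood) &&
        refit$log_likelihood > fit_alt$log_likelihood) fit_alt <- refit
  }
  if (is.na(fit_alt$log_likelihood) || is.na(fit_null$log_likelihood)) {
    return(list(LRT = NA_real_, p = NA_real_, fit_alt = fit_alt,
                fit_null = fit_null))
  }
  LRT <- max(0, 2 * (fit_alt$log_likelihood - fit_null$log_likelihood))
  list(LRT = LRT, p = stats::pchisq(LRT, df = 2, lower.tail = FALSE),
       fit_alt = fit_alt, fit_null = fit_null)
}

#' M1a versus M2a site-model test
#'
#' Nested likelihood-ratio test comparing the neutral site model M1a (two
#' omega classes: 0 < omega0 < 1 and omega1 = 1, free weights) against the
#' positive-selection model M2a (adds omega2 > 1 with a free weight). No
#' synonymous-rate variation or multi-hit substitutions. p-values from
#' chi-squared with 2 df.
#'
#' @inheritParams fit_model
#' @return List with `LRT`, `p`, `fit_m1a`, `fit_m2a`.
#' @export
m1a_m2a_test <- function(aln, tree, n_restarts = 1, seed = 1, maxit = 80) {
  fit1 <- fit_model(aln, tree, "m1a", n_restarts = n_restarts, seed = seed,
                    maxit = maxit)
  init2 <- if (!is.null(fit1$theta))
    c(fit1$theta, log(0.5)) else NULL
  fit2 <- fit_model(aln, tree, "m2a", n_restarts = n_restarts, seed = seed,
                    init = init2, maxit = maxit)
  if (is.na(fit1$log_likelihood) || is.na(fit2$log_likelihood)) {
    return(list(LRT = NA_real_, p = NA_real_, fit_m1a = fit1, fit_m2a = fit2))
  }
  LRT <- max(0, 2 * (fit2$log_likelihood - fit1$log_likelihood))
  list(LRT = LRT, p = stats::pchisq(LRT, df = 2, lower.tail = FALSE),
       fit_m1a = fit1, fit_m2a = fit2)
}

#' Single-omega dN/dS estimate for a gene
#'
#' Maximum-likelihood fit of the one-class codon model (no omega mixture, no
#' synonymous-rate variation, no multi-hit substitutions); the fitted omega
#' is the gene's whole-CDS dN/dS.
#'
#' @inheritParams fit_model
#' @return List with `omega`, `kappa`, `scale`, `log_likelihood`,
#'   `converged`, `identifiable`.
#' @export
fit_global_omega <- function(aln, tree, n_restarts = 1, seed = 1, maxit = 60) {
  ## zero sequence variation makes omega unidentifiable
  idx <- aln$codon_idx
  varying <- apply(idx, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  if (!any(varying)) {
    return(list(omega = NA_real_, kappa = NA_real_, scale = NA_real_,
                log_likelihood = NA_real_, converged = FALSE,
                identifiable = FALSE))
  }
  fit <- fit_model(aln, tree, "global", n_restarts = n_restarts, seed = seed,
                   maxit = maxit)
  list(omega = unname(fit$params$omega), kappa = fit$params$kappa,
       scale = fit$params$scale, log_likelihood = fit$log_likelihood,
       converged = fit$converged, identifiable = TRUE, fit = fit)
}

#' Model-averaged p-value across test variants
#'
#' Akaike-weight averaging over the alternative-model fits of the converged
#' variants: `w_i = exp(-(AIC_i - min AIC)/2) / sum(...)`, and the averaged
#' p-value is `sum(w_i * p_i)`, favoring the best-fitting model while
#' penalizing poor fits.
#'
#' @param aic Numeric vector of alternative-fit AICs (one per variant).
#' @param p Numeric vector of per-variant LRT p-values.
#' @param converged Logical vector; non-converged variants are excluded.
#' @return List with `p` (model-averaged p-value, `NA` if no variant
#'   converged) and `weights` (Akaike weights, `NA` for excluded variants).
#' @export
model_averaged_p <- function(aic, p, converged = rep(TRUE, length(aic))) {
  stopifnot(length(aic) == length(p), length(converged) == length(aic))
  ok <- converged & is.finite(aic) & is.finite(p)
  w <- rep(NA_real_, length(aic))
  if (!any(ok)) return(list(p = NA_real_, weights = w))
  d <- aic[ok] - min(aic[ok])
  wi <- exp(-d / 2)
  wi <- wi / sum(wi)
  w[ok] <- wi
  list(p = sum(wi * p[ok]), weights = w)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up q-values with monotonicity enforcement, plus positive
#' flags at a q-value threshold.
#'
#' @param p Vector of p-values (`NA` allowed, propagated).
#' @param q_threshold Significance threshold on q (default 0.2).
#' @return List with `q` (q-values) and `flag` (`q < q_threshold`).
#' @export
bh_fdr <- function(p, q_threshold = 0.2) {
  if (length(p) == 0) return(list(q = numeric(0), flag = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, flag = !is.na(q) & q < q_threshold)
}

#' Run the full per-gene selection-test battery
#'
#' Fits the three gene-wide test variants (base, +S, +S+MH) with warm-start
#' chaining between variants, the single-omega dN/dS estimate, and
#' optionally the M1a-vs-M2a test; returns a one-row data frame suitable for
#' row-binding across genes.
#'
#' @inheritParams fit_model
#' @param gene_id Identifier copied into the result row.
#' @param variants Character vector of gene-wide test variants to run.
#' @param include_paml Also run the M1a-vs-M2a test (default `TRUE`).
#' @param include_global Also fit the single-omega dN/dS (default `TRUE`).
#' @param maxit Maximum optimizer iterations per fit.
#' @param null_maxit Iteration cap for the constrained fits.
#' @return One-row `data.frame`: per-variant log-likelihoods, LRT statistic
#'   and p-value; Akaike weights; `model_averaged_p`; `paml_p`;
#'   `global_omega`; convergence flags.
#' @export
gene_selection_tests <- function(aln, tree, gene_id = "gene",
                                 variants = c("base", "S", "S_MH"),
                                 include_paml = TRUE, include_global = TRUE,
                                 n_restarts = 1, seed = 1, maxit = 80,
                                 null_maxit = maxit) {
  variants <- match.arg(variants, c("base", "S", "S_MH"), several.ok = TRUE)
  glob <- if (include_global)
    fit_global_omega(aln, tree, seed = seed, maxit = maxit)
  else list(omega = NA_real_)
  out <- list(gene_id = gene_id, global_omega = glob$omega)

  tests <- list()
  prev_alt <- NULL
  for (v in variants) {
    init <- if (!is.null(prev_alt) && !is.null(prev_alt$theta)) {
      th <- prev_alt$theta
      if (v == "S" && prev_alt$variant == "base") c(th, log(0.7), log(1.2))
      else if (v == "S_MH" && prev_alt$variant == "S") c(th, log(0.05), log(0.05))
      else if (v == "S_MH" && prev_alt$variant == "base")
        c(th, log(0.7), log(1.2), log(0.05), log(0.05))
      else NULL
    } else NULL
    tst <- busted_like_test(aln, tree, v, n_restarts = n_restarts,
                            seed = seed, init = init, maxit = maxit,
                            null_maxit = null_maxit)
    tests[[v]] <- tst
    if (!is.null(tst$fit_alt$theta)) prev_alt <- tst$fit_alt
    out[[paste0("logL_null_", v)]] <- tst$fit_null$log_likelihood
    out[[paste0("logL_alt_", v)]] <- tst$fit_alt$log_likelihood
    out[[paste0("LRT_", v)]] <- tst$LRT
    out[[paste0("p_", v)]] <- tst$p
    out[[paste0("converged_", v)]] <-
      isTRUE(tst$fit_alt$converged) && isTRUE(tst$fit_null$converged)
  }

  aic <- vapply(tests, function(t) {
    if (is.null(t$fit_alt$AIC)) NA_real_ else t$fit_alt$AIC
  }, numeric(1))
  pv <- vapply(tests, function(t) t$p, numeric(1))
  conv <- vapply(tests, function(t) !is.na(t$p), logical(1))
  ma <- model_averaged_p(aic, pv, conv)
  out$model_averaged_p <- ma$p
  for (i in seq_along(variants))
    out[[paste0("akaike_w_", variants[i])]] <- ma$weights[i]

  if (include_paml) {
    paml <- m1a_m2a_test(aln, tree, n_restarts = n_restarts, seed = seed,
                         maxit = maxit)
    out$paml_LRT <- paml$LRT
    out$paml_p <- paml$p
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
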