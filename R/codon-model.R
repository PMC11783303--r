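#' Mixture codon substitution model
#'
#' Container for the codon substitution model used by the selection tests and
#' by the alignment simulator: a transition/transversion ratio `kappa`,
#' sense-codon frequencies `pi` (typically F3x4), a discrete mixture of
#' dN/dS classes (`omega`, `p_omega`), a discrete mean-one mixture of
#' synonymous rate classes (`syn_rate`, `q_syn`), and instantaneous
#' double/triple-nucleotide ("multi-hit") substitution rates `delta`/`psi`.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param pi Numeric vector of 61 sense-codon frequencies summing to 1, in
#'   the order of [sense_codons()].
#' @param omega Numeric vector of dN/dS classes, non-negative, ascending.
#' @param p_omega Mixture weights for `omega` (simplex).
#' @param syn_rate Synonymous rate classes, non-negative. Must satisfy
#'   `sum(q_syn * syn_rate) == 1` (mean-one identifiability constraint).
#' @param q_syn Mixture weights for `syn_rate` (simplex).
#' @param delta Instantaneous rate multiplier for codon changes at two
#'   positions, >= 0.
#' @param psi Rate multiplier for codon changes at three positions, >= 0.
#' @return An object of class `mixture_codon_model`.
#' @export
mixture_codon_model <- function(kappa = 2, pi = rep(1 / 61, 61),
                                omega = c(0.1, 0.8, 1.5),
                                p_omega = c(0.6, 0.3, 0.1),
                                syn_rate = 1, q_syn = 1,
                                delta = 0, psi = 0) {
  m <- structure(
    list(kappa = kappa, pi = pi, omega = omega, p_omega = p_omega,
         syn_rate = syn_rate, q_syn = q_syn, delta = delta, psi = psi),
    class = "mixture_codon_model"
  )
  validate_codon_model(m)
  m
}

validate_codon_model <- function(m) {
  stopifnot(inherits(m, "mixture_codon_model"))
  with(m, {
    if (!(kappa > 0)) stop("kappa must be positive")
    if (length(pi) != 61 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
      stop("pi must be 61 non-negative frequencies summing to 1")
    if (any(omega < 0)) stop("omega classes must be non-negative")
    if (is.unsorted(omega)) stop("omega classes must be ascending")
    if (length(p_omega) != length(omega) || any(p_omega < 0) ||
        abs(sum(p_omega) - 1) > 1e-8)
      stop("p_omega must be a simplex matching omega")
    if (length(q_syn) != length(syn_rate) || any(q_syn < 0) ||
        abs(sum(q_syn) - 1) > 1e-8)
      stop("q_syn must be a simplex matching syn_rate")
    if (any(syn_rate < 0)) stop("synonymous rate classes must be non-negative")
    if (abs(sum(q_syn * syn_rate) - 1) > 1e-9)
      stop("synonymous rate classes must have mean 1: sum(q_syn * syn_rate) == 1")
    if (delta < 0 || psi < 0) stop("delta and psi must be non-negative")
  })
  invisible(m)
}

#' @export
print.mixture_codon_model <- function(x, ...) {
  cat("Mixture codon model\n")
  cat("  kappa:", format(x$kappa, digits = 4), "\n")
  cat("  omega:", paste(format(x$omega, digits = 3), collapse = ", "),
      " weights:", paste(format(x$p_omega, digits = 3), collapse = ", "), "\n")
  cat("  syn rates:", paste(format(x$syn_rate, digits = 3), collapse = ", "),
      " weights:", paste(format(x$q_syn, digits = 3), collapse = ", "), "\n")
  cat("  delta:", format(x$delta, digits = 3),
      " psi:", format(x$psi, digits = 3), "\n")
  invisible(x)
}

#' F3x4 codon frequencies from an alignment
#'
#' Sense-codon frequencies constructed as products of the empirical
#' nucleotide frequencies at the three codon positions, renormalized over the
#' 61 sense codons.
#'
#' @param aln A [codon_alignment()].
#' @return Numeric vector of 61 frequencies.
#' @export
f3x4_frequencies <- function(aln) {
  idx <- aln$codon_idx
  obs <- SENSE_CODONS[idx[!is.na(idx)]]
  if (length(obs) == 0) stop("alignment contains no unambiguous codons")
  mat <- do.call(rbind, strsplit(obs, ""))
  posfreq <- lapply(1:3, function(p) {
    f <- table(factor(mat[, p], levels = NUC))
    ## guard against a position where some nucleotide is absent
    f <- (f + 0.5) / sum(f + 0.5 * 4)
    as.numeric(f)
  })
  cmat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  pi <- posfreq[[1]][match(cmat[, 1], NUC)] *
    posfreq[[2]][match(cmat[, 2], NUC)] *
    posfreq[[3]][match(cmat[, 3], NUC)]
  pi / sum(pi)
}

## Off-diagonal "structural" factor matrix: kappa on single-nucleotide
## transitions, delta on double hits, psi on triple hits.
structural_factor <- function(kappa, delta, psi) {
  tb <- codon_pair_tables()
  f <- matrix(0, 61, 61)
  f[tb$ndiff == 1] <- 1
  f[tb$ndiff == 1 & tb$ts] <- kappa
  f[tb$ndiff == 2] <- delta
  f[tb$ndiff == 3] <- psi
  f
}

#' Build the generator matrix for one (omega, synonymous-rate) class
#'
#' Constructs the 61x61 instantaneous rate matrix for a mixture class. For
#' codons i != j differing at d positions the rate is
#' `pi_j * (kappa if transition) * (syn_rate if synonymous else omega)` for
#' d = 1, and `delta * pi_j * (...)` / `psi * pi_j * (...)` for d = 2 / 3.
#' The matrix is scaled by the normalization constant of the base model
#' (omega = 1, syn_rate = 1, current delta and psi) so that one unit of
#' branch length corresponds to one expected substitution per codon under
#' the base model.
#'
#' @param model A [mixture_codon_model()] supplying `kappa`, `pi`, `delta`,
#'   `psi`.
#' @param omega dN/dS for this class.
#' @param syn_rate Synonymous rate for this class.
#' @return 61x61 generator matrix (rows sum to zero).
#' @export
build_rate_matrix <- function(model, omega, syn_rate) {
  validate_codon_model(model)
  build_rate_matrix_raw(model$kappa, model$pi, model$delta, model$psi,
                        omega, syn_rate)
}

## numeric 61x61 masks for the rate-matrix arithmetic, built once
rate_masks <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tb <- codon_pair_tables()
    cache <<- list(
      ts1 = (tb$ndiff == 1 & tb$ts) + 0,
      tv1 = (tb$ndiff == 1 & !tb$ts) + 0,
      d2 = (tb$ndiff == 2) + 0,
      d3 = (tb$ndiff == 3) + 0,
      syn = (tb$syn & tb$ndiff > 0) + 0,
      nonsyn = (!tb$syn & tb$ndiff > 0) + 0
    )
    cache
  }
})

## unvalidated fast path used inside the likelihood optimization
build_rate_matrix_raw <- function(kappa, pi, delta, psi, omega, syn_rate) {
  mk <- rate_masks()
  f <- mk$tv1 + kappa * mk$ts1
  if (delta > 0) f <- f + delta * mk$d2
  if (psi > 0) f <- f + psi * mk$d3
  base <- f * rep(pi, each = 61) # base[i, j] = f[i, j] * pi[j]
  C <- sum(pi * rowSums(base)) # base-model (omega = s = 1) rate
  Q <- base * (syn_rate * mk$syn + omega * mk$nonsyn)
  diag(Q) <- -rowSums(Q)
  Q / C
}

## Expected substitution rate per codon under the base model (omega = 1,
## syn rate = 1, current delta/psi), used as the branch-length unit.
rate_normalization <- function(model) {
  f <- structural_factor(model$kappa, model$delta, model$psi)
  base <- f * rep(model$pi, each = 61)
  diag(base) <- 0
  sum(model$pi * rowSums(base))
}

## All class generator matrices of a mixture model as a 61 x 61 x (K*M)
## array, classes enumerated omega-major: class index = (k-1)*M + m.
class_rate_matrices <- function(model) {
  K <- length(model$omega)
  M <- length(model$syn_rate)
  out <- array(0, c(61, 61, K * M))
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      out[, , (k - 1) * M + m] <-
        build_rate_matrix_raw(model$kappa, model$pi, model$delta, model$psi,
                              model$omega[k], model$syn_rate[m])
    }
  }
  out
}

## Joint class weights matching class_rate_matrices() ordering.
class_weights <- function(model) {
  as.vector(t(outer(model$p_omega, model$q_syn)))
}
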