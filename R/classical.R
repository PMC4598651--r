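#' Classical Markov-chain machinery for the codon and nucleotide channels
#'
#' `stochastic_from_amplitudes()` maps an amplitude matrix to the classical
#' transition matrix of squared magnitudes `p_mn = |a_mn|^2`; for a
#' row-normalized amplitude matrix the result is row-stochastic exactly.
#' For composed (un-normalized) amplitude matrices use
#' [hybrid_stochastic()], which applies the explicit per-row normalization
#' of the hybrid model.
#'
#' @param A Amplitude matrix with unit squared row norms (tolerance `tol`).
#' @param tol Row-sum tolerance.
#' @return A row-stochastic matrix (same dimnames).
#' @export
stochastic_from_amplitudes <- function(A, tol = 1e-8) {
  P <- Mod(unclass(A))^2
  attr(P, "stages") <- NULL
  dev <- max(abs(rowSums(P) - 1))
  if (dev > tol) {
    stop("rows of |A|^2 are not stochastic (max deviation ", format(dev),
         "); use hybrid_stochastic() for composed amplitude matrices",
         call. = FALSE)
  }
  P
}

#' @rdname stochastic_from_amplitudes
#' @details `hybrid_stochastic()` implements the hand-off from a composed
#'   quantum part to classical stages: `p_ij = |a_ij|^2 / sum_n |a_in|^2`,
#'   row-stochastic by construction.
#' @export
hybrid_stochastic <- function(A) {
  P <- Mod(unclass(A))^2
  attr(P, "stages") <- NULL
  P / rowSums(P)
}

#' k-step transition matrix of a Markov chain
#'
#' `P^k` by repeated squaring; `k = 0` gives the identity. Probabilities
#' (not amplitudes) multiply along paths and sum over paths, the classical
#' counterpart of [amp_power()].
#'
#' @param P Row-stochastic matrix.
#' @param k Nonnegative integer number of steps.
#' @return The k-step transition matrix.
#' @export
markov_power <- function(P, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k == round(k), k >= 0)
  R <- diag(nrow(P))
  dimnames(R) <- dimnames(P)
  M <- P
  kk <- as.integer(k)
  while (kk > 0) {
    if (kk %% 2L == 1L) R <- R %*% M
    M <- M %*% M
    kk <- kk %/% 2L
  }
  R
}

#' Stationary distribution of a regular Markov chain
#'
#' Solves `pi = pi P`, `sum(pi) = 1` via the left eigenvector at eigenvalue
#' 1 and verifies that the chain is regular (a unique eigenvalue on the
#' unit circle, so `P^k` converges to identical rows). Reducible or
#' periodic chains raise an error.
#'
#' @param P Row-stochastic matrix.
#' @param tol Numerical tolerance for the spectral-gap and verification
#'   checks.
#' @return Named numeric vector `pi`.
#' @export
stationary_distribution <- function(P, tol = 1e-9) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(rowSums(P) - 1)) > 1e-8) {
    stop("'P' is not row-stochastic", call. = FALSE)
  }
  ev <- eigen(t(P))
  mods <- Mod(ev$values)
  on_circle <- sum(mods > 1 - 1e-9)
  if (on_circle != 1L) {
    stop("chain is not regular (", on_circle,
         " eigenvalues on the unit circle); no convergent stationary ",
         "distribution", call. = FALSE)
  }
  v <- Re(ev$vectors[, which.max(mods)])
  pi <- v / sum(v)
  if (min(pi) < -tol) {
    stop("stationary eigenvector has negative mass; chain not regular",
         call. = FALSE)
  }
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  # verify lim P^k rows -> pi
  Pk <- markov_power(P, 2L^16)
  if (max(abs(sweep(Pk, 2, pi))) > sqrt(tol)) {
    stop("P^k did not converge to the stationary rows", call. = FALSE)
  }
  stats::setNames(pi, rownames(P))
}

#' Nucleotide-level reference processes: 4-ary symmetric and Kimura
#'
#' `msc_matrix()` is the 4-ary symmetric channel over the DNA bases
#' T, C, A, G: diagonal `1 - Ps`, every substitution `Ps/3`.
#' `kimura_matrix()` generalizes it with the two-parameter substitution
#' model: the favored partner base receives `(1 - 2*gamma/3) * Ps` and the
#' other two `gamma * Ps / 3` each, so rows always sum to 1;
#' `gamma = 1` recovers the symmetric channel. The `"canonical"` layout
#' gives the enhanced rate to the transition partner (T<->C within
#' pyrimidines, A<->G within purines); the `"as-printed"` layout instead
#' pairs T<->G and C<->A. Per-step capacity is identical between layouts
#' (rows are permutations of one another) but multi-step powers differ.
#'
#' @param Ps Symbol (nucleotide) error probability in `[0, 1]`. Powers of
#'   the matrix converge to the uniform chain only for `Ps < 3/4`; larger
#'   values are accepted with a warning.
#' @return A 4 x 4 row-stochastic matrix with dimnames T, C, A, G.
#' @export
msc_matrix <- function(Ps) {
  stopifnot(is.numeric(Ps), length(Ps) == 1L)
  if (Ps < 0 || Ps > 1) stop("'Ps' must be in [0, 1]", call. = FALSE)
  if (Ps >= 3 / 4) {
    warning("Ps >= 3/4: matrix powers do not converge to the uniform chain")
  }
  b <- dna_bases()
  M <- matrix(Ps / 3, 4, 4, dimnames = list(b, b))
  diag(M) <- 1 - Ps
  M
}

#' @rdname msc_matrix
#' @param gamma Kimura parameter in `[0, 3/2]`; typical empirical values
#'   fall between 0.07 and 0.79.
#' @param layout `"canonical"` (transition partner favored, following the
#'   purine/pyrimidine classification) or `"as-printed"` (T<->G, C<->A
#'   pairing).
#' @export
kimura_matrix <- function(Ps, gamma, layout = c("canonical", "as-printed")) {
  layout <- match.arg(layout)
  stopifnot(is.numeric(Ps), length(Ps) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (Ps < 0 || Ps > 1) stop("'Ps' must be in [0, 1]", call. = FALSE)
  if (gamma < 0 || gamma > 3 / 2) {
    stop("'gamma' must be in [0, 3/2]", call. = FALSE)
  }
  b <- dna_bases()
  partner <- if (layout == "canonical") {
    c(T = "C", C = "T", A = "G", G = "A")
  } else {
    c(T = "G", C = "A", A = "C", G = "T")
  }
  M <- matrix(gamma * Ps / 3, 4, 4, dimnames = list(b, b))
  diag(M) <- 1 - Ps
  for (x in b) M[x, partner[[x]]] <- (1 - 2 * gamma / 3) * Ps
  M
}

#' @rdname msc_matrix
#' @export
dna_bases <- function() c("T", "C", "A", "G")

#' Effective symbol error probability of the n-step symmetric chain
#'
#' The n-th power of the 4-ary symmetric matrix is again 4-ary symmetric
#' with error probability
#' `Ps(n) = (3/4) * (1 - (1 - 4 Ps / 3)^n)` (eigenvalue closed form), so a
#' generation sweep of the symmetric chain is a single-step sweep at the
#' effective error.
#'
#' @inheritParams msc_matrix
#' @param n Number of steps/generations.
#' @return Effective symbol error probability.
#' @export
msc_effective_error <- function(Ps, n) {
  (3 / 4) * (1 - (1 - 4 * Ps / 3)^n)
}
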