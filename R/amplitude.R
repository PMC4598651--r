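#' Single-stage probability-amplitude transition matrix
#'
#' Builds the 64 x 64 matrix of transition probability amplitudes for one
#' stage of the codon channel under the single-error-per-codon truncation:
#' the self-transition amplitude is `sqrt(1 - 3p)` and each of the nine
#' single-base neighbors receives amplitude `sqrt(p/3)`, where `p` is the
#' per-base error probability (three bases contribute `3p` in total). Rows
#' then satisfy the Kraus normalization `sum(|a|^2) = 1` exactly.
#'
#' Amplitudes are real and nonnegative by default -- the minimal phase
#' assumption, giving maximal constructive interference between
#' indistinguishable paths. A phase matrix can be supplied to explore other
#' conventions; squared magnitudes (and hence the induced classical chain)
#' are unaffected by it.
#'
#' @param p Single-base error probability, `0 <= p < 1/3`. At `p = 1/3` and
#'   beyond, row normalization is impossible under the single-error
#'   truncation.
#' @param phases Optional 64 x 64 matrix of phases in radians; entry
#'   `[m, n]` multiplies amplitude `a_mn` by `exp(1i * phases[m, n])`.
#' @return An `amplitude_matrix`: a (possibly complex) matrix with codon
#'   dimnames and a `stages` attribute of 1.
#' @examples
#' A <- amplitude_matrix(0.003)
#' A["UUU", "UUU"]^2 # 0.991
#' @export
amplitude_matrix <- function(p, phases = NULL) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p < 0 || p >= 1 / 3) {
    stop("'p' must lie in [0, 1/3): got ", format(p), call. = FALSE)
  }
  A <- sqrt(1 - 3 * p) * diag(64) + sqrt(p / 3) * neighbor_matrix()
  dimnames(A) <- list(codon_alphabet(), codon_alphabet())
  if (!is.null(phases)) {
    stopifnot(is.matrix(phases), all(dim(phases) == c(64, 64)))
    A <- A * exp(1i * phases)
  }
  new_amplitude_matrix(A, stages = 1L)
}

#' Construct an amplitude matrix from an arbitrary square matrix
#'
#' Used for toy state spaces (2-4 states) in oracles and for user-supplied
#' stage matrices. Checks the Kraus row normalization `sum(|a_mn|^2) = 1`
#' unless `check = FALSE`.
#'
#' @param A Square numeric or complex matrix of amplitudes, `A[m, n]` the
#'   amplitude for the transition from state `m` to state `n`.
#' @param stages Number of stages the matrix represents.
#' @param check Verify row normalization (tolerance `tol`)?
#' @param tol Tolerance for the row-norm check.
#' @return An `amplitude_matrix`.
#' @export
as_amplitude_matrix <- function(A, stages = 1L, check = TRUE, tol = 1e-8) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (check) {
    dev <- max(abs(amp_row_norms(A) - 1))
    if (dev > tol) {
      stop("rows are not amplitude-normalized (max |.|^2 deviation ",
           format(dev), ")", call. = FALSE)
    }
  }
  new_amplitude_matrix(A, stages = as.integer(stages))
}

new_amplitude_matrix <- function(A, stages) {
  structure(A, stages = as.integer(stages),
            class = c("amplitude_matrix", class(unclass(A))))
}

#' @export
print.amplitude_matrix <- function(x, ...) {
  cat(sprintf("<amplitude_matrix: %d states, %d stage(s)>\n",
              nrow(x), amp_stages(x)))
  cat(sprintf("  max row |.|^2 deviation from 1: %.3g\n",
              max(abs(amp_row_norms(x) - 1))))
  invisible(x)
}

#' @rdname amp_compose
#' @export
amp_stages <- function(A) {
  s <- attr(A, "stages")
  if (is.null(s)) 1L else s
}

#' Squared row norms of an amplitude matrix
#'
#' `sum_n |a_mn|^2` per row. Equal to 1 for a single stage; for composed
#' stages it grows above 1 (path interference makes the literal operator
#' sum trace increasing), uniformly across rows for the codon channel.
#'
#' @param A Amplitude matrix.
#' @return Numeric vector of squared row 2-norms.
#' @export
amp_row_norms <- function(A) rowSums(Mod(A)^2)

#' Compose amplitude transition matrices over stages
#'
#' Sequential stages compose by ordinary (complex) matrix multiplication:
#' amplitudes multiply along a path and sum over indistinguishable paths, so
#' the k-stage amplitude from `m` to `n` is `sum_l a_ml^(k-1) a_ln`. The
#' composed family satisfies the amplitude Chapman-Kolmogorov identity
#' `A^(k) = A^(k-r) A^(r)`. This differs from the classical chain, which
#' composes squared magnitudes; the two-state worked case is the Malus-law
#' fixture `(cos(phi), sin(phi))` then `(cos(theta), sin(theta))` giving
#' total probability `cos^2(phi - theta)` rather than the classical
#' `cos^2(phi) cos^2(theta) + sin^2(phi) sin^2(theta)`.
#'
#' @param A,B Amplitude matrices (stage counts add).
#' @param k Number of stages, `k >= 1`.
#' @return An `amplitude_matrix` for the composed stages.
#' @export
amp_compose <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  new_amplitude_matrix(unclass(A) %*% unclass(B),
                       stages = amp_stages(A) + amp_stages(B))
}

#' @rdname amp_compose
#' @export
amp_power <- function(A, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k == round(k))
  if (k < 1) stop("'k' must be a positive integer", call. = FALSE)
  M <- unclass(A)
  R <- diag(nrow(M))
  dimnames(R) <- dimnames(M)
  kk <- as.integer(k)
  while (kk > 0) {            # repeated squaring
    if (kk %% 2L == 1L) R <- R %*% M
    M <- M %*% M
    kk <- kk %/% 2L
  }
  dimnames(R) <- dimnames(unclass(A))
  new_amplitude_matrix(R, stages = amp_stages(A) * as.integer(k))
}

#' k-stage transition probability between two codons
#'
#' The probability of reaching `to` from `from` after `k` stages of the
#' amplitude chain, `|(A^k)_{from,to}|^2`. With real nonnegative phases the
#' self-transition interferes constructively (an error in one stage can be
#' reverted by nine distinct errors in the next), so this generally differs
#' from the classical Markov k-step probability built from `|a|^2`.
#'
#' @param A Single-stage amplitude matrix.
#' @param from,to Codon triplets (or integer state indices for toy spaces).
#' @param k Number of stages.
#' @return Transition probability in `[0, 1]` (literal squared magnitude;
#'   can marginally exceed 1 for composed stages, see [amp_row_norms()]).
#' @export
kstage_transition_probability <- function(A, from, to, k = 1L) {
  Ak <- if (k == 1L) A else amp_power(A, k)
  i <- if (is.character(from)) codon_index(from) else as.integer(from)
  j <- if (is.character(to)) codon_index(to) else as.integer(to)
  Mod(unclass(Ak)[i, j])^2
}

#' Renormalize amplitude rows to unit 2-norm
#'
#' Composed amplitude matrices are not row-normalized (the literal operator
#' sum is not trace preserving); dividing each row by its 2-norm is the
#' minimal repair that makes the induced operator set a completely positive
#' trace-preserving channel. It is the amplitude-level analogue of the
#' explicit per-row normalization the hybrid model applies to its classical
#' transition matrix.
#'
#' @param A Amplitude matrix.
#' @return An `amplitude_matrix` with unit squared row norms.
#' @export
amp_renormalize <- function(A) {
  new_amplitude_matrix(unclass(A) / sqrt(amp_row_norms(A)),
                       stages = amp_stages(A))
}
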