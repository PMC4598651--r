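#' Operator-sum (Kraus) representation of the amplitude chain
#'
#' Each nonzero amplitude `a_mn` defines one Kraus operator
#' `E_mn = a_mn |n><m|`; the channel acts as
#' `xi(rho) = sum_mn E_mn rho E_mn^dagger`. Completeness
#' `sum E^dagger E = I` holds exactly when the amplitude rows have unit
#' 2-norm, which is why [kraus_from_amplitudes()] insists on it (renormalize
#' composed matrices with [amp_renormalize()] first).
#'
#' Because every operator here is rank one with a baseket on each side, the
#' channel output is always diagonal in the codon basis:
#' `xi(rho) = diag(t(|A|^2) %*% diag(rho))`. [apply_superoperator()] uses
#' that closed form; the brute-force double sum over operators is kept as a
#' test oracle.
#'
#' @param A Row-normalized amplitude matrix (any dimension; toy spaces
#'   allowed).
#' @param tol Tolerance on the row 2-norms.
#' @return A `kraus_set` object.
#' @examples
#' K <- kraus_from_amplitudes(amplitude_matrix(0.003))
#' length(kraus_nonzero(K)$amplitude) # 64 diagonal + 576 neighbor operators
#' @export
kraus_from_amplitudes <- function(A, tol = 1e-8) {
  dev <- max(abs(amp_row_norms(A) - 1))
  if (dev > tol) {
    stop("amplitude rows must have unit 2-norm to define a ",
         "trace-preserving Kraus set (max deviation ", format(dev),
         "); see amp_renormalize()", call. = FALSE)
  }
  structure(list(amp = unclass(A), dim = nrow(A)), class = "kraus_set")
}

#' @export
print.kraus_set <- function(x, ...) {
  nz <- sum(Mod(x$amp) > 0)
  cat(sprintf("<kraus_set: %d operators a_mn|n><m| on a %d-state space>\n",
              nz, x$dim))
  invisible(x)
}

#' @rdname kraus_from_amplitudes
#' @return `kraus_nonzero()`: a list with the row index `from`, column index
#'   `to` and complex `amplitude` of each nonzero operator.
#' @export
kraus_nonzero <- function(K) {
  idx <- which(Mod(K$amp) > 0, arr.ind = TRUE)
  list(from = idx[, 1], to = idx[, 2], amplitude = K$amp[idx])
}

#' @rdname kraus_from_amplitudes
#' @param K A `kraus_set`.
#' @return `kraus_completeness_defect()`: the max-abs deviation of
#'   `sum E^dagger E` from the identity (a diagonal matrix of squared row
#'   norms for this operator family).
#' @export
kraus_completeness_defect <- function(K) {
  max(abs(amp_row_norms(K$amp) - 1))
}

#' Apply a superoperator to a density matrix
#'
#' Evaluates `xi(rho) = sum_k E_k rho E_k^dagger`. `K` may be a `kraus_set`
#' built from an amplitude matrix (closed-form diagonal output) or a plain
#' list of operator matrices (generic sum, used e.g. for the
#' Lindblad-derived operators of [kraus_from_lindblad()]).
#'
#' @param K `kraus_set` or list of matrices.
#' @param rho Density matrix (Hermitian, unit trace, positive semidefinite).
#' @param check Validate `rho` before applying (tolerance 1e-8)?
#' @return The output density matrix; trace and positivity are preserved up
#'   to the completeness defect of `K`.
#' @export
apply_superoperator <- function(K, rho, check = TRUE) {
  if (check) assert_density(rho)
  if (inherits(K, "kraus_set")) {
    q <- as.vector(crossprod(Mod(K$amp)^2, Re(diag(rho))))
    out <- diag(q)
    dimnames(out) <- dimnames(K$amp)
    out
  } else {
    Reduce(`+`, lapply(K, function(E) E %*% rho %*% Conj(t(E))))
  }
}

#' Density-matrix helpers
#'
#' A density matrix is Hermitian, unit-trace and positive semidefinite.
#' `pure_state_density(v)` builds `|v><v|` from a (normalized) ket;
#' `mixed_density(idx, dim)` the uniform mixture of basekets `idx`.
#'
#' @param rho Matrix to validate.
#' @param tol Tolerance for Hermiticity, trace and eigenvalue checks.
#' @export
assert_density <- function(rho, tol = 1e-8) {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (max(abs(rho - Conj(t(rho)))) > tol) {
    stop("density matrix is not Hermitian", call. = FALSE)
  }
  if (abs(sum(diag(rho)) - 1) > tol) {
    stop("density matrix trace differs from 1 by ",
         format(abs(sum(diag(rho)) - 1)), call. = FALSE)
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("density matrix has negative eigenvalue ", format(min(ev)),
         call. = FALSE)
  }
  invisible(rho)
}

#' @rdname assert_density
#' @param v Complex or numeric ket; normalized to unit length.
#' @export
pure_state_density <- function(v) {
  v <- v / sqrt(sum(Mod(v)^2))
  outer(v, Conj(v))
}

#' @rdname assert_density
#' @param idx Integer baseket indices to mix uniformly.
#' @param dim Dimension of the state space.
#' @export
mixed_density <- function(idx, dim = 64L) {
  rho <- matrix(0, dim, dim)
  rho[cbind(idx, idx)] <- 1 / length(idx)
  rho
}
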