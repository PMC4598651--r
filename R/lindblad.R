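#' Lindblad generator and its stage-wise operator-sum discretization
#'
#' The quantum master equation in Lindblad form,
#' `drho/dt = [-iH, rho] + sum_k (L_k rho L_k^dagger
#' - 0.5 {L_k^dagger L_k, rho})`,
#' is the first-order limit of a stage-wise operator-sum map with
#' `E_0 = I + (K - iH) dt` and `E_k = L_k sqrt(dt)`, where
#' `K = -0.5 sum_k L_k^dagger L_k` is forced by the completeness condition
#' at first order. The `sqrt(dt)` scaling makes `E_k rho E_k^dagger` first
#' order in `dt`; the residual between one superoperator step and one Euler
#' step of the master equation is then O(dt^2). The reduced Planck constant
#' is set to 1.
#'
#' @param H Hermitian Hamiltonian matrix.
#' @param L List of Lindblad (jump) operator matrices, same dimension as
#'   `H`.
#' @param dt Time step used by the discretization.
#' @return `lindblad_model()`: a `lindblad_model` object with fields `H`,
#'   `L`, `K` and `dt`.
#' @export
lindblad_model <- function(H, L = list(), dt = 1e-3) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H), is.list(L), dt >= 0)
  if (max(abs(H - Conj(t(H)))) > 1e-10) {
    stop("'H' must be Hermitian", call. = FALSE)
  }
  K <- matrix(0, nrow(H), ncol(H))
  for (Lk in L) {
    stopifnot(all(dim(Lk) == dim(H)))
    K <- K - 0.5 * Conj(t(Lk)) %*% Lk
  }
  structure(list(H = H, L = L, K = K, dt = dt), class = "lindblad_model")
}

#' @export
print.lindblad_model <- function(x, ...) {
  cat(sprintf("<lindblad_model: dim %d, %d jump operator(s), dt = %g>\n",
              nrow(x$H), length(x$L), x$dt))
  invisible(x)
}

#' @rdname lindblad_model
#' @param model A `lindblad_model`.
#' @param rho Density matrix.
#' @return `qme_rhs()`: the Lindblad right-hand side, a traceless Hermitian
#'   matrix.
#' @export
qme_rhs <- function(model, rho) {
  H <- model$H
  out <- -1i * (H %*% rho - rho %*% H)
  for (Lk in model$L) {
    LdL <- Conj(t(Lk)) %*% Lk
    out <- out + Lk %*% rho %*% Conj(t(Lk)) - 0.5 * (LdL %*% rho + rho %*% LdL)
  }
  out
}

#' @rdname lindblad_model
#' @param dt Time step; defaults to the model's.
#' @return `kraus_from_lindblad()`: a plain list of operator matrices
#'   (`E_0`, then one per jump operator) usable with
#'   [apply_superoperator()]. Completeness holds up to O(dt^2).
#' @export
kraus_from_lindblad <- function(model, dt = model$dt) {
  I <- diag(nrow(model$H))
  c(list(I + (model$K - 1i * model$H) * dt),
    lapply(model$L, function(Lk) Lk * sqrt(dt)))
}

#' Deviation between one superoperator stage and one Euler step of the QME
#'
#' Measures `max | xi(rho) - (rho + qme_rhs(rho) * dt) |` with the
#' operator set of [kraus_from_lindblad()] at step `dt`. The deviation
#' scales as O(dt^2): halving `dt` quarters it, which is the numerical
#' statement that the master equation is the first-order limit of the
#' stage-wise operator-sum map.
#'
#' @inheritParams qme_rhs
#' @param dt Time step (`dt = 0` gives 0 exactly).
#' @return Nonnegative scalar (max-abs norm of the residual).
#' @export
qme_superop_deviation <- function(model, rho, dt = model$dt) {
  if (dt == 0) return(0)
  K <- kraus_from_lindblad(model, dt)
  xi <- apply_superoperator(K, rho, check = FALSE)
  euler <- rho + qme_rhs(model, rho) * dt
  max(Mod(xi - euler))
}
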