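#' Von Neumann entropy of a density matrix
#'
#' `S(rho) = -sum_i lambda_i log2(lambda_i)` over the eigenvalues of `rho`,
#' in bits, with `0 log 0 = 0` (eigenvalues are clipped at 1e-15 before the
#' logarithm). For a diagonal density matrix this is the Shannon entropy of
#' the diagonal, the classical special case.
#'
#' @param rho Density matrix.
#' @param tol Eigenvalues below `-tol` raise an error.
#' @return Entropy in bits.
#' @examples
#' von_neumann_entropy(diag(64) / 64) # 6 bits, maximally mixed
#' @export
von_neumann_entropy <- function(rho, tol = 1e-8) {
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("not positive semidefinite: eigenvalue ", format(min(ev)),
         call. = FALSE)
  }
  shannon_entropy(pmax(ev, 0))
}

#' @rdname von_neumann_entropy
#' @param p Nonnegative weights (need not be normalized for intermediate
#'   use).
#' @export
shannon_entropy <- function(p) {
  p <- pmax(p, 1e-15)
  -sum(ifelse(p > 1e-15, p * log2(p), 0))
}

#' Holevo quantity of an ensemble through a channel
#'
#' `chi = S(xi(sum_x p_x rho_x)) - sum_x p_x S(xi(rho_x))`, the
#' accessible-information bound whose maximum over priors is the HSW
#' capacity. Always nonnegative (concavity of the entropy).
#'
#' @param ens A [codon ensemble][mixed_state_ensemble] (or any tibble with
#'   `prior` and `state` columns).
#' @param channel A `kraus_set` (or list of Kraus operator matrices).
#' @param priors Optional priors overriding `ens$prior`.
#' @return Holevo quantity in bits.
#' @export
holevo_quantity <- function(ens, channel, priors = NULL) {
  p <- if (is.null(priors)) ens$prior else priors
  if (abs(sum(p) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  outs <- lapply(ens$state, function(rho) {
    apply_superoperator(channel, rho, check = FALSE)
  })
  avg <- Reduce(`+`, Map(`*`, outs, p))
  von_neumann_entropy(avg) -
    sum(p * vapply(outs, von_neumann_entropy, numeric(1)))
}

#' HSW capacity of a quantum channel for a fixed-state ensemble
#'
#' Maximizes the Holevo quantity over the prior simplex for the fixed
#' channel-output states `sigma_x = xi(rho_x)` by the exponentiated-gradient
#' (Blahut-Arimoto type) iteration `p_x <- p_x 2^{D(sigma_x || sigma_bar)}`,
#' where `D` is the quantum relative entropy in bits. The objective is
#' concave in the priors and the iteration brackets the optimum: the run
#' stops when the gap between `max_x D` (upper bound) and `sum_x p_x D`
#' (lower bound) falls below `tol`.
#'
#' When all output states commute (they are simultaneously diagonal for
#' every operator-sum channel of the `a_mn |n><m|` form), the iteration
#' reduces exactly to classical Blahut-Arimoto on the diagonal
#' distributions, and that reduction is used.
#'
#' @inheritParams holevo_quantity
#' @param tol Convergence tolerance on the capacity bracket, in bits.
#' @param max_iter Maximum number of iterations; non-convergence is flagged
#'   in the result, not silent.
#' @return A `capacity_result` with the capacity (bits/residue), the
#'   optimizing priors, and convergence diagnostics.
#' @examples
#' K <- kraus_from_amplitudes(amplitude_matrix(0))
#' hsw_capacity(random_eigenket_ensemble(seed = 1), K)$capacity # log2(21)
#' @export
hsw_capacity <- function(ens, channel, tol = 1e-9, max_iter = 10000L) {
  outs <- lapply(ens$state, function(rho) {
    apply_superoperator(channel, rho, check = FALSE)
  })
  offdiag <- vapply(outs, function(s) max(Mod(s - diag(diag(s)))),
                    numeric(1))
  if (max(offdiag) < 1e-12) {
    W <- do.call(rbind, lapply(outs, function(s) Re(diag(s))))
    res <- ba_maximize(W, tol = tol, max_iter = max_iter)
  } else {
    res <- hsw_maximize_general(outs, tol = tol, max_iter = max_iter)
  }
  new_capacity_result(res, labels = ens$class, units = "bits/residue",
                      method = "hsw")
}

# general (non-commuting) exponentiated-gradient ascent over priors
hsw_maximize_general <- function(outs, tol, max_iter) {
  nx <- length(outs)
  logs <- lapply(outs, herm_log2)
  tr_slog <- vapply(seq_len(nx), function(x) {
    Re(sum(diag(outs[[x]] %*% logs[[x]])))
  }, numeric(1))
  p <- rep(1 / nx, nx)
  upper <- lower <- NA_real_
  for (it in seq_len(max_iter)) {
    avg <- Reduce(`+`, Map(`*`, outs, p))
    lavg <- herm_log2(avg)
    D <- vapply(seq_len(nx), function(x) {
      tr_slog[x] - Re(sum(diag(outs[[x]] %*% lavg)))
    }, numeric(1))
    lower <- sum(p * D)
    upper <- max(D)
    if (upper - lower < tol) {
      return(list(capacity = upper, priors = p, iterations = it,
                  converged = TRUE, gap = upper - lower))
    }
    p <- p * 2^(D - max(D))
    p <- p / sum(p)
  }
  list(capacity = upper, priors = p, iterations = max_iter,
       converged = FALSE, gap = upper - lower)
}

herm_log2 <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  lv <- log2(pmax(e$values, 1e-15))
  e$vectors %*% (lv * Conj(t(e$vectors)))
}

#' Shannon capacity of a discrete memoryless channel
#'
#' Blahut-Arimoto maximization of the mutual information `I(X; Y)` over
#' input priors for a row-stochastic transition matrix. For the codon-level
#' chain the natural inputs are the amino-acid classes: pass
#' `input_partition` to average the codon rows uniformly within each class
#' (capacity then in bits/residue); without it every matrix row is an input
#' (bits/symbol for the 4-state nucleotide models).
#'
#' @param P Row-stochastic transition matrix.
#' @param input_partition Optional named list of row-index groups (e.g.
#'   [aa_classes()]); inputs become the groups, each emitting a uniform
#'   mixture of its rows.
#' @param tol Convergence tolerance on the capacity bracket, in bits.
#' @param max_iter Iteration cap; non-convergence is flagged.
#' @return A `capacity_result`.
#' @examples
#' shannon_capacity(msc_matrix(0))$capacity # 2 bits/symbol
#' @export
shannon_capacity <- function(P, input_partition = NULL, tol = 1e-9,
                             max_iter = 10000L) {
  if (max(abs(rowSums(P) - 1)) > 1e-8) {
    stop("'P' must be row-stochastic", call. = FALSE)
  }
  if (is.null(input_partition)) {
    W <- P
    labels <- rownames(P)
    units <- if (nrow(P) == 4) "bits/symbol" else "bits/input"
  } else {
    W <- do.call(rbind, lapply(input_partition, function(ix) {
      colMeans(P[ix, , drop = FALSE])
    }))
    labels <- names(input_partition)
    units <- "bits/residue"
  }
  res <- ba_maximize(W, tol = tol, max_iter = max_iter)
  new_capacity_result(res, labels = labels, units = units,
                      method = "blahut-arimoto")
}

# classical Blahut-Arimoto on a nonnegative row matrix W (rows: inputs).
# Lower/upper capacity bounds per Blahut's bracket; monotone in the lower
# bound for stochastic W.
ba_maximize <- function(W, tol = 1e-9, max_iter = 10000L) {
  nx <- nrow(W)
  r <- rep(1 / nx, nx)
  lW <- ifelse(W > 0, log(W), 0)
  upper <- lower <- NA_real_
  for (it in seq_len(max_iter)) {
    q <- as.vector(crossprod(W, r))
    lq <- ifelse(q > 0, log(q), 0)
    D <- rowSums(W * (lW - matrix(lq, nx, ncol(W), byrow = TRUE)))
    lower <- sum(r * D) / log(2)
    upper <- max(D) / log(2)
    if (upper - lower < tol) {
      return(list(capacity = upper, priors = r, iterations = it,
                  converged = TRUE, gap = upper - lower))
    }
    r <- r * exp(D - max(D))
    r <- r / sum(r)
  }
  list(capacity = upper, priors = r, iterations = max_iter,
       converged = FALSE, gap = upper - lower)
}

new_capacity_result <- function(res, labels, units, method) {
  structure(list(capacity = res$capacity,
                 priors = stats::setNames(res$priors, labels),
                 iterations = res$iterations,
                 converged = res$converged,
                 gap = res$gap,
                 units = units,
                 method = method),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("Channel capacity: %.9g %s\n", x$capacity, x$units))
  cat(sprintf("  method: %s; %d iteration(s); %s (bracket gap %.2e bits)\n",
              x$method, x$iterations,
              if (x$converged) "converged" else "NOT converged", x$gap))
  invisible(x)
}

#' Tidy methods for capacity results
#'
#' `tidy()` returns one row per input class with its optimizing prior;
#' `glance()` a one-row summary (capacity, units, convergence diagnostics).
#'
#' @param x A `capacity_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy capacity_result
#' @export
tidy.capacity_result <- function(x, ...) {
  tibble::tibble(class = names(x$priors), prior = unname(x$priors))
}

#' @rdname tidy.capacity_result
#' @method glance capacity_result
#' @export
glance.capacity_result <- function(x, ...) {
  tibble::tibble(capacity = x$capacity, units = x$units,
                 method = x$method, iterations = x$iterations,
                 converged = x$converged, gap = x$gap)
}

#' Serialize a capacity result to JSON
#'
#' @param x A `capacity_result`.
#' @param path Output file.
#' @export
write_capacity_json <- function(x, path) {
  jsonlite::write_json(
    list(capacity = x$capacity, units = x$units, method = x$method,
         priors = as.list(x$priors), iterations = x$iterations,
         converged = x$converged, gap = x$gap),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
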