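#' Capacity of the multi-stage codon channel models
#'
#' High-level wrappers that assemble a channel from the single-base error
#' probability `p` and a stage count, and hand it to the capacity
#' optimizers.
#'
#' `classical_codon_capacity()` is the Shannon capacity of the classical
#' Markov chain `P^k` built from the single-stage probabilities
#' `p_mn = |a_mn|^2`, with the amino-acid classes as inputs (uniform codon
#' usage within a class).
#'
#' `quantum_codon_capacity()` is the HSW capacity of the k-stage amplitude
#' chain for a given input ensemble. Because the composed operator sum is
#' not trace preserving (interfering paths inflate the squared row norms by
#' a uniform factor `c >= 1`), two evaluation conventions are offered:
#'
#' * `"stochastic"` (default): amplitude rows are renormalized to unit
#'   2-norm before the Kraus set is formed -- a completely positive
#'   trace-preserving channel, the principled HSW setting.
#' * `"literal"`: the composed operator sum is evaluated as written. The
#'   row-norm factor is uniform across codons (the neighbor graph is
#'   vertex-transitive), so this equals the stochastic-convention capacity
#'   multiplied by `c`; the factor is computed and checked for uniformity.
#'
#' The conventions agree at a single stage and diverge for `k >= 2`; see
#' the package vignette for why the choice matters.
#'
#' @param p Single-base error probability in `[0, 1/3)`.
#' @param stages Number of chain stages (generations), `>= 1`.
#' @param ensemble Input ensemble (see [mixed_state_ensemble()] and
#'   friends); defaults to the superposition ensemble.
#' @param convention `"stochastic"` or `"literal"` (see Details).
#' @param exclude_stop Drop the stop class from the classical input
#'   partition?
#' @param tol,max_iter Optimizer controls, see [hsw_capacity()].
#' @return A `capacity_result`. For the literal convention the result
#'   carries a `trace_factor` field.
#' @examples
#' quantum_codon_capacity(0, 1)$capacity # log2(21)
#' @export
quantum_codon_capacity <- function(p, stages = 1L,
                                   ensemble = superposition_ensemble(),
                                   convention = c("stochastic", "literal"),
                                   tol = 1e-9, max_iter = 10000L) {
  convention <- match.arg(convention)
  Ak <- amp_power(amplitude_matrix(p), stages)
  norms <- amp_row_norms(Ak)
  K <- kraus_from_amplitudes(amp_renormalize(Ak))
  res <- hsw_capacity(ensemble, K, tol = tol, max_iter = max_iter)
  res$convention <- convention
  if (convention == "literal") {
    if (diff(range(norms)) > 1e-6 * max(norms)) {
      stop("literal convention needs a uniform operator-sum trace factor; ",
           "row norms vary by ", format(diff(range(norms))), call. = FALSE)
    }
    res$trace_factor <- mean(norms)
    res$capacity <- res$capacity * res$trace_factor
  } else {
    res$trace_factor <- 1
  }
  res
}

#' @rdname quantum_codon_capacity
#' @export
classical_codon_capacity <- function(p, stages = 1L, exclude_stop = FALSE,
                                     tol = 1e-9, max_iter = 10000L) {
  P <- stochastic_from_amplitudes(amplitude_matrix(p))
  shannon_capacity(markov_power(P, stages),
                   input_partition = aa_classes(exclude_stop),
                   tol = tol, max_iter = max_iter)
}

#' Capacity of the hybrid quantum-classical codon channel
#'
#' `kq` amplitude-composed quantum stages followed by `kc` classical
#' Markov steps. The classical transition matrix is the per-row-normalized
#' squared-magnitude matrix of the composed quantum amplitudes
#' ([hybrid_stochastic()]); `kc = 0` reduces to the pure quantum model.
#' Under the `"literal"` convention the quantum part keeps its operator-sum
#' trace factor, as in [quantum_codon_capacity()].
#'
#' @inheritParams quantum_codon_capacity
#' @param kq Quantum stages (`>= 1`).
#' @param kc Classical stages (`>= 0`).
#' @export
hybrid_codon_capacity <- function(p, kq = 1L, kc = 0L,
                                  exclude_stop = FALSE,
                                  convention = c("stochastic", "literal"),
                                  tol = 1e-9, max_iter = 10000L) {
  convention <- match.arg(convention)
  stopifnot(kq >= 1, kc >= 0)
  Akq <- amp_power(amplitude_matrix(p), kq)
  Pq <- hybrid_stochastic(Akq)
  W <- Pq %*% markov_power(Pq, kc)
  res <- shannon_capacity(W, input_partition = aa_classes(exclude_stop),
                          tol = tol, max_iter = max_iter)
  res$convention <- convention
  res$trace_factor <- 1
  if (convention == "literal") {
    norms <- amp_row_norms(Akq)
    res$trace_factor <- mean(norms)
    res$capacity <- res$capacity * res$trace_factor
  }
  res
}

#' Capacity of the nucleotide-level reference chains
#'
#' Shannon capacity (bits/symbol) of the n-generation 4-ary symmetric or
#' Kimura Markov process.
#'
#' @param Ps Symbol error probability.
#' @param generations Number of chain steps.
#' @param gamma Kimura parameter (ignored for the symmetric model).
#' @param model `"msc"` or `"kimura"`.
#' @param layout Kimura row layout, see [kimura_matrix()].
#' @inheritParams quantum_codon_capacity
#' @export
nucleotide_capacity <- function(Ps, generations = 1L,
                                model = c("msc", "kimura"), gamma = 1,
                                layout = "canonical",
                                tol = 1e-9, max_iter = 10000L) {
  model <- match.arg(model)
  M <- if (model == "msc") msc_matrix(Ps) else
    kimura_matrix(Ps, gamma, layout)
  shannon_capacity(markov_power(M, generations), tol = tol,
                   max_iter = max_iter)
}
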