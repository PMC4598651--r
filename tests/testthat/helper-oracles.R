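# Independent oracles used across the suite. They deliberately avoid the
# package's matrix-power/superoperator code paths: path sums are recursive
# enumerations, superoperator application is the explicit double sum.

# sum over all length-k paths of products of stage amplitudes (also valid
# for probabilities when given a stochastic matrix)
enumerate_paths <- function(M, from, to, k) {
  if (k == 1) return(M[from, to])
  sum(vapply(seq_len(nrow(M)), function(l) {
    M[from, l] * enumerate_paths(M, l, to, k - 1)
  }, M[1, 1]))
}

# brute-force operator-sum application for E_mn = a_mn |n><m|
brute_force_superop <- function(amp, rho) {
  n <- nrow(amp)
  out <- matrix(0 + 0i, n, n)
  for (m in seq_len(n)) {
    for (nn in seq_len(n)) {
      if (Mod(amp[m, nn]) > 0) {
        E <- matrix(0 + 0i, n, n)
        E[nn, m] <- amp[m, nn]
        out <- out + E %*% rho %*% Conj(t(E))
      }
    }
  }
  out
}

# random amplitude matrix with unit 2-norm rows (complex unless real = TRUE)
random_amplitude <- function(n, seed, real = FALSE) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(n * n), n, n)
    if (!real) M <- M + 1i * matrix(stats::rnorm(n * n), n, n)
    M / sqrt(rowSums(Mod(M)^2))
  })
}

random_stochastic <- function(n, seed) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(n * n), n, n)
    M / rowSums(M)
  })
}

# random density matrix via a Wishart-type construction
random_density <- function(n, seed) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * n), n, n) +
      1i * matrix(stats::rnorm(n * n), n, n)
    W <- X %*% Conj(t(X))
    W / Re(sum(diag(W)))
  })
}

# two-state rotation-style amplitude stage: row m = amplitudes from m
rot_amp <- function(phi) {
  as_amplitude_matrix(matrix(c(cos(phi), sin(phi),
                               -sin(phi), cos(phi)),
                             2, 2, byrow = TRUE))
}

binary_entropy <- function(f) {
  ifelse(f <= 0 | f >= 1, 0, -f * log2(f) - (1 - f) * log2(1 - f))
}

msc_closed_form <- function(Ps) {
  2 + (1 - Ps) * log2(max(1 - Ps, 1e-300)) +
    ifelse(Ps > 0, Ps * log2(Ps / 3), 0)
}
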