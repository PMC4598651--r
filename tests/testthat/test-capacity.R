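test_that("von Neumann entropy has its characteristic limits", {
  expect_equal(von_neumann_entropy(pure_state_density(c(1, 0, 0))), 0,
               tolerance = 1e-10)
  expect_equal(von_neumann_entropy(diag(64) / 64), 6, tolerance = 1e-12)

  # diagonal density: reduces to the Shannon entropy of the diagonal
  d <- c(0.5, 0.25, 0.125, 0.125)
  expect_equal(von_neumann_entropy(diag(d)), shannon_entropy(d),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(d), 1.75)

  expect_error(von_neumann_entropy(diag(c(1.2, -0.2))), "semidefinite")
})

test_that("the Holevo quantity bounds ensembles as expected", {
  K0 <- kraus_from_amplitudes(amplitude_matrix(0))
  ens <- random_eigenket_ensemble(seed = 1)

  # single-state ensemble carries no information
  one <- ens[1, ]
  one$prior <- 1
  expect_equal(holevo_quantity(one, K0), 0, tolerance = 1e-10)

  # orthogonal pure states through the identity: entropy of the priors
  expect_equal(holevo_quantity(ens, K0), log2(21), tolerance = 1e-9)

  ensn <- mixed_state_ensemble()
  expect_gte(holevo_quantity(ensn, kraus_from_amplitudes(
    amplitude_matrix(0.01))), 0)
  expect_error(holevo_quantity(ens, K0, priors = rep(0.5, 21)), "sum to 1")
})

test_that("Blahut-Arimoto matches symmetric-channel closed forms", {
  # binary symmetric toy
  for (f in c(0.05, 0.11, 0.3)) {
    B <- matrix(c(1 - f, f, f, 1 - f), 2, 2)
    expect_equal(shannon_capacity(B, tol = 1e-12)$capacity,
                 1 - binary_entropy(f), tolerance = 1e-9)
  }
  # 4-ary symmetric channel over a grid
  for (Ps in c(0.001, 0.01, 0.1, 0.3, 0.5, 0.7)) {
    expect_equal(shannon_capacity(msc_matrix(Ps), tol = 1e-12)$capacity,
                 msc_closed_form(Ps), tolerance = 1e-9)
  }
  expect_equal(shannon_capacity(msc_matrix(0))$capacity, 2,
               tolerance = 1e-9)
  expect_error(shannon_capacity(matrix(1, 2, 2)), "stochastic")
})

test_that("optimal priors are uniform for symmetric channels and
           convergence is diagnosed", {
  res <- shannon_capacity(msc_matrix(0.1), tol = 1e-12)
  expect_true(res$converged)
  expect_equal(unname(res$priors), rep(0.25, 4), tolerance = 1e-5)

  # an asymmetric channel cannot converge in a single iteration
  starved <- shannon_capacity(random_stochastic(3, seed = 9),
                              max_iter = 1L)
  expect_false(starved$converged)
  expect_true(is.finite(starved$capacity))
})

test_that("HSW capacity reduces to the classical capacity for diagonal
           (commuting) ensembles", {
  p <- 1e-3
  K <- kraus_from_amplitudes(amplitude_matrix(p))
  P <- stochastic_from_amplitudes(amplitude_matrix(p))

  # mixed ensemble <-> class-uniform partition
  hsw <- hsw_capacity(mixed_state_ensemble(), K, tol = 1e-10)
  cls <- shannon_capacity(P, input_partition = aa_classes(), tol = 1e-10)
  expect_equal(hsw$capacity, cls$capacity, tolerance = 1e-6)

  # baseket ensemble <-> singleton partition
  ens <- random_eigenket_ensemble(seed = 4)
  picks <- attr(ens, "picks")
  hsw3 <- hsw_capacity(ens, K, tol = 1e-10)
  cls3 <- shannon_capacity(P, input_partition = as.list(picks),
                           tol = 1e-10)
  expect_equal(hsw3$capacity, cls3$capacity, tolerance = 1e-6)
})

test_that("the general (non-commuting) optimizer matches the two-pure-state
           oracle", {
  # states |0> and |+> through the identity channel
  ens <- tibble::tibble(
    class = c("a", "b"),
    prior = c(0.5, 0.5),
    state = list(pure_state_density(c(1, 0)),
                 pure_state_density(c(1, 1) / sqrt(2))))
  K <- list(diag(2))
  res <- hsw_capacity(ens, K, tol = 1e-11)

  # oracle: brute-force maximization of the mixture entropy over the prior
  chi <- function(q) {
    avg <- q * ens$state[[1]] + (1 - q) * ens$state[[2]]
    von_neumann_entropy(avg)
  }
  oracle <- stats::optimize(chi, c(0, 1), maximum = TRUE,
                            tol = 1e-10)$objective
  expect_equal(res$capacity, oracle, tolerance = 1e-7)
  # closed form for two pure states with overlap c: H((1 + c)/2)
  expect_equal(res$capacity, binary_entropy((1 + 1 / sqrt(2)) / 2),
               tolerance = 1e-7)
})

test_that("noiseless capacity is the class entropy and noise only hurts", {
  for (ens in list(superposition_ensemble(),
                   random_eigenket_ensemble(seed = 2))) {
    res <- hsw_capacity(ens, kraus_from_amplitudes(amplitude_matrix(0)),
                        tol = 1e-10)
    expect_equal(res$capacity, log2(21), tolerance = 1e-8)
    expect_equal(unname(res$priors), rep(1 / 21, 21), tolerance = 1e-4)
  }
  noisy <- hsw_capacity(superposition_ensemble(),
                        kraus_from_amplitudes(amplitude_matrix(0.3)))
  expect_lt(noisy$capacity, log2(21) - 1)
})

test_that("capacity results have tidy and glance methods", {
  res <- shannon_capacity(msc_matrix(0.1))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$prior), 1, tolerance = 1e-9)

  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("capacity", "units", "method", "iterations",
                     "converged", "gap"))
  expect_output(print(res), "Channel capacity")
})
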