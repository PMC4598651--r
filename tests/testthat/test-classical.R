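test_that("squared amplitudes give the classical transition matrix", {
  expect_equal(stochastic_from_amplitudes(amplitude_matrix(0)), diag(64),
               ignore_attr = TRUE)
  P <- stochastic_from_amplitudes(amplitude_matrix(0.003))
  expect_equal(unname(P["UUU", "UUU"]), 0.991, tolerance = 1e-14)
  expect_equal(unname(P["UUU", "UUC"]), 0.001, tolerance = 1e-14)
  expect_equal(rowSums(P), rep(1, 64), tolerance = 1e-14,
               ignore_attr = TRUE)

  A2 <- amp_power(amplitude_matrix(0.01), 2)
  expect_error(stochastic_from_amplitudes(A2), "hybrid_stochastic")
  expect_equal(rowSums(hybrid_stochastic(A2)), rep(1, 64),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("Markov powers follow classical path composition", {
  P <- stochastic_from_amplitudes(amplitude_matrix(0.02))
  expect_equal(markov_power(P, 0), diag(64), ignore_attr = TRUE)

  # two-step probability restricted to the single-error support has
  # exactly the four classical terms
  P2 <- markov_power(P, 2)
  expect_equal(P2["UUU", "UUC"],
               P["UUU", "UUU"] * P["UUU", "UUC"] +
                 P["UUU", "UUC"] * P["UUC", "UUC"] +
                 P["UUU", "UUG"] * P["UUG", "UUC"] +
                 P["UUU", "UUA"] * P["UUA", "UUC"],
               tolerance = 1e-14)

  # brute-force path enumeration oracle on toy chains
  for (n in 2:4) {
    Q <- random_stochastic(n, seed = 200 + n)
    for (k in 2:5) {
      expect_equal(markov_power(Q, k)[1, n],
                   enumerate_paths(Q, 1, n, k), tolerance = 1e-12)
    }
  }
  expect_true(all(abs(rowSums(markov_power(P, 7)) - 1) < 1e-12))
})

test_that("stationary distributions are uniform for the symmetric chains", {
  expect_equal(stationary_distribution(msc_matrix(0.2)), rep(0.25, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  P <- stochastic_from_amplitudes(amplitude_matrix(0.05))
  expect_equal(stationary_distribution(P), rep(1 / 64, 64),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stationary distribution matches a long-run power oracle and
           rejects non-regular chains", {
  Q <- random_stochastic(3, seed = 77)
  pi1 <- stationary_distribution(Q)
  oracle <- markov_power(Q, 4096)[1, ]   # long-run row
  expect_equal(unname(pi1), unname(oracle), tolerance = 1e-9)
  expect_equal(unname(as.vector(pi1 %*% Q)), unname(pi1),
               tolerance = 1e-12)

  reducible <- diag(2)
  expect_error(stationary_distribution(reducible), "regular")
  periodic <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(stationary_distribution(periodic), "regular")
})

test_that("the 4-ary symmetric matrix and its powers behave as a family", {
  expect_equal(msc_matrix(0), diag(4), ignore_attr = TRUE)
  M <- msc_matrix(0.3)
  expect_equal(rowSums(M), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(diag(M)), rep(0.7, 4))

  # n-step chain is again symmetric at the effective error probability
  for (n in c(2, 7, 31)) {
    expect_equal(markov_power(msc_matrix(0.05), n),
                 msc_matrix(msc_effective_error(0.05, n)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_warning(msc_matrix(0.8), "3/4")
  expect_error(msc_matrix(1.2), "0, 1")
})

test_that("the Kimura matrix reduces to the symmetric channel at gamma 1
           and splits transitions from transversions otherwise", {
  expect_equal(kimura_matrix(0.1, 1), msc_matrix(0.1),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(kimura_matrix(0.1, 1, layout = "as-printed"),
               msc_matrix(0.1), tolerance = 1e-14, ignore_attr = TRUE)

  for (g in c(0, 0.07, 0.79, 1.5)) {
    Kc <- kimura_matrix(0.2, g)
    expect_equal(rowSums(Kc), rep(1, 4), tolerance = 1e-14,
                 ignore_attr = TRUE)
  }

  # canonical: the transition partner carries the enhanced rate
  Kc <- kimura_matrix(0.3, 0.2)
  expect_equal(Kc["T", "C"], (1 - 2 * 0.2 / 3) * 0.3, tolerance = 1e-14)
  expect_equal(Kc["A", "G"], (1 - 2 * 0.2 / 3) * 0.3, tolerance = 1e-14)
  expect_equal(Kc["T", "A"], 0.2 * 0.3 / 3, tolerance = 1e-14)

  # as-printed pairs T<->G and C<->A instead
  Kp <- kimura_matrix(0.3, 0.2, layout = "as-printed")
  expect_equal(Kp["T", "G"], (1 - 2 * 0.2 / 3) * 0.3, tolerance = 1e-14)
  expect_equal(Kp["C", "A"], (1 - 2 * 0.2 / 3) * 0.3, tolerance = 1e-14)

  # gamma = 0: all substitution mass on the designated partner
  K0 <- kimura_matrix(0.3, 0)
  expect_equal(K0["T", "C"], 0.3, tolerance = 1e-14)
  expect_equal(K0["T", "A"], 0)

  # rows are permutations of each other across layouts, so per-step
  # capacity coincides even though multi-step powers differ
  expect_equal(sort(Kc[1, ]), sort(Kp[1, ]), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(markov_power(Kc, 3),
                                markov_power(Kp, 3),
                                ignore_attr = TRUE)))

  expect_error(kimura_matrix(0.1, 2), "3/2")
})
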