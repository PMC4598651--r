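test_that("the single-stage amplitude matrix has the truncated-error form", {
  expect_equal(unclass(amplitude_matrix(0)), diag(64),
               ignore_attr = TRUE)

  A <- amplitude_matrix(0.003)
  expect_equal(A["UUU", "UUU"], sqrt(0.991), tolerance = 1e-12)
  expect_equal(A["UUU", "UUC"], sqrt(0.001), tolerance = 1e-12)
  expect_equal(A["UUU", "AAA"], 0)
  expect_equal(sum(Mod(unclass(A)) > 0), 64 + 64 * 9)

  for (p in c(1e-6, 0.01, 0.2, 0.33)) {
    expect_equal(amp_row_norms(amplitude_matrix(p)), rep(1, 64),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  expect_error(amplitude_matrix(1 / 3), "1/3")
  expect_error(amplitude_matrix(-0.01), "1/3")
})

test_that("phases change amplitudes but not squared magnitudes", {
  ph <- matrix(seq(0, 2 * pi, length.out = 64 * 64), 64, 64)
  A <- amplitude_matrix(0.01, phases = ph)
  expect_true(is.complex(unclass(A)))
  expect_equal(Mod(unclass(A))^2,
               Mod(unclass(amplitude_matrix(0.01)))^2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("amplitude composition satisfies Chapman-Kolmogorov", {
  for (A in list(amplitude_matrix(1e-3), random_amplitude(4, seed = 7))) {
    pows <- lapply(1:8, function(k) unclass(amp_power(A, k)))
    for (k in 2:8) {
      for (r in 1:(k - 1)) {
        expect_equal(pows[[k]], pows[[k - r]] %*% pows[[r]],
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
  A <- amplitude_matrix(1e-3)
  expect_equal(unclass(amp_power(A, 1)), unclass(A), ignore_attr = TRUE)
  expect_equal(amp_stages(amp_power(A, 3)), 3L)
  expect_error(amp_power(A, 0), "positive")
})

test_that("two-stage worked transitions match the explicit path sums", {
  A <- amplitude_matrix(0.02)
  A2 <- amp_power(A, 2)
  # off-diagonal: direct-then-stay, stay-then-direct, and the two
  # common-neighbor detours are the only contributing paths
  expect_equal(A2["UUU", "UUC"],
               A["UUU", "UUU"] * A["UUU", "UUC"] +
                 A["UUU", "UUC"] * A["UUC", "UUC"] +
                 A["UUU", "UUG"] * A["UUG", "UUC"] +
                 A["UUU", "UUA"] * A["UUA", "UUC"],
               tolerance = 1e-14)
  # self-transition: the direct path plus nine error-and-revert paths
  # interfere constructively to amplitude exactly 1
  nb <- single_base_neighbors("UUU")
  expect_equal(A2["UUU", "UUU"],
               A["UUU", "UUU"]^2 +
                 sum(vapply(nb, function(x) A["UUU", x] * A[x, "UUU"],
                            numeric(1))),
               tolerance = 1e-14)
  expect_equal(unname(A2["UUU", "UUU"]), 1, tolerance = 1e-12)
})

test_that("revert-path interference beats the classical self-transition", {
  for (p in c(1e-4, 1e-3, 1e-2, 0.1, 0.3)) {
    A <- amplitude_matrix(p)
    q2 <- kstage_transition_probability(A, "UUU", "UUU", k = 2)
    P <- stochastic_from_amplitudes(A)
    c2 <- markov_power(P, 2)["UUU", "UUU"]
    expect_gte(q2, c2)
  }
})

test_that("the Malus two-stage fixture reproduces cos^2(phi - theta)", {
  grid <- expand.grid(phi = seq(0, pi, length.out = 10),
                      theta = seq(0, pi, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    phi <- grid$phi[i]
    theta <- grid$theta[i]
    atot <- unclass(amp_compose(rot_amp(phi), rot_amp(-theta)))[1, 1]
    expect_equal(atot, cos(phi - theta), tolerance = 1e-12)
    ptot <- Mod(atot)^2
    expect_equal(ptot, cos(phi - theta)^2, tolerance = 1e-12)
    # the classical composition differs by exactly sin(2phi)sin(2theta)/2
    pclass <- cos(phi)^2 * cos(theta)^2 + sin(phi)^2 * sin(theta)^2
    expect_equal(ptot - pclass, 0.5 * sin(2 * phi) * sin(2 * theta),
                 tolerance = 1e-12)
  }
})

test_that("matrix powers agree with brute-force path enumeration", {
  for (n in 2:4) {
    A <- random_amplitude(n, seed = 100 + n)
    for (k in 2:5) {
      Ak <- unclass(amp_power(A, k))
      expect_equal(Ak[1, n], enumerate_paths(unclass(A), 1, n, k),
                   tolerance = 1e-12)
      expect_equal(Ak[2, 1], enumerate_paths(unclass(A), 2, 1, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("renormalized composed amplitudes have unit row norms", {
  A2 <- amp_power(amplitude_matrix(0.01), 2)
  expect_gt(max(amp_row_norms(A2)), 1)         # literal sum inflates
  expect_equal(amp_row_norms(amp_renormalize(A2)), rep(1, 64),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(as_amplitude_matrix(unclass(A2)), "normalized")
})
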