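test_that("Loewdin orthogonalization reduces to F for identity overlap", {
  F <- matrix(c(-5, 0.3, 0.3, -5.5), 2, 2)
  sys <- atomic_basis_system(F, diag(2),
    partition = list(1L, 2L),
    basepair_groups = list(c(1L, 2L))
  )
  expect_equal(lowdin_orthogonalize(sys), F, tolerance = 1e-14)
})

test_that("Loewdin spectrum matches the generalized eigenvalue oracle", {
  F <- matrix(c(0, 1, 1, 0), 2, 2)
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  sys <- atomic_basis_system(F, S,
    partition = list(1L, 2L),
    basepair_groups = list(c(1L, 2L))
  )
  H_a <- lowdin_orthogonalize(sys)
  # independent oracle: generalized eigenvalues of (F, S) via S^{-1} F
  gen <- sort(Re(eigen(solve(S, F))$values))
  expect_equal(sort(eigen(H_a, symmetric = TRUE)$values), gen,
    tolerance = 1e-10
  )
})

test_that("Loewdin output is symmetric and spectrum-preserving on random systems", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    F <- matrix(rnorm(n * n), n)
    F <- (F + t(F)) / 2
    B <- matrix(rnorm(n * n), n)
    S <- crossprod(B) / n + diag(n) # SPD, well conditioned
    part <- split(seq_len(n), rep(1:2, length.out = n))
    sys <- atomic_basis_system(F, S,
      partition = part,
      basepair_groups = list(c(1L, 2L))
    )
    H_a <- lowdin_orthogonalize(sys)
    expect_lt(max(abs(H_a - t(H_a))), 1e-12)
    gen <- sort(Re(eigen(solve(S, F))$values))
    expect_equal(sort(eigen(H_a, symmetric = TRUE)$values), gen,
      tolerance = 1e-9
    )
  }
})

test_that("non-positive-definite overlap is rejected with the eigenvalue named", {
  S_bad <- matrix(c(1, 1, 1, 1), 2, 2)
  sys <- atomic_basis_system(diag(2), diag(2),
    partition = list(1L, 2L),
    basepair_groups = list(c(1L, 2L))
  )
  sys$S <- S_bad
  expect_error(lowdin_orthogonalize(sys),
    class = "dnarom_overlap_error", regexp = "eigenvalue"
  )
  expect_error(
    atomic_basis_system(diag(2), diag(3),
      partition = list(1L, 2L),
      basepair_groups = list(c(1L, 2L))
    ),
    class = "dnarom_input_error"
  )
})

test_that("block diagonalization preserves spectrum and diagonalizes blocks", {
  set.seed(7)
  # two-nucleotide, 4-orbital toy system
  H_a <- matrix(rnorm(16), 4)
  H_a <- (H_a + t(H_a)) / 2
  part <- list(1:2, 3:4)
  hb <- block_diagonalize(H_a, part, basepair_groups = list(c(1L, 2L)))
  expect_equal(
    sort(eigen(hb$H, symmetric = TRUE)$values),
    sort(eigen(H_a, symmetric = TRUE)$values),
    tolerance = 1e-10
  )
  expect_equal(sum(diag(hb$H)), sum(diag(H_a)), tolerance = 1e-10)
  # diagonal blocks are diagonal by construction
  for (ix in part) {
    blk <- hb$H[ix, ix]
    expect_lt(max(abs(blk - diag(diag(blk)))), 1e-10)
  }
  # U orthogonal
  expect_lt(max(abs(crossprod(hb$U) - diag(4))), 1e-12)
})

test_that("already block-diagonal input is returned with identical eigenvalues", {
  H_a <- diag(c(-5.1, -5.3, -5.6, -5.0))
  hb <- block_diagonalize(H_a, list(1:2, 3:4),
    basepair_groups = list(c(1L, 2L))
  )
  expect_equal(sort(diag(hb$H)), sort(diag(H_a)), tolerance = 1e-12)
  expect_error(
    block_diagonalize(H_a, list(integer(0), 1:4),
      basepair_groups = list(c(1L, 2L))
    ),
    class = "dnarom_input_error"
  )
})

test_that("whole pipeline conserves the generalized spectrum", {
  set.seed(11)
  n <- 8
  F <- matrix(rnorm(n * n), n)
  F <- (F + t(F)) / 2
  B <- matrix(rnorm(n * n), n)
  S <- crossprod(B) / n + diag(n)
  part <- list(1:2, 3:4, 5:6, 7:8)
  bps <- list(c(1L, 3L), c(2L, 4L))
  sys <- atomic_basis_system(F, S, partition = part, basepair_groups = bps)
  hb <- block_diagonalize(lowdin_orthogonalize(sys), part, bps)
  gen <- sort(Re(eigen(solve(S, F))$values))
  got <- sort(eigen(hb$H, symmetric = TRUE)$values)
  expect_lt(max(abs(got - gen)) / max(abs(gen)), 1e-9)
})

test_that("bias ramp reproduces the printed seven-base-pair profile exactly", {
  expect_identical(
    bias_ramp_voltages(7, 1),
    c(0, 0.40, 0.45, 0.50, 0.55, 0.60, 1.0)
  )
  expect_identical(bias_ramp_voltages(7, -1), -bias_ramp_voltages(7, 1))
  expect_error(bias_ramp_voltages(3, 1), class = "dnarom_geometry_error")
  expect_error(bias_ramp_voltages(2, 1), class = "dnarom_geometry_error")
})

test_that("ramp endpoints and interior span hold for any length", {
  for (N in c(4, 5, 9, 20)) {
    for (vb in c(0.3, 1, 2)) {
      v <- bias_ramp_voltages(N, vb)
      expect_identical(v[1], 0)
      expect_identical(v[N], vb)
      expect_true(all(diff(v) >= 0))
      interior <- v[2:(N - 1)]
      expect_true(all(interior >= 0.4 * vb - 1e-12))
      expect_true(all(interior <= 0.6 * vb + 1e-12))
    }
  }
})

test_that("applying the ramp shifts diagonals per base pair and nothing else", {
  hb <- fixture_hb("CT1C")
  ramped <- apply_bias_ramp(hb, 1)
  v <- bias_ramp_voltages(hb$N, 1)
  for (p in seq_len(hb$N)) {
    orb <- unlist(hb$blocks[hb$basepair_groups[[p]]])
    expect_equal(diag(ramped$H)[orb], diag(hb$H)[orb] + v[p], tolerance = 1e-12)
  }
  off <- ramped$H - diag(diag(ramped$H))
  off0 <- hb$H - diag(diag(hb$H))
  expect_identical(off, off0)
  expect_identical(apply_bias_ramp(hb, 0)$H, hb$H)
})
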