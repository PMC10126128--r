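# circuit-level verification of the Kirchhoff oracle and the parametric model

linear_spec <- function(m, n, r_cell = 1e6, r_int = 1e4, v_in = 1,
                        bits = NULL) {
  iv <- linear_iv_table(r_cell)
  iv2 <- linear_iv_table(r_cell)
  bits <- bits %||% matrix(0L, m, n)
  crossbar_spec(bits, iv, iv2, r_int = r_int, v_in = v_in)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a single linear cell behaves as the hand-solved voltage divider", {
  r_cell <- 1e6
  r_int <- 1e4
  spec <- linear_spec(1, 1, r_cell, r_int)
  st <- solve_kirchhoff(spec, 1)
  expect_equal(st$V[1, 1], r_cell / (r_cell + 2 * r_int), tolerance = 1e-9)
  expect_equal(st$I_out[1], st$V[1, 1] / r_cell, tolerance = 1e-9)
})

test_that("vanishing interconnect resistance delivers the full bias to every read", {
  spec <- linear_spec(4, 5, 1e6, r_int = 1e-3)
  rm <- readout_map(spec, solver = "kirchhoff")
  # V[i, j] is the cell voltage seen while row i is being read
  expect_lt(max(abs(rm$V - 1)), 1e-6)
})

test_that("Kirchhoff node voltages match an independent dense netlist solve", {
  set.seed(3)
  G <- matrix(10^runif(4, -7, -5.5), 2, 2)
  spec <- linear_spec(2, 2, 1e6, 5e4)
  # override the secant seed so the linearization is exactly G
  st <- solve_kirchhoff(spec, 1, G_init = G, max_iter = 200)
  oracle <- netlist_oracle(2, 2, 5e4, matrix(spec$g_seed, 2, 2), 1, 1)
  expect_equal(st$V_word, oracle$V_word, tolerance = 1e-10)
  expect_equal(st$V_bit, oracle$V_bit, tolerance = 1e-10)
})

test_that("larger heterogeneous arrays agree with the netlist oracle", {
  set.seed(9)
  m <- 6
  n <- 5
  G <- matrix(10^runif(m * n, -7.5, -5.5), m, n)
  ed <- dnarom:::kirchhoff_edges(m, n)
  sol <- dnarom:::kirchhoff_linear_solve(ed, 1 / 2e4, as.vector(G), 3, 1)
  oracle <- netlist_oracle(m, n, 2e4, G, 3, 1)
  expect_equal(sol$V_word, oracle$V_word, tolerance = 1e-9)
  expect_equal(sol$V_bit, oracle$V_bit, tolerance = 1e-9)
})

test_that("KCL residual and energy balance hold on nonlinear fixture arrays", {
  ivs <- fixture_ivs_coarse()
  set.seed(5)
  bits <- random_bits(8, 8, 0.5)
  for (r_int in c(1e4, 1e6)) {
    spec <- crossbar_spec(bits, ivs$iv0, ivs$iv1, r_int = r_int)
    st <- solve_kirchhoff(spec, 3)
    expect_lt(st$kcl_residual, 1e-9 * spec$v_in / spec$r_int)
    expect_equal(st$power_W, source_power(st),
      tolerance = 1e-9
    )
    # driven-row cells are forward biased; floating-row cells may sit at
    # small voltages of either sign
    expect_true(all(st$V[3, ] >= -1e-9 & st$V[3, ] <= spec$v_in + 1e-9))
    expect_true(all(abs(st$V) <= spec$v_in + 1e-9))
  }
})

test_that("sneak factors are unity without parasitics and degrade with them", {
  spec0 <- linear_spec(8, 8, 1e6, r_int = 1e-3)
  sp0 <- estimate_sneak_parameters(spec0, G_avg = 1e-6)
  expect_lt(max(abs(sp0$alpha - 1)), 1e-6)
  expect_lt(max(abs(sp0$beta - 1)), 1e-6)

  spec <- linear_spec(12, 12, 1e6, r_int = 1e4)
  sp <- estimate_sneak_parameters(spec, G_avg = 1e-6)
  expect_true(all(sp$alpha > 0 & sp$alpha <= 1 + 1e-12))
  expect_true(all(sp$beta > 0))
  # row 1 is farthest from the grounded bitline ends, so its reads see the
  # largest voltage degradation
  expect_identical(which.min(sp$alpha), 1L)
  expect_true(all(diff(sp$alpha) > 0))
  # the first column feeds the most sneak current into its neighbours, so
  # its calibrated collection factor is the smallest
  expect_identical(which.min(sp$beta), 1L)
})

test_that("sneak factors are independent of the calibration bias", {
  spec <- linear_spec(10, 10, 1e6, r_int = 1e5)
  a <- estimate_sneak_parameters(spec, G_avg = 1e-6, v_ref = 0.5)
  b <- estimate_sneak_parameters(spec, G_avg = 1e-6, v_ref = 1.0)
  expect_equal(a$alpha, b$alpha, tolerance = 1e-9)
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
})

test_that("open cells see the full scaled wordline voltage", {
  spec <- linear_spec(4, 6, 1e6, 1e4)
  sneak <- estimate_sneak_parameters(spec, G_avg = 1e-6)
  for (form in c("calibrated", "literal")) {
    v <- voltage_distribution(spec, rep(0, 6), sneak, 2, form = form)
    expect_equal(v, rep(1 * sneak$alpha[2], 6), tolerance = 1e-12)
  }
})

test_that("the literal empty-sum profile collapses onto V_in alpha_i", {
  spec <- linear_spec(4, 6, 1e6, 1e4)
  sneak <- estimate_sneak_parameters(spec, G_avg = 1e-6)
  G_row <- rep(1e-6, 6)
  v_lit <- voltage_distribution(spec, G_row, sneak, 1, form = "literal")
  expect_equal(v_lit, rep(spec$v_in * sneak$alpha[1], 6), tolerance = 1e-12)
  # last column of the calibrated form: numerator is the empty sum, 1
  v_cal <- voltage_distribution(spec, G_row, sneak, 1, form = "calibrated")
  S <- seq_len(6) / spec$g_int
  den <- 1 + sum(G_row * S)
  expect_equal(v_cal[6], spec$v_in * sneak$alpha[1] / den, tolerance = 1e-12)
  expect_true(all(diff(v_cal) < 0))
})

test_that("parametric iteration on linear cells converges in two sweeps", {
  spec <- linear_spec(6, 6, 1e6, 1e4)
  st <- iterate_parametric(spec, 2)
  expect_lte(st$iterations, 2L)
  expect_identical(st$solver, "parametric")
  expect_true(all(is.na(st$V[-2, ])))
  expect_true(all(!is.na(st$V[2, ])))
})

test_that("the parametric fixed point is independent of the seed voltage", {
  ivs <- fixture_ivs_coarse()
  bits <- random_bits(64, 64, 0.5, seed = 21)
  spec <- crossbar_spec(bits, ivs$iv0, ivs$iv1, r_int = 1e5)
  sneak <- estimate_sneak_parameters(spec)
  a <- dnarom:::parametric_fixed_point(spec, rows = 1:64, sneak = sneak,
    seed_v = 0.05)
  b <- dnarom:::parametric_fixed_point(spec, rows = 1:64, sneak = sneak,
    seed_v = 0.01)
  expect_lt(max(abs(a$V - b$V)), 1e-5)
})

test_that("normalized voltages degrade toward the far column", {
  ivs <- fixture_ivs_coarse()
  bits <- matrix(1L, 16, 16)
  spec <- crossbar_spec(bits, ivs$iv0, ivs$iv1, r_int = 1e5)
  sneak <- estimate_sneak_parameters(spec)
  st <- iterate_parametric(spec, 1, sneak = sneak)
  norm_v <- st$V[1, ] / (spec$v_in * sneak$alpha[1])
  expect_true(all(diff(norm_v) <= 1e-12))
  stk <- solve_kirchhoff(spec, 1)
  expect_true(all(diff(stk$V[1, ]) <= 1e-9))
})

test_that("read voltages of a homogeneous array degrade most at row 1, far column", {
  ivs <- fixture_ivs_coarse()
  bits <- matrix(1L, 12, 12)
  spec <- crossbar_spec(bits, ivs$iv0, ivs$iv1, r_int = 1e6)
  rm <- readout_map(spec, solver = "kirchhoff")
  expect_equal(which(rm$V == min(rm$V), arr.ind = TRUE)[1, ],
    c(row = 1, col = 12))
  expect_true(all(diff(rm$V[1, ]) < 0))
})

test_that("parametric and Kirchhoff read-out maps agree on fixture arrays", {
  ivs <- fixture_ivs_coarse()
  bits <- random_bits(16, 16, 0.5, seed = 4)
  spec <- crossbar_spec(bits, ivs$iv0, ivs$iv1, r_int = 1e4)
  rk <- readout_map(spec, solver = "kirchhoff")
  rp <- readout_map(spec, solver = "parametric")
  rms <- sqrt(mean((rp$I_out - rk$I_out)^2)) / sqrt(mean(rk$I_out^2))
  expect_lt(rms, 0.05)
})

test_that("array power reduces to V^2/R for one ideally connected cell", {
  spec <- linear_spec(1, 1, 1e6, r_int = 1e-3)
  p <- array_power(spec)
  expect_equal(p, 1 / 1e6, tolerance = 1e-6)
})

test_that("read power falls from low to high interconnect resistance", {
  # the trend needs arrays large enough that a mega-Ohm interconnect
  # actually loads the mega-Ohm-scale cells
  ivs <- fixture_ivs_coarse()
  bits <- random_bits(48, 48, 0.5, seed = 8)
  p <- vapply(c(1e4, 1e6), function(r) {
    array_power(crossbar_spec(bits, ivs$iv0, ivs$iv1, r_int = r),
      rows = c(1, 16, 32, 48))
  }, numeric(1))
  expect_lt(p[2], p[1])
})
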