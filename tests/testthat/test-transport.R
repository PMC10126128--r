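test_that("single-site Green's function matches the closed form", {
  eps <- -5.2
  gam <- 0.4
  hb <- single_site_hb(eps)
  params <- transport_params(E_fL = eps, gamma_L = gam, gamma_R = gam,
    gamma_probe = 0)
  se <- self_energy_set(hb, params)
  for (E in c(-6, -5.2, -4.7)) {
    G <- retarded_green(E, hb, se)
    expect_equal(G[1, 1], 1 / (E - eps + 1i * gam), tolerance = 1e-12)
  }
})

test_that("with all couplings zero the resolvent is real and exact", {
  hb <- two_site_hb(-5.0, -5.4, 0.2)
  params <- transport_params(E_fL = -5, gamma_L = 0, gamma_R = 0,
    gamma_probe = 0)
  se <- self_energy_set(hb, params)
  G <- retarded_green(-3, hb, se)
  expect_lt(max(abs(Im(G))), 1e-14)
  expect_equal(Re(G), solve(-3 * diag(2) - hb$H), tolerance = 1e-12)
})

test_that("resolvent identity G^r - G^a = G^r (Sigma - Sigma^dag) G^a holds", {
  hb <- fixture_hb("CT1C")
  params <- transport_params(E_fL = -5.2)
  se <- self_energy_set(hb, params)
  G <- retarded_green(-5.1, hb, se)
  Ga <- Conj(t(G))
  lhs <- G - Ga
  rhs <- G %*% diag(-1i * se$gamma_diag) %*% Ga
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
})

test_that("symmetric single-site junction transmits perfectly on resonance", {
  eps <- -5.2
  hb <- single_site_hb(eps)
  params <- transport_params(E_fL = eps, gamma_L = 0.5, gamma_R = 0.5,
    gamma_probe = 0)
  se <- self_energy_set(hb, params)
  tr <- transmission_matrix(retarded_green(eps, hb, se), hb, se, E = eps)
  expect_equal(tr$T_LR, 1, tolerance = 1e-12)
  expect_equal(effective_transmission(tr), 1, tolerance = 1e-12)
})

test_that("single-site transmission matches the Lorentzian closed form", {
  eps <- -5.2
  gam <- 0.3
  hb <- single_site_hb(eps)
  params <- transport_params(E_fL = eps, gamma_L = gam, gamma_R = gam,
    gamma_probe = 0)
  se <- self_energy_set(hb, params)
  for (E in seq(-6, -4.4, by = 0.2)) {
    tr <- transmission_matrix(retarded_green(E, hb, se), hb, se, E = E)
    expect_equal(tr$T_LR, gam^2 / ((E - eps)^2 + gam^2), tolerance = 1e-10)
  }
})

test_that("two-site chain transmission matches the hand-derived formula", {
  eps1 <- -5.3
  eps2 <- -5.1
  t <- 0.15
  gl <- 0.8
  gr <- 0.6
  hb <- two_site_hb(eps1, eps2, t)
  params <- transport_params(E_fL = -5.2, gamma_L = gl, gamma_R = gr,
    gamma_probe = 0)
  se <- self_energy_set(hb, params)
  for (E in seq(-5.8, -4.6, by = 0.1)) {
    tr <- transmission_matrix(retarded_green(E, hb, se), hb, se, E = E)
    expect_equal(tr$T_LR, two_site_T_oracle(E, eps1, eps2, t, gl, gr),
      tolerance = 1e-10
    )
  }
})

test_that("transmission is reciprocal and nonnegative for a real Hamiltonian", {
  hb <- fixture_hb("CT1C")
  params <- transport_params(E_fL = -5.2)
  se <- self_energy_set(hb, params)
  for (E in c(-5.5, -5.2, -4.9)) {
    tr <- transmission_matrix(retarded_green(E, hb, se), hb, se, E = E)
    expect_lt(max(abs(tr$T_kl - t(tr$T_kl))), 1e-9)
    expect_true(all(tr$T_kl >= -1e-12))
    t_eff <- effective_transmission(tr)
    expect_gte(t_eff, tr$T_LR - 1e-12)
  }
})

test_that("single-probe elimination matches the hand-solved probe balance", {
  # three-nucleotide chain, probe on the middle site: imposing J_k(E) = 0 by
  # hand gives T_eff = T_LR + T_Lk T_kR / (T_kL + T_kR)
  H <- matrix(c(
    -5.2, -0.1, 0,
    -0.1, -5.3, -0.1,
    0, -0.1, -5.1
  ), 3, 3, byrow = TRUE)
  hb <- block_hamiltonian(H, list(1L, 2L, 3L),
    basepair_groups = list(1L, 2L, 3L), contact_sites = c(1L, 3L)
  )
  params <- transport_params(E_fL = -5.2, gamma_probe = 0.05)
  se <- self_energy_set(hb, params)
  expect_identical(se$N_b, 1L)
  for (E in c(-5.4, -5.2, -5.0)) {
    tr <- transmission_matrix(retarded_green(E, hb, se), hb, se, E = E)
    k <- setdiff(tr$labels, c("L", "R"))
    by_hand <- tr$T_LR +
      tr$T_kl["L", k] * tr$T_kl[k, "R"] / (tr$T_kl[k, "L"] + tr$T_kl[k, "R"])
    expect_equal(as.numeric(effective_transmission(tr)), by_hand,
      tolerance = 1e-12
    )
  }
})

test_that("without probes the effective transmission is exactly T_LR", {
  hb <- two_site_hb(-5.2, -5.2, 0.1)
  params <- transport_params(E_fL = -5.2, gamma_probe = 0)
  se <- self_energy_set(hb, params)
  se$labels <- c("L", "R")
  se$sites <- se$sites[c(1, length(se$sites))]
  se$gamma <- se$gamma[c(1, length(se$gamma))]
  se$N_b <- 0L
  se$probe_sites <- integer(0)
  tr <- transmission_matrix(retarded_green(-5.2, hb, se), hb, se)
  expect_identical(effective_transmission(tr), tr$T_LR)
})

test_that("probe currents vanish at every energy after elimination", {
  hb <- apply_bias_ramp(fixture_hb("CT1C"), 0.8)
  params <- transport_params(E_fL = -5.2, V_bias = 0.8)
  se <- self_energy_set(hb, params)
  energies <- seq(-5.6, -4.4, by = 0.1)
  J_list <- list()
  gross_list <- list()
  for (i in seq_along(energies)) {
    E <- energies[i]
    tr <- transmission_matrix(retarded_green(E, hb, se), hb, se, E = E)
    f_L <- dnarom:::fermi(E, params$E_fL, params$kT)
    f_R <- dnarom:::fermi(E, params$E_fL + 0.8, params$kT)
    jc <- dnarom:::probe_spectral_currents(tr, f_L, f_R)
    probes <- setdiff(tr$labels, c("L", "R"))
    J_list[[i]] <- jc$J[probes]
    gross_list[[i]] <- jc$gross[probes]
  }
  J <- unlist(J_list)
  gross <- unlist(gross_list)
  peak <- max(gross)
  # wherever a probe carries appreciable gross flow, its net current
  # cancels to 1e-9 relative; elsewhere it is absolutely negligible
  active <- gross >= 1e-6 * peak
  expect_true(any(active))
  expect_lt(max(abs(J[active]) / gross[active]), 1e-9)
  expect_lt(max(abs(J)), 1e-12 * peak)
})

test_that("terminal currents balance: I_L + I_R = 0", {
  hb <- apply_bias_ramp(fixture_hb("TC1T"), 1)
  params <- transport_params(E_fL = -5.2, V_bias = 1)
  se <- self_energy_set(hb, params)
  grid <- seq(-5.8, -3.9, by = 0.002)
  J_L <- numeric(length(grid))
  J_R <- numeric(length(grid))
  for (i in seq_along(grid)) {
    tr <- transmission_matrix(retarded_green(grid[i], hb, se), hb, se)
    f_L <- dnarom:::fermi(grid[i], params$E_fL, params$kT)
    f_R <- dnarom:::fermi(grid[i], params$E_fL + 1, params$kT)
    jc <- dnarom:::probe_spectral_currents(tr, f_L, f_R)
    J_L[i] <- jc$J[["L"]]
    J_R[i] <- jc$J[["R"]]
  }
  I_L <- sum(J_L)
  I_R <- sum(J_R)
  expect_lt(abs(I_L + I_R) / max(abs(I_L), 1e-300), 1e-9)
})

test_that("dephasing correction vanishes in the coherent limit", {
  hb <- fixture_hb("CT1C")
  window <- seq(-5.45, -5.05, by = 0.005)
  spec <- transmission_spectrum(
    hb, transport_params(E_fL = -5.2, gamma_probe = 1e-11), window
  )
  expect_lt(max(abs(spec$T_eff - spec$T_LR) / spec$T_LR), 1e-3)
  # the dephasing correction scales linearly with the probe coupling
  rel_of <- function(gk) {
    s <- transmission_spectrum(
      hb, transport_params(E_fL = -5.2, gamma_probe = gk),
      seq(-5.3, -5.1, by = 0.01)
    )
    max(abs(s$T_eff - s$T_LR) / s$T_LR)
  }
  r1 <- rel_of(1e-8)
  r2 <- rel_of(1e-9)
  expect_gt(r1 / r2, 5)
  expect_lt(r1 / r2, 20)
})

test_that("zero bias gives exactly zero current", {
  hb <- fixture_hb("CT1C")
  params <- transport_params(E_fL = -5.2, V_bias = 0)
  expect_identical(terminal_current(hb, params), 0)
})

test_that("single-site current matches the analytic Landauer integral", {
  eps <- -5.2
  gam <- 0.05
  kT <- 0.0259
  hb <- single_site_hb(eps)
  for (vb in c(0.3, 1)) {
    params <- transport_params(
      E_fL = eps - 0.1, V_bias = vb, gamma_L = gam, gamma_R = gam,
      gamma_probe = 0, kT = kT, energy_step = 5e-4
    )
    got <- terminal_current(hb, params)
    want <- single_site_current_oracle(eps, gam, eps - 0.1, vb, kT)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("current is integration-grid converged on the duplex fixture", {
  hb <- apply_bias_ramp(fixture_hb("CT1C"), 1)
  p1 <- transport_params(E_fL = -5.2, V_bias = 1, energy_step = 0.002)
  p2 <- transport_params(E_fL = -5.2, V_bias = 1, energy_step = 0.001)
  i1 <- terminal_current(hb, p1)
  i2 <- terminal_current(hb, p2)
  expect_lt(abs(i2 - i1) / abs(i2), 1e-4)
})

test_that("integration domain errors are raised for short grids", {
  hb <- apply_bias_ramp(fixture_hb("CT1C"), 1)
  params <- transport_params(E_fL = -5.2, V_bias = 1)
  narrow <- transmission_spectrum(hb, params, seq(-5.3, -5.0, by = 0.01))
  expect_error(terminal_current(hb, params, spectrum = narrow),
    class = "dnarom_integration_error"
  )
})

test_that("peak finding recovers constructed Lorentzian centers", {
  E <- seq(-6, -4, by = 0.002)
  lor <- function(E, c, w) w^2 / ((E - c)^2 + w^2)
  single <- lor(E, -5.2, 0.02)
  pk <- find_transmission_peaks(E, single)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$energy_eV - (-5.2)), 0.002)
  double <- lor(E, -5.5, 0.03) + 0.6 * lor(E, -4.8, 0.03)
  pk2 <- find_transmission_peaks(E, double)
  expect_identical(nrow(pk2), 2L)
  expect_lt(abs(pk2$energy_eV[1] - (-5.5)), 0.004)
  expect_lt(abs(pk2$energy_eV[2] - (-4.8)), 0.004)
  expect_identical(nrow(find_transmission_peaks(E[1:2], single[1:2])), 0L)
})

test_that("the HOMO peak shifts with the sign of the applied bias", {
  hb0 <- fixture_hb("CT1C")
  grid <- seq(-6.4, -3.8, by = 0.004)
  p <- transport_params(E_fL = -5.2)
  peak0 <- homo_peak_energy(transmission_spectrum(hb0, p, grid))
  peak_pos <- homo_peak_energy(
    transmission_spectrum(apply_bias_ramp(hb0, 1), p, grid)
  )
  peak_neg <- homo_peak_energy(
    transmission_spectrum(apply_bias_ramp(hb0, -1), p, grid)
  )
  expect_gt(peak_pos, peak0)
  expect_lt(peak_neg, peak0)
})
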