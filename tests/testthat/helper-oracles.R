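# Independent oracles used across the suite. None of these share code with
# the package's computational paths.

# single-site toy junction: one nucleotide, one orbital, both contacts on it
single_site_hb <- function(eps) {
  block_hamiltonian(
    H = matrix(eps, 1, 1), blocks = list(1L), basepair_groups = list(1L),
    contact_sites = c(1L, 1L)
  )
}

# two-site chain, contacts on either end, no probes
two_site_hb <- function(eps1, eps2, t) {
  block_hamiltonian(
    H = matrix(c(eps1, -t, -t, eps2), 2, 2),
    blocks = list(1L, 2L), basepair_groups = list(1L, 2L),
    contact_sites = c(1L, 2L)
  )
}

# textbook two-level Landauer transmission via the explicit 2x2 adjugate
# inverse, written out by hand
two_site_T_oracle <- function(E, eps1, eps2, t, gamma_L, gamma_R) {
  a <- E - eps1 + 1i * gamma_L / 2
  d <- E - eps2 + 1i * gamma_R / 2
  det <- a * d - t^2
  g12 <- t / det # off-diagonal of the inverse (sign cancels in |.|^2)
  gamma_L * gamma_R * Mod(g12)^2
}

# Landauer current through a Lorentzian channel at finite temperature:
# integral of gamma^2 / ((E-eps)^2 + gamma^2) * f(E; mu, kT) equals
# gamma * (pi/2 - Im psi(1/2 + (gamma + i(eps - mu)) / (2 pi kT))), with the
# imaginary part of the digamma evaluated by its convergent series
# Im psi(x + iy) = sum_{k>=0} y / ((k + x)^2 + y^2).
im_digamma <- function(x, y, n_terms = 2e6) {
  k <- seq(0, n_terms)
  sum(y / ((k + x)^2 + y^2))
}

lorentzian_fermi_integral <- function(gamma, eps, mu, kT) {
  x <- 0.5 + gamma / (2 * pi * kT)
  y <- (eps - mu) / (2 * pi * kT)
  gamma * (pi / 2 - im_digamma(x, y))
}

single_site_current_oracle <- function(eps, gamma, E_fL, V_bias, kT) {
  # equal couplings gamma_L = gamma_R = gamma; total half-width gamma
  pref <- dnarom::dna_constants$prefactor_S
  E_fR <- E_fL + V_bias
  pref * (lorentzian_fermi_integral(gamma, eps, E_fR, kT) -
    lorentzian_fermi_integral(gamma, eps, E_fL, kT))
}

# dense nodal solve of the crossbar netlist, assembled independently with
# scalar loops (wordline node (i,j) -> index k_w, bitline node -> k_b)
netlist_oracle <- function(m, n, r_int, G_cells, driven_row, v_in) {
  g <- 1 / r_int
  N <- 2 * m * n
  kw <- function(i, j) (j - 1) * m + i
  kb <- function(i, j) m * n + (j - 1) * m + i
  A <- matrix(0, N, N)
  b <- numeric(N)
  add_edge <- function(p, q, w) {
    A[p, p] <<- A[p, p] + w
    A[q, q] <<- A[q, q] + w
    A[p, q] <<- A[p, q] - w
    A[q, p] <<- A[q, p] - w
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      if (j < n) add_edge(kw(i, j), kw(i, j + 1), g)
      if (i < m) add_edge(kb(i, j), kb(i + 1, j), g)
      add_edge(kw(i, j), kb(i, j), G_cells[i, j])
    }
  }
  for (j in seq_len(n)) A[kb(m, j), kb(m, j)] <- A[kb(m, j), kb(m, j)] + g
  s <- kw(driven_row, 1)
  A[s, s] <- A[s, s] + g
  b[s] <- g * v_in
  v <- solve(A, b)
  list(
    V_word = matrix(v[1:(m * n)], m, n),
    V_bit = matrix(v[m * n + 1:(m * n)], m, n)
  )
}

# brute-force optimal threshold: exhaustive scan over a dense grid of
# candidate thresholds spanning the data
threshold_oracle <- function(class0, class1) {
  lo <- min(class0, class1)
  hi <- max(class0, class1)
  cand <- sort(unique(c(
    seq(lo - abs(lo) * 0.1 - 1e-12, hi + abs(hi) * 0.1 + 1e-12, length.out = 2001),
    c(class0, class1) - 1e-15, c(class0, class1) + 1e-15
  )))
  errs <- vapply(cand, function(th) {
    sum(class1 < th) + sum(class0 >= th)
  }, numeric(1))
  min(errs) / (length(class0) + length(class1)) * 100
}
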