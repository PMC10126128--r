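#' Transport parameters for the decoherent Landauer calculation
#'
#' @param E_fL Left-contact Fermi energy (eV). Usually anchored at (or `delta`
#'   above) the HOMO transmission peak of the strand.
#' @param V_bias Applied bias (V). The right-contact Fermi level is
#'   `E_fR = E_fL + q V_bias`.
#' @param gamma_L,gamma_R Contact coupling strengths (eV). Default 1 eV.
#' @param gamma_probe Coupling of each dephasing probe (eV). Default 10 meV.
#' @param kT Thermal energy (eV). Default 0.0259 eV (300 K).
#' @param energy_grid Optional explicit energy grid (eV, strictly increasing)
#'   for the current integral. When `NULL`, a uniform grid of step
#'   `energy_step` spanning the Fermi window plus a `10 kT` margin on each
#'   side is built automatically.
#' @param energy_step Grid step (eV) for the automatic grid. Default 1 meV,
#'   fine enough to resolve the 10 meV probe broadening.
#' @return A `transport_params` list.
#' @export
transport_params <- function(E_fL, V_bias = 0, gamma_L = 1.0, gamma_R = 1.0,
                             gamma_probe = 0.010, kT = dna_constants$kT_room_eV,
                             energy_grid = NULL, energy_step = 0.001) {
  if (any(c(gamma_L, gamma_R, gamma_probe) < 0)) {
    abort("Coupling strengths must be non-negative.", class = "dnarom_input_error")
  }
  if (kT <= 0) abort("`kT` must be positive.", class = "dnarom_input_error")
  if (!is.null(energy_grid) && any(diff(energy_grid) <= 0)) {
    abort("`energy_grid` must be strictly increasing.", class = "dnarom_input_error")
  }
  structure(
    list(
      E_fL = E_fL, V_bias = V_bias, gamma_L = gamma_L, gamma_R = gamma_R,
      gamma_probe = gamma_probe, kT = kT, energy_grid = energy_grid,
      energy_step = energy_step
    ),
    class = "transport_params"
  )
}

#' Contact and dephasing-probe self-energies for a blocked Hamiltonian
#'
#' Attaches wide-band contact self-energies `-i Gamma_L(R)/2` to the orbitals
#' of the 3' and 5' terminal nucleotides and a dephasing probe
#' `-i Gamma_k/2` to every other nucleotide block. Probes absorb and re-inject
#' carriers with randomized phase and are constrained (in
#' [effective_transmission()]) to carry zero net current at every energy.
#'
#' @param hb A `block_hamiltonian`.
#' @param params A [transport_params()].
#' @return A `self_energy_set`: `labels` (terminal names, L first, R last),
#'   `sites` (orbital indices per terminal), `gamma` (eV per terminal),
#'   `probe_sites` (nucleotide indices), `N_b` (probe count), and
#'   `gamma_diag`, the orbital-resolved total broadening.
#' @export
self_energy_set <- function(hb, params) {
  stopifnot(inherits(hb, "block_hamiltonian"))
  probe_nucs <- setdiff(seq_len(hb$N_nuc), hb$contact_sites)
  probe_labels <- if (length(probe_nucs)) paste0("P", probe_nucs) else character(0)
  labels <- c("L", probe_labels, "R")
  sites <- c(
    list(hb$blocks[[hb$contact_sites[1]]]),
    hb$blocks[probe_nucs],
    list(hb$blocks[[hb$contact_sites[2]]])
  )
  gamma <- c(
    params$gamma_L, rep(params$gamma_probe, length(probe_nucs)),
    params$gamma_R
  )
  gamma_diag <- numeric(nrow(hb$H))
  for (k in seq_along(sites)) gamma_diag[sites[[k]]] <- gamma_diag[sites[[k]]] + gamma[k]
  structure(
    list(
      labels = labels, sites = sites, gamma = gamma,
      probe_sites = probe_nucs, N_b = length(probe_nucs),
      gamma_diag = gamma_diag
    ),
    class = "self_energy_set"
  )
}

#' Retarded Green's function at one energy
#'
#' Solves `[E - (H_b + Sigma_L + Sigma_R + Sigma_B)] G^r = I` with the
#' diagonal wide-band self-energies of `se`. The advanced function is
#' `G^a = Conj(t(G^r))`.
#'
#' @param E Energy (eV).
#' @param hb A `block_hamiltonian` (bias ramp applied by the caller if any).
#' @param se A [self_energy_set()].
#' @return Complex matrix `G^r`.
#' @export
retarded_green <- function(E, hb, se) {
  n <- nrow(hb$H)
  A <- -hb$H * (1 + 0i)
  diag(A) <- diag(A) + E + 1i * se$gamma_diag / 2
  G <- tryCatch(
    solve(A),
    error = function(e) {
      abort(
        sprintf("Green's function system is numerically singular at E = %g eV.", E),
        class = "dnarom_singular_error"
      )
    }
  )
  G
}

#' Terminal-to-terminal transmission matrix at one energy
#'
#' Computes `T_kl = Tr_block(Gamma_k G^r Gamma_l G^a)` for every ordered pair
#' of terminals (left contact, dephasing probes, right contact); with the
#' diagonal wide-band couplings this reduces to
#' `gamma_k gamma_l * sum(|G^r[block_k, block_l]|^2)`. Also returns the
#' reflection probabilities `R_kk = 1 - sum_{l != k} T_kl` and the probe
#' elimination matrix `W` (`W_kk = 1 - R_kk`, `W_kl = -T_kl` off-diagonal,
#' probes only).
#'
#' @param G Retarded Green's function from [retarded_green()].
#' @param hb The `block_hamiltonian` used to compute `G`.
#' @param se The matching [self_energy_set()].
#' @param E Energy (eV), carried through for bookkeeping.
#' @return A `transmission_result` with fields `E`, `T_kl` (labeled matrix),
#'   `T_LR`, `R_kk`, `W`, `labels`, `N_b`.
#' @export
transmission_matrix <- function(G, hb, se, E = NA_real_) {
  K <- length(se$labels)
  absG2 <- Mod(G)^2
  Tm <- matrix(0, K, K, dimnames = list(se$labels, se$labels))
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      if (l == k) next
      Tm[k, l] <- se$gamma[k] * se$gamma[l] *
        sum(absG2[se$sites[[k]], se$sites[[l]], drop = FALSE])
    }
  }
  row_tot <- rowSums(Tm)
  R_kk <- 1 - row_tot
  probes <- which(!se$labels %in% c("L", "R"))
  W <- -Tm[probes, probes, drop = FALSE]
  # 1 - R_kk written as the direct row sum to avoid cancellation when the
  # probe couplings are taken to the coherent limit
  diag(W) <- row_tot[probes]
  structure(
    list(
      E = E, T_kl = Tm, T_LR = Tm["L", "R"], R_kk = R_kk, W = W,
      labels = se$labels, N_b = se$N_b
    ),
    class = "transmission_result"
  )
}

#' Effective transmission after probe elimination
#'
#' Eliminates the zero-net-current dephasing probes, giving
#' `T_eff = T_LR + sum_kl T_Lk W^{-1}_kl T_lR`: the coherent left-right
#' transmission plus the probe-mediated incoherent contribution. With no
#' probes this is exactly `T_LR`.
#'
#' @param tr A [transmission_matrix()] result.
#' @return Scalar effective transmission, with the reciprocal condition number
#'   of `W` attached as attribute `"rcond"` when probes are present.
#' @export
effective_transmission <- function(tr) {
  if (tr$N_b == 0L) {
    return(tr$T_LR)
  }
  probes <- setdiff(tr$labels, c("L", "R"))
  rc <- rcond(tr$W)
  if (!is.finite(rc) || rc < 1e-14) {
    abort(
      sprintf("Probe elimination matrix W is singular (rcond = %.3g).", rc),
      class = "dnarom_elimination_error"
    )
  }
  x <- solve(tr$W, tr$T_kl[probes, "R"])
  t_eff <- tr$T_LR + drop(tr$T_kl["L", probes, drop = FALSE] %*% x)
  attr(t_eff, "rcond") <- rc
  t_eff
}

#' Energy-resolved coherent and effective transmission
#'
#' @param hb A `block_hamiltonian` (ramped if a bias is intended).
#' @param params A [transport_params()].
#' @param energies Energy grid (eV).
#' @return A tibble with columns `energy_eV`, `T_LR`, `T_eff`, of class
#'   `transmission_spectrum`.
#' @export
transmission_spectrum <- function(hb, params, energies) {
  se <- self_energy_set(hb, params)
  t_lr <- numeric(length(energies))
  t_eff <- numeric(length(energies))
  for (i in seq_along(energies)) {
    tr <- transmission_matrix(retarded_green(energies[i], hb, se), hb, se,
      E = energies[i]
    )
    t_lr[i] <- tr$T_LR
    t_eff[i] <- as.numeric(effective_transmission(tr))
  }
  out <- tibble(energy_eV = energies, T_LR = t_lr, T_eff = t_eff)
  class(out) <- c("transmission_spectrum", class(out))
  out
}

fermi <- function(E, mu, kT) 1 / (1 + exp((E - mu) / kT))

# Probe occupation factors implied by the zero-net-current condition,
# f_k - f_L = (W^{-1} T_{kR}) (f_R - f_L), and the reconstructed per-terminal
# spectral currents J_k(E) = sum_l T_kl (f_k - f_l). Used by tests to verify
# that probes carry no current at any energy and that I_L + I_R = 0.
probe_spectral_currents <- function(tr, f_L, f_R) {
  labels <- tr$labels
  probes <- setdiff(labels, c("L", "R"))
  f <- setNames(numeric(length(labels)), labels)
  f["L"] <- f_L
  f["R"] <- f_R
  if (length(probes)) {
    rhs <- tr$T_kl[probes, "R"]
    phi <- solve(tr$W, rhs)
    # two steps of iterative refinement: the balance residual is otherwise
    # limited by the conditioning of W rather than by the elimination itself
    for (k in 1:2) phi <- phi + solve(tr$W, rhs - tr$W %*% phi)
    f[probes] <- f_L + drop(phi) * (f_R - f_L)
  }
  J <- vapply(labels, function(k) {
    sum(tr$T_kl[k, ] * (f[k] - f))
  }, numeric(1))
  # cancellation scale of J_k: the sum of unsigned in/out flow magnitudes
  gross <- vapply(labels, function(k) {
    sum(tr$T_kl[k, ] * (abs(f[k]) + abs(f)))
  }, numeric(1))
  list(f = f, J = J, gross = gross)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1))) / 2

default_energy_grid <- function(params) {
  E_fR <- params$E_fL + params$V_bias
  lo <- min(params$E_fL, E_fR) - 10 * params$kT
  hi <- max(params$E_fL, E_fR) + 10 * params$kT
  seq(lo, hi + params$energy_step, by = params$energy_step)
}

#' Terminal current through the strand at one bias point
#'
#' Landauer integral with probe-eliminated effective transmission:
#' `I = (2 q^2 / h) * integral T_eff(E) [f_R(E) - f_L(E)] dE` with
#' `E_fR = E_fL + q V_bias`. The sign convention makes the current positive
#' for positive bias through a conducting channel. Trapezoidal integration on
#' the params' energy grid.
#'
#' @param hb A `block_hamiltonian` with the bias ramp for `params$V_bias`
#'   already applied.
#' @param params A [transport_params()].
#' @param spectrum Optional precomputed [transmission_spectrum()] covering the
#'   integration window (reused across Fermi offsets by [iv_sweep()]).
#' @return Current (A).
#' @export
terminal_current <- function(hb, params, spectrum = NULL) {
  if (params$V_bias == 0) {
    return(0)
  }
  E_fR <- params$E_fL + params$V_bias
  grid <- params$energy_grid %||% default_energy_grid(params)
  if (is.null(spectrum)) {
    spectrum <- transmission_spectrum(hb, params, grid)
  } else {
    lo <- min(params$E_fL, E_fR) - 10 * params$kT
    hi <- max(params$E_fL, E_fR) + 10 * params$kT
    if (min(spectrum$energy_eV) > lo + 1e-9 || max(spectrum$energy_eV) < hi - 1e-9) {
      abort("Energy grid does not cover the Fermi window plus 10 kT margin.",
        class = "dnarom_integration_error"
      )
    }
  }
  occ <- fermi(spectrum$energy_eV, E_fR, params$kT) -
    fermi(spectrum$energy_eV, params$E_fL, params$kT)
  dna_constants$prefactor_S * trapz(spectrum$energy_eV, spectrum$T_eff * occ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate transmission peaks
#'
#' Finds local maxima of an energy-resolved transmission that rise above a
#' relative prominence threshold. Used to track the HOMO resonance and its
#' bias-induced shift.
#'
#' @param energy Energy grid (eV).
#' @param transmission Transmission values on the grid.
#' @param rel_height Minimum peak height relative to the global maximum.
#' @return A tibble `energy_eV`, `height`, ordered by energy; zero rows when
#'   no peak qualifies.
#' @export
find_transmission_peaks <- function(energy, transmission, rel_height = 0.01) {
  if (inherits(energy, "transmission_spectrum")) {
    transmission <- energy$T_eff
    energy <- energy$energy_eV
  }
  n <- length(transmission)
  if (n < 3L) {
    return(tibble(energy_eV = numeric(), height = numeric()))
  }
  y <- transmission
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_peak <- is_peak & y >= rel_height * max(y)
  tibble(energy_eV = energy[is_peak], height = y[is_peak])
}

#' Energy of the HOMO transmission peak
#'
#' The highest-energy prominent peak of the effective transmission: the top
#' of the occupied-orbital band, i.e. the resonance that anchors the Fermi
#' energy in this device model. Peaks below `rel_height` of the global
#' maximum are treated as shoulders and ignored.
#'
#' @param spectrum A [transmission_spectrum()].
#' @inheritParams find_transmission_peaks
#' @return Peak energy (eV), or `NA` if no peak is found.
#' @export
homo_peak_energy <- function(spectrum, rel_height = 0.2) {
  pk <- find_transmission_peaks(spectrum$energy_eV, spectrum$T_eff, rel_height)
  if (nrow(pk) == 0L) {
    return(NA_real_)
  }
  max(pk$energy_eV)
}
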