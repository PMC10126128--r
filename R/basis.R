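#' Assemble an atomic-basis electronic-structure system
#'
#' Bundles the Fock matrix `F` (eV) and overlap matrix `S` (dimensionless) of
#' a DNA duplex together with the orbital-to-nucleotide partition and the
#' base-pair grouping of nucleotides. This is the entry point for transport
#' calculations starting from quantum-chemistry output; surrogate tight-binding
#' fixtures bypass it via [surrogate_hamiltonian()].
#'
#' @param F Real symmetric Fock matrix (eV).
#' @param S Real symmetric positive-definite overlap matrix, same dimension.
#' @param partition List of integer vectors, one per nucleotide in strand
#'   order, giving the orbital (row/column) indices belonging to that
#'   nucleotide. Ranges must be disjoint and cover every orbital index.
#' @param basepair_groups List of length-2 integer vectors pairing nucleotide
#'   indices into base pairs, in base-pair order along the duplex. Every
#'   nucleotide must appear exactly once.
#'
#' @return An object of class `atomic_basis_system`.
#' @export
#' @examples
#' sys <- atomic_basis_system(
#'   F = diag(c(-5, -5.5)), S = diag(2),
#'   partition = list(1L, 2L), basepair_groups = list(c(1L, 2L))
#' )
atomic_basis_system <- function(F, S, partition, basepair_groups) {
  F <- as.matrix(F)
  S <- as.matrix(S)
  if (!is.numeric(F) || !is.numeric(S)) {
    abort("`F` and `S` must be numeric matrices.", class = "dnarom_input_error")
  }
  if (nrow(F) != ncol(F) || nrow(S) != ncol(S) || nrow(F) != nrow(S)) {
    abort(
      sprintf(
        "`F` (%dx%d) and `S` (%dx%d) must be square and of equal dimension.",
        nrow(F), ncol(F), nrow(S), ncol(S)
      ),
      class = "dnarom_input_error"
    )
  }
  partition <- lapply(partition, function(ix) sort(as.integer(ix)))
  all_ix <- unname(sort(unlist(partition)))
  if (any(lengths(partition) == 0L)) {
    abort("Every partition range must contain at least one orbital.",
      class = "dnarom_input_error"
    )
  }
  if (!identical(all_ix, seq_len(nrow(F)))) {
    abort("Partition ranges must be disjoint and cover all orbital indices.",
      class = "dnarom_input_error"
    )
  }
  basepair_groups <- lapply(basepair_groups, as.integer)
  nucs <- unname(sort(unlist(basepair_groups)))
  if (!identical(nucs, seq_along(partition))) {
    abort("`basepair_groups` must cover every nucleotide exactly once.",
      class = "dnarom_input_error"
    )
  }
  structure(
    list(F = F, S = S, partition = partition, basepair_groups = basepair_groups),
    class = "atomic_basis_system"
  )
}

#' @export
print.atomic_basis_system <- function(x, ...) {
  cat(
    "<atomic_basis_system> ", nrow(x$F), " orbitals, ",
    length(x$partition), " nucleotides, ",
    length(x$basepair_groups), " base pairs\n",
    sep = ""
  )
  invisible(x)
}

#' Loewdin symmetric orthogonalization
#'
#' Maps the generalized eigenproblem `(F, S)` of a non-orthogonal atomic basis
#' to an ordinary one by forming `H_a = S^(-1/2) F S^(-1/2)`. The spectrum of
#' `H_a` equals the generalized eigenvalues of `(F, S)`.
#'
#' @param system An [atomic_basis_system()].
#' @param tol Relative tolerance below which an overlap eigenvalue is treated
#'   as non-positive.
#' @return The orthogonalized Hamiltonian `H_a` (real symmetric matrix, eV).
#' @export
#' @examples
#' sys <- atomic_basis_system(
#'   F = matrix(c(0, 1, 1, 0), 2), S = diag(2),
#'   partition = list(1L, 2L), basepair_groups = list(c(1L, 2L))
#' )
#' lowdin_orthogonalize(sys) # identity overlap: H_a == F
lowdin_orthogonalize <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "atomic_basis_system"))
  es <- eigen(system$S, symmetric = TRUE)
  lam <- es$values
  if (min(lam) <= tol * max(abs(lam))) {
    abort(
      sprintf(
        "Overlap matrix is not positive definite: smallest eigenvalue %.6g.",
        min(lam)
      ),
      class = "dnarom_overlap_error"
    )
  }
  s_inv_sqrt <- es$vectors %*% (t(es$vectors) / sqrt(lam))
  h <- s_inv_sqrt %*% system$F %*% s_inv_sqrt
  (h + t(h)) / 2
}

# Eigenvectors of one nucleotide sub-block, ascending eigenvalue, sign fixed
# so the largest-magnitude component of each vector is positive. Degeneracies
# keep eigen()'s ordering (original-index tie-break); the resulting H_b is
# unique up to a rotation inside the degenerate subspace, which no
# spectrum-level quantity sees.
block_eigvecs <- function(sub) {
  es <- eigen(sub, symmetric = TRUE)
  ord <- order(es$values)
  vec <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vec))) {
    i_max <- which.max(abs(vec[, k]))
    if (vec[i_max, k] < 0) vec[, k] <- -vec[, k]
  }
  vec
}

#' Block-diagonalize an orthogonal Hamiltonian by nucleotide
#'
#' Builds the block transform `U` from the eigenvectors of each nucleotide's
#' diagonal sub-block of `H_a` and returns `H_b = t(U) %*% H_a %*% U`. The
#' diagonal entries of each diagonal block of `H_b` are the molecular-orbital
#' energies of that nucleotide; off-diagonal blocks are inter-nucleotide
#' electronic couplings. The spectrum and trace of `H_a` are preserved.
#'
#' @param H_a Orthogonalized Hamiltonian (real symmetric, eV), e.g. from
#'   [lowdin_orthogonalize()].
#' @param partition List of orbital-index vectors, one per nucleotide.
#' @param basepair_groups List of nucleotide-index pairs (base pairs).
#' @param contact_sites Length-2 integer vector: nucleotide indices of the 3'
#'   and 5' terminal contact sites. Defaults to the two nucleotides of the
#'   first and last base pair that lie on the first strand (nucleotide 1 and
#'   the first member of the last base-pair group).
#' @return A `block_hamiltonian` object: fields `H` (the blocked matrix), `U`,
#'   `blocks` (orbital indices per nucleotide), `contact_sites`,
#'   `basepair_groups`, `N` (base pairs), `N_nuc`.
#' @export
block_diagonalize <- function(H_a, partition, basepair_groups,
                              contact_sites = NULL) {
  H_a <- as.matrix(H_a)
  n <- nrow(H_a)
  partition <- lapply(partition, as.integer)
  if (any(lengths(partition) == 0L)) {
    abort("Empty partition range.", class = "dnarom_input_error")
  }
  if (!identical(unname(sort(unlist(partition))), seq_len(n))) {
    abort("Partition inconsistent with Hamiltonian dimension.",
      class = "dnarom_input_error"
    )
  }
  U <- matrix(0, n, n)
  for (ix in partition) {
    U[ix, ix] <- block_eigvecs(H_a[ix, ix, drop = FALSE])
  }
  H_b <- crossprod(U, H_a) %*% U
  H_b <- (H_b + t(H_b)) / 2
  if (is.null(contact_sites)) {
    contact_sites <- c(
      basepair_groups[[1]][1],
      basepair_groups[[length(basepair_groups)]][1]
    )
  }
  block_hamiltonian(
    H = H_b, blocks = partition, basepair_groups = basepair_groups,
    contact_sites = as.integer(contact_sites), U = U
  )
}

#' Construct a nucleotide-blocked Hamiltonian object
#'
#' Low-level constructor used by [block_diagonalize()] and by the surrogate
#' fixture generator.
#'
#' @param H Real symmetric matrix (eV) in the nucleotide-blocked basis.
#' @param blocks List of orbital-index vectors, one per nucleotide.
#' @param basepair_groups List of nucleotide-index pairs.
#' @param contact_sites Nucleotide indices of the two contact sites.
#' @param U Orthogonal transform that produced `H` (or `NULL`).
#' @param ramp Per-base-pair potentials already folded into `H` (V), or `NULL`.
#' @return A `block_hamiltonian`.
#' @export
block_hamiltonian <- function(H, blocks, basepair_groups, contact_sites,
                              U = NULL, ramp = NULL) {
  H <- as.matrix(H)
  structure(
    list(
      H = H,
      U = U,
      blocks = lapply(blocks, as.integer),
      contact_sites = as.integer(contact_sites),
      basepair_groups = lapply(basepair_groups, as.integer),
      N = length(basepair_groups),
      N_nuc = length(blocks),
      ramp = ramp
    ),
    class = "block_hamiltonian"
  )
}

#' @export
print.block_hamiltonian <- function(x, ...) {
  cat(
    "<block_hamiltonian> ", nrow(x$H), " orbitals, ", x$N_nuc,
    " nucleotides, ", x$N, " base pairs; contacts at nucleotides ",
    x$contact_sites[1], " and ", x$contact_sites[2], "\n",
    sep = ""
  )
  if (!is.null(x$ramp)) {
    cat("  bias ramp applied: V_N =", x$ramp[length(x$ramp)], "V\n")
  }
  invisible(x)
}

#' Per-base-pair potentials of the linear-ramp bias profile
#'
#' 40% of the applied bias drops at each contact and the remaining 20% drops
#' linearly along the interior base pairs: `V_1 = 0`, `V_N = V_bias`, and
#' `V_n = V_bias * (0.4 + 0.2 (n - 2) / (N - 3))` for `2 <= n <= N - 1`.
#'
#' @param N Number of base pairs (must be at least 4; the interior formula
#'   divides by `N - 3`).
#' @param V_bias Applied bias (V).
#' @return Numeric vector of length `N` (V).
#' @export
#' @examples
#' bias_ramp_voltages(7, 1) # 0.00 0.40 0.45 0.50 0.55 0.60 1.00
bias_ramp_voltages <- function(N, V_bias) {
  N <- as.integer(N)
  if (N <= 3L) {
    abort(
      sprintf("Bias ramp needs at least 4 base pairs (got N = %d).", N),
      class = "dnarom_geometry_error"
    )
  }
  n <- seq_len(N)
  # rational form (2(N-3) + (n-2)) / (5(N-3)) so the n = 2 and n = N-1
  # endpoints evaluate to exactly 0.4 and 0.6 in floating point
  v <- V_bias * (2 * (N - 3) + (n - 2)) / (5 * (N - 3))
  v[1] <- 0
  v[N] <- V_bias
  v
}

#' Apply the bias-dependent potential ramp to a blocked Hamiltonian
#'
#' Adds the electrostatic potential energy `q V_n` (numerically `V_n` eV per
#' volt of potential, with `q` one elementary charge) to every diagonal entry
#' of both nucleotide blocks of base pair `n`. Off-diagonal couplings are
#' untouched. The ramp follows [bias_ramp_voltages()].
#'
#' @param hb A `block_hamiltonian` without a previously applied ramp.
#' @param V_bias Applied bias (V).
#' @return A new `block_hamiltonian` with shifted diagonals and the ramp
#'   recorded in its `ramp` field.
#' @export
apply_bias_ramp <- function(hb, V_bias) {
  stopifnot(inherits(hb, "block_hamiltonian"))
  v_n <- bias_ramp_voltages(hb$N, V_bias)
  H <- hb$H
  for (p in seq_len(hb$N)) {
    orbitals <- unlist(hb$blocks[hb$basepair_groups[[p]]])
    idx <- cbind(orbitals, orbitals)
    H[idx] <- H[idx] + v_n[p]
  }
  block_hamiltonian(
    H = H, blocks = hb$blocks, basepair_groups = hb$basepair_groups,
    contact_sites = hb$contact_sites, U = hb$U, ramp = v_n
  )
}
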