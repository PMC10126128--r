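# Nodal analysis of the crossbar ladder network. Every cell has a wordline
# node and a bitline node; adjacent cells are joined by interconnect segments
# g = 1/R_int along wordlines and bitlines; the driven row is fed V_in through
# a segment at its first cell; floating rows have no external connection; each
# bitline is grounded through a segment below its last row. Node ordering:
# wordline nodes (column-major m x n), then bitline nodes.

kirchhoff_edges <- function(m, n) {
  mn <- m * n
  widx <- function(i, j) (j - 1L) * m + i
  bidx <- function(i, j) mn + (j - 1L) * m + i
  iw <- rep(seq_len(m), n - 1L)
  jw <- rep(seq_len(n - 1L), each = m)
  ib <- rep(seq_len(m - 1L), n)
  jb <- rep(seq_len(n), each = m - 1L)
  ic <- rep(seq_len(m), n)
  jc <- rep(seq_len(n), each = m)
  list(
    m = m, n = n, N = 2L * mn,
    from = c(widx(iw, jw), bidx(ib, jb), widx(ic, jc)),
    to = c(widx(iw, jw + 1L), bidx(ib + 1L, jb), bidx(ic, jc)),
    n_int = length(iw) + length(ib), # leading interconnect edges
    ground_nodes = bidx(m, seq_len(n)),
    word_in = widx(seq_len(m), 1L)
  )
}

# assemble the (symmetric positive definite) nodal conductance matrix;
# driven_row = NULL omits the source segment (used by the sneak-parameter
# calibration, which adds it back as a rank-1 update)
kirchhoff_matrix <- function(ed, g_int, G_cells, driven_row = NULL) {
  w <- c(rep(g_int, ed$n_int), as.vector(G_cells))
  diag_extra <- numeric(ed$N)
  diag_extra[ed$ground_nodes] <- g_int
  if (!is.null(driven_row)) {
    s <- ed$word_in[driven_row]
    diag_extra[s] <- diag_extra[s] + g_int
  }
  dn <- which(diag_extra != 0)
  forceSymmetric(sparseMatrix(
    i = c(ed$from, ed$to, ed$from, ed$to, dn),
    j = c(ed$to, ed$from, ed$from, ed$to, dn),
    x = c(-w, -w, w, w, diag_extra[dn]),
    dims = c(ed$N, ed$N)
  ))
}

kirchhoff_linear_solve <- function(ed, g_int, G_cells, driven_row, v_in) {
  A <- kirchhoff_matrix(ed, g_int, G_cells, driven_row)
  b <- numeric(ed$N)
  b[ed$word_in[driven_row]] <- g_int * v_in
  v <- as.numeric(solve(A, b))
  resid <- max(abs(A %*% v - b))
  mn <- ed$m * ed$n
  list(
    V_word = matrix(v[seq_len(mn)], ed$m, ed$n),
    V_bit = matrix(v[mn + seq_len(mn)], ed$m, ed$n),
    kcl_residual = resid
  )
}

#' Solve one biased row of the crossbar by Kirchhoff nodal analysis
#'
#' The reference solver: full nodal analysis of the resistive ladder
#' network, iterated until every cell satisfies its nonlinear I-V at the
#' converged node voltages and every internal node satisfies KCL. Two
#' mathematically equivalent iterations to the same fixed point are
#' provided. `"source"` (default) keeps the linear interconnect network
#' fixed - factorized once and cached on the spec - and re-injects each
#' cell's table current as a nonlinear source; because the cell
#' conductances are orders of magnitude below the interconnect conductance
#' this contracts in a handful of cached triangular solves. `"secant"`
#' relinearizes each cell at its operating point through the I-V secant and
#' refactorizes every sweep, starting from the 0.05 V seed conductance with
#' adaptive damping on oscillation.
#'
#' @param spec A [crossbar_spec()].
#' @param driven_row Row index receiving `v_in`.
#' @param tol Convergence tolerance on the max cell-voltage change (V).
#' @param max_iter Maximum number of linearized solves.
#' @param damping Relaxation factor applied to the conductance update when
#'   the secant iteration starts oscillating.
#' @param G_init Optional initial cell conductance matrix (warm start,
#'   secant method).
#' @param method `"source"` or `"secant"`.
#' @return A `crossbar_state`: cell voltages `V` (m x n), cell currents
#'   `I_cell`, bitline read-out currents `I_out` (length n), wordline and
#'   bitline node voltages, iteration count, `max_dV`, `kcl_residual`,
#'   `power_W`, and `solver = "kirchhoff"`.
#' @export
solve_kirchhoff <- function(spec, driven_row = 1L, tol = 1e-6,
                            max_iter = 400L, damping = 0.5, G_init = NULL,
                            method = c("source", "secant")) {
  stopifnot(inherits(spec, "crossbar_spec"))
  method <- match.arg(method)
  if (method == "source") {
    return(solve_kirchhoff_source(spec, driven_row, tol, max_iter, damping))
  }
  ed <- kirchhoff_edges(spec$m, spec$n)
  G <- as.vector(G_init %||% spec$g_seed)
  V_old <- NULL
  dv_prev <- Inf
  lambda <- 1 # relaxation on the conductance update; halved on stagnation
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    sol <- kirchhoff_linear_solve(ed, spec$g_int, G, driven_row, spec$v_in)
    V_cell <- sol$V_word - sol$V_bit
    if (!is.null(V_old)) {
      dv <- max(abs(V_cell - V_old))
      history <- c(history, dv)
      # a damped step understates the distance to the fixed point by the
      # relaxation factor, so the acceptance threshold scales with lambda
      if (dv < tol * lambda) {
        V_old <- V_cell
        break
      }
      if (dv > dv_prev) {
        lambda <- max(lambda * damping, 0.01)
      } else if (dv < 0.9 * dv_prev) {
        lambda <- min(1, lambda * 1.25)
      }
      dv_prev <- dv
    }
    V_old <- V_cell
    G_new <- cell_conductance_at(spec, V_cell)
    G <- lambda * G_new + (1 - lambda) * G
    if (it == max_iter) {
      abort(
        paste0(
          "Kirchhoff iteration did not converge; |dV| history: ",
          paste(signif(tail(history, 5), 3), collapse = ", ")
        ),
        class = "dnarom_convergence_error"
      )
    }
  }
  V_cell <- V_old
  I_cell <- matrix(G * as.vector(V_cell), spec$m, spec$n)
  I_out <- spec$g_int * sol$V_bit[spec$m, ]
  new_crossbar_state(
    spec = spec, driven_row = driven_row, solver = "kirchhoff",
    V = V_cell, I_cell = I_cell, I_out = I_out,
    V_word = sol$V_word, V_bit = sol$V_bit, G = matrix(G, spec$m, spec$n),
    iterations = it, max_dV = if (length(history)) tail(history, 1) else 0,
    kcl_residual = sol$kcl_residual
  )
}

# Fixed-network current-source iteration. The interconnect network plus a
# constant reference conductance per cell is factorized once (CHOLMOD factor
# cached on the spec); each sweep re-injects the difference between the
# cell's true table current and the reference-linear current as a nodal
# source, and the per-row source segment enters through a rank-one
# Sherman-Morrison update. Contraction rate ~ G_cell/g_int, so a few cached
# triangular solves reach the same fixed point as the secant sweep.
solve_kirchhoff_source <- function(spec, driven_row, tol = 1e-6,
                                   max_iter = 400L, damping = 0.5) {
  cache <- spec$cache
  if (is.null(cache$ed)) {
    cache$ed <- kirchhoff_edges(spec$m, spec$n)
    # per-cell reference: each cell's low-bias secant, so floating-row
    # cells (which sit near zero bias) carry almost no source correction
    cache$gref <- as.vector(spec$g_seed)
    cache$J0 <- kirchhoff_matrix(cache$ed, spec$g_int, cache$gref,
      driven_row = NULL
    )
    cache$y <- vector("list", spec$m)
  }
  ed <- cache$ed
  g <- spec$g_int
  gref <- cache$gref
  s <- ed$word_in[driven_row]
  if (is.null(cache$y[[driven_row]])) {
    e <- numeric(ed$N)
    e[s] <- 1
    cache$y[[driven_row]] <- as.numeric(solve(cache$J0, e))
  }
  y <- cache$y[[driven_row]]
  sm_solve <- function(r) {
    z <- as.numeric(solve(cache$J0, r))
    z - y * (g * z[s] / (1 + g * y[s]))
  }
  mn <- spec$m * spec$n
  wi <- seq_len(mn)
  bi <- mn + seq_len(mn)
  b <- numeric(ed$N)
  b[s] <- g * spec$v_in
  v <- sm_solve(b)
  V_cell <- v[wi] - v[bi]
  cres <- numeric(mn)
  lambda <- 1
  dv_prev <- Inf
  dv <- Inf
  for (it in seq_len(max_iter)) {
    I_true <- cell_current_at(spec$curves, V_cell)
    cres_new <- I_true - gref * V_cell
    cres <- lambda * cres_new + (1 - lambda) * cres
    rhs <- b
    rhs[wi] <- rhs[wi] - cres
    rhs[bi] <- rhs[bi] + cres
    v_new <- sm_solve(rhs)
    V_new <- v_new[wi] - v_new[bi]
    dv <- max(abs(V_new - V_cell))
    v <- v_new
    V_cell <- V_new
    if (dv < tol * lambda) break
    if (dv > dv_prev) {
      lambda <- max(lambda * damping, 0.05)
    } else if (dv < 0.9 * dv_prev) {
      lambda <- min(1, lambda * 1.25)
    }
    dv_prev <- dv
    if (it == max_iter) {
      abort("Kirchhoff source iteration did not converge.",
        class = "dnarom_convergence_error"
      )
    }
  }
  # the accepted state is the exact solution of the linear network
  # (interconnects + gref cells) with the source injections `cres`; report
  # the currents that network actually carries, so KCL and the energy
  # balance hold to solver precision. These differ from the raw table
  # currents by at most ~dI/dV * tol.
  I_cell <- gref * V_cell + cres
  r_true <- as.numeric(cache$J0 %*% v)
  r_true[s] <- r_true[s] + g * v[s]
  r_true <- r_true - b
  r_true[wi] <- r_true[wi] + cres
  r_true[bi] <- r_true[bi] - cres
  G_rep <- ifelse(abs(V_cell) > 1e-300, I_cell / V_cell, gref)
  new_crossbar_state(
    spec = spec, driven_row = driven_row, solver = "kirchhoff",
    V = matrix(V_cell, spec$m, spec$n),
    I_cell = matrix(I_cell, spec$m, spec$n),
    I_out = g * matrix(v[bi], spec$m, spec$n)[spec$m, ],
    V_word = matrix(v[wi], spec$m, spec$n),
    V_bit = matrix(v[bi], spec$m, spec$n),
    G = matrix(G_rep, spec$m, spec$n),
    iterations = it, max_dV = dv, kcl_residual = max(abs(r_true))
  )
}

new_crossbar_state <- function(spec, driven_row, solver, V, I_cell, I_out,
                               V_word = NULL, V_bit = NULL, G = NULL,
                               iterations = NA_integer_, max_dV = NA_real_,
                               kcl_residual = NA_real_) {
  st <- structure(
    list(
      m = spec$m, n = spec$n, driven_row = driven_row, solver = solver,
      V = V, I_cell = I_cell, I_out = I_out, V_word = V_word, V_bit = V_bit,
      G = G, iterations = iterations, max_dV = max_dV,
      kcl_residual = kcl_residual, v_in = spec$v_in, r_int = spec$r_int
    ),
    class = "crossbar_state"
  )
  if (solver == "kirchhoff") st$power_W <- state_power(st, spec)
  st
}

#' @export
print.crossbar_state <- function(x, ...) {
  cat(
    "<crossbar_state> ", x$m, " x ", x$n, " array, row ", x$driven_row,
    " driven (", x$solver, "), ", x$iterations, " iterations, max |dV| = ",
    format(x$max_dV, digits = 3), " V\n",
    sep = ""
  )
  invisible(x)
}

# total dissipated power of one converged Kirchhoff solve: cells plus every
# interconnect segment (wordline, bitline, ground, and source segments)
state_power <- function(st, spec) {
  ed <- kirchhoff_edges(st$m, st$n)
  v <- c(as.vector(st$V_word), as.vector(st$V_bit))
  seg <- seq_len(ed$n_int)
  dv_int <- v[ed$from[seg]] - v[ed$to[seg]]
  p_int <- spec$g_int * sum(dv_int^2) +
    spec$g_int * sum(v[ed$ground_nodes]^2) +
    spec$g_int * (st$v_in - v[ed$word_in[st$driven_row]])^2
  p_cells <- sum(as.vector(st$G) * as.vector(st$V)^2)
  p_cells + p_int
}

#' Source power delivered to a converged Kirchhoff state
#'
#' `V_in` times the current entering the driven wordline. Equals the total
#' dissipated power (cells plus interconnects) by energy conservation.
#'
#' @param state A `crossbar_state` from [solve_kirchhoff()].
#' @return Power (W).
#' @export
source_power <- function(state) {
  if (state$solver != "kirchhoff") {
    abort("Source power requires a Kirchhoff state (branch currents).",
      class = "dnarom_input_error"
    )
  }
  g <- 1 / state$r_int
  state$v_in * g * (state$v_in - state$V_word[state$driven_row, 1])
}

#' Average read power of an array
#'
#' Mean total dissipated power (memory cells and interconnects) over
#' sequential row reads, evaluated on the Kirchhoff solution.
#'
#' @param spec A [crossbar_spec()].
#' @param rows Rows to average over (default all).
#' @param ... Passed to [solve_kirchhoff()].
#' @return Power (W).
#' @export
array_power <- function(spec, rows = seq_len(spec$m), ...) {
  G_warm <- NULL
  p <- numeric(length(rows))
  for (k in seq_along(rows)) {
    st <- solve_kirchhoff(spec, rows[k], G_init = G_warm, ...)
    G_warm <- st$G
    p[k] <- st$power_W
  }
  mean(p)
}
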