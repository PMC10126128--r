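# Fast approximate crossbar model: a closed-form column voltage profile along
# the driven wordline plus row/column sneak-path scale factors alpha_i/beta_j
# calibrated once against the Kirchhoff oracle on a homogeneous average-
# conductance array.

# Column voltage profile for one driven row. form = "calibrated" starts the
# denominator's inner interconnect sum at the first segment, which matches
# the exact wordline ladder to first order in G_cell/g_int; form = "literal"
# keeps the printed empty-sum convention, under which numerator and
# denominator coincide and the profile is flat.
voltage_profile_row <- function(G_row, g_int, v_in, alpha_i,
                                form = c("calibrated", "literal")) {
  form <- match.arg(form)
  if (g_int <= 0) {
    abort("Interconnect conductance must be positive.",
      class = "dnarom_input_error"
    )
  }
  n <- length(G_row)
  S <- seq_len(n) / g_int # cumulative segment resistance to column k
  gs_suffix <- rev(cumsum(rev(G_row * S))) # sum_{k>=j} G_k S_k
  g_suffix <- rev(cumsum(rev(G_row))) # sum_{k>=j} G_k
  shift1 <- function(x) c(x[-1], 0)
  num <- 1 + shift1(gs_suffix) - S * shift1(g_suffix)
  den <- switch(form,
    calibrated = 1 + sum(G_row * S),
    literal = num
  )
  v_in * alpha_i * num / den
}

#' Voltage distribution of one driven row under the parametric model
#'
#' @param spec A [crossbar_spec()].
#' @param conductances Length-`n` vector of cell conductances for the driven
#'   row at the current operating point (S).
#' @param sneak A [estimate_sneak_parameters()] result.
#' @param driven_row Row index.
#' @param form `"calibrated"` (default; denominator interconnect sums start
#'   at the first segment) or `"literal"` (empty-sum convention as printed,
#'   collapsing the profile to `v_in * alpha_i`).
#' @return Length-`n` vector of cell voltages (V).
#' @export
voltage_distribution <- function(spec, conductances, sneak, driven_row,
                                 form = c("calibrated", "literal")) {
  voltage_profile_row(
    conductances, spec$g_int, spec$v_in, sneak$alpha[driven_row],
    form = match.arg(form)
  )
}

#' Calibrate the sneak-path scale factors alpha and beta
#'
#' Solves the homogeneous linear array (every cell at the average conductance
#' `G_avg`) with the Kirchhoff oracle for every driven row - via a rank-one
#' source update of a single factorization - and extracts
#' `alpha_i = mean_j V_ij / (V_in rho_j)` (with `rho_j` the parametric column
#' profile at `G_avg`) and `beta_j = mean_i I_ij / I_cell(V_ij)`. Both
#' factors are independent of the bias voltage (the reference network is
#' linear), degrade away from the driven and grounded edges, and equal 1 in
#' the vanishing-interconnect limit.
#'
#' @param spec A [crossbar_spec()].
#' @param G_avg Average cell conductance (S). Default: mean secant
#'   conductance of the array's cells at `v_in`.
#' @param v_ref Reference bias used for the linear calibration solve (value
#'   irrelevant to the result; exposed for the bias-independence test).
#' @return A `sneak_params`: `alpha` (length m), `beta` (length n), `G_avg`,
#'   `rho` (the Eq.-10 column profile used), and geometry metadata.
#' @export
estimate_sneak_parameters <- function(spec, G_avg = NULL, v_ref = NULL) {
  stopifnot(inherits(spec, "crossbar_spec"))
  if (is.null(G_avg)) {
    G_avg <- mean(cell_conductance_at(spec, rep(spec$v_in, spec$m * spec$n)))
  }
  if (G_avg <= 0) abort("`G_avg` must be positive.", class = "dnarom_input_error")
  v_in <- v_ref %||% spec$v_in
  m <- spec$m
  n <- spec$n
  g <- spec$g_int
  ed <- kirchhoff_edges(m, n)
  A0 <- kirchhoff_matrix(ed, g, rep(G_avg, m * n), driven_row = NULL)
  ch <- Cholesky(A0, LDL = FALSE)
  rho <- voltage_profile_row(rep(G_avg, n), g, 1, 1, form = "calibrated")
  alpha <- numeric(m)
  beta_num <- matrix(0, m, n)
  mn <- m * n
  for (i in seq_len(m)) {
    e <- numeric(ed$N)
    e[ed$word_in[i]] <- 1
    z <- as.numeric(solve(ch, e))
    cc <- g * v_in / (1 + g * z[ed$word_in[i]])
    v <- cc * z
    V_word <- matrix(v[seq_len(mn)], m, n)
    V_bit <- matrix(v[mn + seq_len(mn)], m, n)
    V_cell_row <- V_word[i, ] - V_bit[i, ]
    I_out <- g * V_bit[m, ]
    alpha[i] <- mean(V_cell_row / (v_in * rho))
    beta_num[i, ] <- I_out / (G_avg * V_cell_row)
  }
  structure(
    list(
      alpha = alpha, beta = colMeans(beta_num), G_avg = G_avg, rho = rho,
      m = m, n = n, r_int = spec$r_int
    ),
    class = "sneak_params"
  )
}

#' @export
print.sneak_params <- function(x, ...) {
  cat(
    "<sneak_params> ", x$m, " x ", x$n, ", R_int = ", format(x$r_int),
    " Ohm, G_avg = ", format(x$G_avg, digits = 3), " S\n  alpha range [",
    format(min(x$alpha), digits = 4), ", ", format(max(x$alpha), digits = 4),
    "], beta range [", format(min(x$beta), digits = 4), ", ",
    format(max(x$beta), digits = 4), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Iterate the parametric model to its nonlinear fixed point
#'
#' Seeds every cell with the I-V secant conductance at 0.05 V, then
#' alternates the parametric voltage distribution with the conductance update
#' `G_ij = I_DNA(V_ij) / V_ij` until the largest voltage change drops below
#' `tol`; the update is damped if it starts oscillating. Read-out currents
#' follow as `I_ij = beta_j * I_DNA(V_ij)`.
#'
#' @inheritParams solve_kirchhoff
#' @param sneak Optional precomputed [estimate_sneak_parameters()].
#' @param form Passed to [voltage_distribution()].
#' @return A `crossbar_state` with `solver = "parametric"`; cell voltages
#'   are available for the driven row only (other entries `NA`).
#' @export
iterate_parametric <- function(spec, driven_row = 1L, sneak = NULL,
                               tol = 1e-6, max_iter = 400L, damping = 0.5,
                               form = "calibrated") {
  sneak <- sneak %||% estimate_sneak_parameters(spec)
  res <- parametric_fixed_point(
    spec,
    rows = driven_row, sneak = sneak, tol = tol,
    max_iter = max_iter, damping = damping, form = form
  )
  V <- matrix(NA_real_, spec$m, spec$n)
  V[driven_row, ] <- res$V[1, ]
  I_cell <- matrix(NA_real_, spec$m, spec$n)
  I_cell[driven_row, ] <- res$I[1, ]
  new_crossbar_state(
    spec = spec, driven_row = driven_row, solver = "parametric",
    V = V, I_cell = I_cell, I_out = sneak$beta * res$I[1, ],
    iterations = res$iterations, max_dV = res$max_dV
  )
}

# driven rows are electrically independent in the parametric model, so the
# fixed-point iteration runs on whole matrices at once
parametric_fixed_point <- function(spec, rows, sneak, tol = 1e-6,
                                   max_iter = 400L, damping = 0.5,
                                   form = "calibrated", seed_v = 0.05) {
  nr <- length(rows)
  cells <- as.vector(
    outer(rows, (seq_len(spec$n) - 1L) * spec$m, `+`) # column-major index
  )
  curves <- list(bias = spec$curves$bias, C = spec$curves$C[cells, , drop = FALSE])
  G <- cell_current_at(curves, rep(seed_v, nr * spec$n)) / seed_v
  G <- matrix(G, nr, spec$n)
  V_old <- NULL
  dv_prev <- Inf
  lambda <- 1
  dv <- NA_real_
  for (it in seq_len(max_iter)) {
    V <- t(vapply(seq_len(nr), function(k) {
      voltage_profile_row(G[k, ], spec$g_int, spec$v_in,
        sneak$alpha[rows[k]],
        form = form
      )
    }, numeric(spec$n)))
    if (nr == 1L) V <- matrix(V, 1L, spec$n)
    if (!is.null(V_old)) {
      dv <- max(abs(V - V_old))
      if (dv < tol * lambda) {
        V_old <- V
        break
      }
      if (dv > dv_prev) {
        lambda <- max(lambda * damping, 0.01)
      } else if (dv < 0.9 * dv_prev) {
        lambda <- min(1, lambda * 1.25)
      }
      dv_prev <- dv
    }
    V_old <- V
    Vc <- pmax(V, 1e-12)
    G_new <- matrix(cell_current_at(curves, as.vector(Vc)), nr, spec$n) / Vc
    G <- lambda * G_new + (1 - lambda) * G
    if (it == max_iter) {
      abort("Parametric iteration did not converge.",
        class = "dnarom_convergence_error"
      )
    }
  }
  V <- V_old
  I <- matrix(cell_current_at(curves, pmax(as.vector(V), 0)), nr, spec$n)
  list(V = V, I = I, iterations = it, max_dV = dv)
}
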