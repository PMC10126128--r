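#' Crossbar array specification
#'
#' Binds the stored bit pattern, the two species' I-V lookup tables, the
#' per-cell Fermi offsets, and the electrical parameters of the array. Read
#' scheme: one wordline (row) is driven at `v_in` through an interconnect
#' segment, all other wordlines float, and every bitline (column) is grounded
#' at its bottom through an interconnect segment; adjacent cells are joined
#' by interconnect segments of resistance `r_int` along both wordlines and
#' bitlines.
#'
#' @param bits `m x n` 0/1 matrix; 1 selects the high-conductance species
#'   (`iv1`).
#' @param iv0,iv1 `iv_table`s for the logic-0 and logic-1 species.
#' @param r_int Interconnect resistance between adjacent cells (Ohm).
#' @param v_in Read bias applied to the driven wordline (V; default 1).
#' @param delta Fermi offset (eV): scalar or `m x n` matrix of per-cell
#'   offsets. Must lie inside the tables' delta grids.
#' @return A `crossbar_spec`.
#' @export
crossbar_spec <- function(bits, iv0, iv1, r_int, v_in = 1, delta = 0) {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0L, 1L))) {
    abort("`bits` must be a 0/1 matrix.", class = "dnarom_input_error")
  }
  if (r_int <= 0) abort("`r_int` must be positive.", class = "dnarom_input_error")
  m <- nrow(bits)
  n <- ncol(bits)
  if (length(delta) == 1L) delta <- matrix(delta, m, n)
  delta <- as.matrix(delta)
  stopifnot(dim(delta)[1] == m, dim(delta)[2] == n)
  curves <- build_cell_curves(bits, iv0, iv1, delta)
  g_seed <- cell_current_at(curves, rep(0.05, m * n)) / 0.05
  structure(
    list(
      m = m, n = n, bits = bits, iv0 = iv0, iv1 = iv1,
      r_int = r_int, g_int = 1 / r_int, v_in = v_in, delta = delta,
      curves = curves, g_seed = g_seed,
      cache = new.env(parent = emptyenv())
    ),
    class = "crossbar_spec"
  )
}

#' @export
print.crossbar_spec <- function(x, ...) {
  cat(
    "<crossbar_spec> ", x$m, " x ", x$n, " array, R_int = ",
    format(x$r_int, big.mark = ","), " Ohm, V_in = ", x$v_in, " V, ",
    round(100 * mean(x$bits), 1), "% logic-1 cells\n",
    sep = ""
  )
  invisible(x)
}

# Per-cell current-vs-bias curves on the shared bias grid: each cell's delta
# column interpolation is folded in once, so repeated voltage lookups during
# the nonlinear iteration are a single findInterval pass.
build_cell_curves <- function(bits, iv0, iv1, delta) {
  g0 <- iv_current_matrix(iv0)
  g1 <- iv_current_matrix(iv1)
  if (!isTRUE(all.equal(g0$bias, g1$bias))) {
    abort("The two I-V tables must share a bias grid.",
      class = "dnarom_input_error"
    )
  }
  curve_for <- function(g, dvec) {
    di <- pmin(pmax(findInterval(dvec, g$delta), 1L), length(g$delta) - 1L)
    wd <- (dvec - g$delta[di]) / (g$delta[di + 1L] - g$delta[di])
    if (any(wd < -1e-9 | wd > 1 + 1e-9)) {
      abort("Per-cell Fermi offset outside the tabulated delta grid.",
        class = "dnarom_input_error"
      )
    }
    t(g$I[, di, drop = FALSE]) * (1 - wd) + t(g$I[, di + 1L, drop = FALSE]) * wd
  }
  dvec <- as.vector(delta)
  b <- as.vector(bits)
  curves <- matrix(0, length(b), length(g0$bias))
  if (any(b == 0L)) curves[b == 0L, ] <- curve_for(g0, dvec[b == 0L])
  if (any(b == 1L)) curves[b == 1L, ] <- curve_for(g1, dvec[b == 1L])
  list(bias = g0$bias, C = curves)
}

# currents of all cells at per-cell voltages V (vector, column-major order);
# the junction is symmetric, so the table extends as an odd function to the
# small negative voltages floating-row cells can see
cell_current_at <- function(curves, V) {
  sv <- sign(V)
  av <- abs(V)
  nb <- length(curves$bias)
  k <- pmin(pmax(findInterval(av, curves$bias), 1L), nb - 1L)
  w <- (av - curves$bias[k]) / (curves$bias[k + 1L] - curves$bias[k])
  idx <- seq_along(av)
  sv * (curves$C[cbind(idx, k)] * (1 - w) + curves$C[cbind(idx, k + 1L)] * w)
}

# secant conductances I(V)/V; continuous down to V -> 0, where the
# piecewise-linear table makes the secant equal the first-segment slope
# (the 0.05 V seed secant for the shipped grids), so no 0/0 arises
cell_conductance_at <- function(spec, V, v_floor = 1e-12) {
  av <- pmax(abs(as.vector(V)), v_floor)
  cell_current_at(spec$curves, av) / av
}
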