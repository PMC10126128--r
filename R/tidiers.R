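#' Tidy a crossbar state into a per-cell tibble
#'
#' @param x A `crossbar_state`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `V_cell`, `I_cell`, and for the driven
#'   row the read-out current `I_out`.
#' @export
tidy.crossbar_state <- function(x, ...) {
  grid <- tidyr::expand_grid(col = seq_len(x$n), row = seq_len(x$m))
  out <- tibble(
    row = grid$row, col = grid$col,
    V_cell = as.vector(x$V), I_cell = as.vector(x$I_cell)
  )
  out$I_out <- ifelse(out$row == x$driven_row, x$I_out[out$col], NA_real_)
  out
}

#' @rdname tidy.crossbar_state
#' @export
glance.crossbar_state <- function(x, ...) {
  tibble(
    m = x$m, n = x$n, driven_row = x$driven_row, solver = x$solver,
    iterations = x$iterations, max_dV = x$max_dV,
    kcl_residual = x$kcl_residual,
    power_W = if (is.null(x$power_W)) NA_real_ else x$power_W
  )
}

#' Tidy a Monte Carlo BER report
#'
#' @param x A `ber_report`.
#' @param ... Unused.
#' @return The per-simulation tibble (`tidy`) or a one-row summary
#'   (`glance`).
#' @export
tidy.ber_report <- function(x, ...) x$per_sim

#' @rdname tidy.ber_report
#' @export
glance.ber_report <- function(x, ...) {
  tibble(
    n_sims = x$config$n_sims, m = x$config$m, n = x$config$n,
    r_int_ohm = x$config$r_int, delta_max_eV = x$config$delta_max,
    sampling = x$config$sampling, solver = x$config$solver,
    mean_ber_pct = x$mean_ber_pct, max_ber_pct = x$max_ber_pct,
    mean_voltage_V = x$mean_voltage_V, mean_power_W = x$mean_power_W,
    n_failed = x$n_failed
  )
}

#' Tidy a read-out map into a per-cell tibble
#'
#' @param x A `readout_map`.
#' @param ... Unused.
#' @return Tibble `row, col, bit, I_out, V_cell`.
#' @export
tidy.readout_map <- function(x, ...) {
  grid <- tidyr::expand_grid(col = seq_len(x$n), row = seq_len(x$m))
  tibble(
    row = grid$row, col = grid$col,
    bit = as.vector(x$bits)[ (grid$col - 1L) * x$m + grid$row ],
    I_out = as.vector(x$I_out)[ (grid$col - 1L) * x$m + grid$row ],
    V_cell = as.vector(x$V)[ (grid$col - 1L) * x$m + grid$row ]
  )
}

#' @rdname tidy.readout_map
#' @export
glance.readout_map <- function(x, ...) {
  ber <- readout_ber(x)
  tibble(
    m = x$m, n = x$n, solver = x$solver, r_int_ohm = x$r_int,
    v_in = x$v_in, ber_pct = ber$ber_pct, threshold_A = ber$threshold_A,
    power_W = x$power_W
  )
}
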