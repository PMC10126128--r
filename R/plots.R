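#' Plot an I-V table
#'
#' Current-voltage transfer curves, one line per Fermi offset.
#'
#' @param object An `iv_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iv_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bias_V, y = .data$current_A * 1e9,
    colour = factor(.data$delta_eV), group = .data$delta_eV
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Bias (V)", y = "Current (nA)", colour = "delta (eV)",
      title = paste0("I-V, species ", attr(object, "species"))
    )
}

#' Plot a transmission spectrum
#'
#' Effective and coherent transmission versus energy on a log scale.
#'
#' @param object A [transmission_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transmission_spectrum <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("T_LR", "T_eff"),
    names_to = "component", values_to = "transmission"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$energy_eV, y = .data$transmission, colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Energy (eV)", y = "Transmission")
}

#' Heatmap of a read-out current map
#'
#' @param object A [readout_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.readout_map <- function(object, ...) {
  df <- tidy.readout_map(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$I_out * 1e9
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "Column (bitline)", y = "Row (wordline)", fill = "I (nA)",
      title = paste0("Read-out currents (", object$solver, ")")
    )
}

#' Read-current class distributions and BER histogram of a Monte Carlo run
#'
#' @param object A `ber_report`.
#' @param type `"currents"` (pooled class current histograms) or `"ber"`
#'   (per-simulation BER histogram).
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ber_report <- function(object, type = c("currents", "ber"),
                                bins = 60, ...) {
  type <- match.arg(type)
  if (type == "currents") {
    df <- bind_rows(
      tibble(current_nA = object$class0 * 1e9, class = "logic 0"),
      tibble(current_nA = object$class1 * 1e9, class = "logic 1")
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$current_nA, fill = .data$class)) +
      ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
      ggplot2::labs(x = "Read current (nA)", y = "Cells")
  } else {
    ggplot2::ggplot(object$per_sim, ggplot2::aes(x = .data$ber_pct)) +
      ggplot2::geom_histogram(bins = bins) +
      ggplot2::labs(x = "Bit error rate (%)", y = "Simulations")
  }
}

#' Sneak-path scale factors versus row and column index
#'
#' @param object A `sneak_params`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sneak_params <- function(object, ...) {
  df <- bind_rows(
    tibble(index = seq_along(object$alpha), value = object$alpha, factor = "alpha (row)"),
    tibble(index = seq_along(object$beta), value = object$beta, factor = "beta (column)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = "Index", y = "Scale factor")
}

#' Storage benchmark BER-by-bit-load summary plot
#'
#' @param object A `storage_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.storage_result <- function(object, ...) {
  ggplot2::ggplot(object$ber, ggplot2::aes(
    x = .data$bit_load_pct, y = .data$ber_pct,
    colour = factor(.data$r_int_ohm)
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~size, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Bit load (%)", y = "Bit error rate (%)", colour = "R_int (Ohm)"
    )
}
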