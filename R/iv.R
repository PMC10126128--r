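#' Current-voltage lookup table for one strand species
#'
#' Sweeps bias and Fermi-energy offset, re-applying the potential ramp at
#' every bias point, and tabulates the terminal current. The Fermi offset
#' `delta` raises the left-contact Fermi energy `delta` eV above the anchor
#' (normally the zero-bias HOMO peak); `E_fR = E_fL + q V_bias` throughout.
#' For each bias the effective transmission is computed once on a grid
#' covering the union of all Fermi windows and then integrated per offset.
#'
#' @param hb Unramped `block_hamiltonian` of the species.
#' @param params A [transport_params()]; `params$E_fL` is the anchor energy.
#' @param bias_grid Biases (V), must include 0.
#' @param delta_grid Fermi offsets (eV), non-negative, must include 0.
#' @param species Label stored with the table (e.g. `"CT1C"`).
#' @return An `iv_table`: tibble with columns `bias_V`, `delta_eV`,
#'   `current_A`, plus attributes `species`, `E_fL_anchor`, `bias_grid`,
#'   `delta_grid`.
#' @export
iv_sweep <- function(hb, params, bias_grid, delta_grid, species = "DNA") {
  stopifnot(inherits(hb, "block_hamiltonian"))
  if (!any(bias_grid == 0)) {
    abort("`bias_grid` must include 0.", class = "dnarom_input_error")
  }
  bias_grid <- sort(unique(bias_grid))
  delta_grid <- sort(unique(delta_grid))
  anchor <- params$E_fL
  kT <- params$kT
  rows <- vector("list", length(bias_grid))
  for (bi in seq_along(bias_grid)) {
    v <- bias_grid[bi]
    current <- numeric(length(delta_grid))
    if (v != 0) {
      ramped <- apply_bias_ramp(hb, v)
      mus <- c(anchor + delta_grid, anchor + delta_grid + v)
      grid <- seq(min(mus) - 10 * kT, max(mus) + 10 * kT + params$energy_step,
        by = params$energy_step
      )
      spec <- transmission_spectrum(ramped, params, grid)
      for (di in seq_along(delta_grid)) {
        p <- params
        p$E_fL <- anchor + delta_grid[di]
        p$V_bias <- v
        current[di] <- terminal_current(ramped, p, spectrum = spec)
      }
    }
    rows[[bi]] <- tibble(
      bias_V = v, delta_eV = delta_grid, current_A = current
    )
  }
  out <- bind_rows(rows)
  out <- new_iv_table(out,
    species = species, E_fL_anchor = anchor,
    bias_grid = bias_grid, delta_grid = delta_grid
  )
  # record the bias-monotonicity check: worst relative backward step over
  # all offset columns (0 or positive means nondecreasing throughout)
  g <- iv_current_matrix(out)
  steps <- apply(g$I, 2, function(col) {
    if (max(col) == 0) 0 else min(diff(col)) / max(col)
  })
  attr(out, "monotone_check") <- list(
    worst_step_rel = min(steps),
    nondecreasing = min(steps) >= 0
  )
  out
}

#' Ideal linear-resistor I-V table
#'
#' Ohmic lookup table (`I = V / resistance`, independent of the Fermi
#' offset), used for circuit-level verification against hand-solvable
#' networks.
#'
#' @param resistance Cell resistance (Ohm).
#' @param bias_grid Biases (V).
#' @param delta_grid Fermi offsets (eV).
#' @param species Label.
#' @return An `iv_table`.
#' @export
linear_iv_table <- function(resistance, bias_grid = seq(0, 1, by = 0.05),
                            delta_grid = c(0, 0.25), species = "linear") {
  df <- tidyr::expand_grid(bias_V = bias_grid, delta_eV = delta_grid)
  df$current_A <- df$bias_V / resistance
  new_iv_table(df,
    species = species, E_fL_anchor = NA_real_,
    bias_grid = sort(unique(bias_grid)), delta_grid = sort(unique(delta_grid))
  )
}

new_iv_table <- function(df, species, E_fL_anchor, bias_grid, delta_grid) {
  out <- as_tibble(df)
  attr(out, "species") <- species
  attr(out, "E_fL_anchor") <- E_fL_anchor
  attr(out, "bias_grid") <- bias_grid
  attr(out, "delta_grid") <- delta_grid
  class(out) <- unique(c("iv_table", class(out)))
  out
}

#' @export
print.iv_table <- function(x, ...) {
  cat(
    "<iv_table> species ", attr(x, "species"),
    ", anchor E_fL = ", format(attr(x, "E_fL_anchor")), " eV, ",
    length(attr(x, "bias_grid")), " bias x ",
    length(attr(x, "delta_grid")), " delta points\n",
    sep = ""
  )
  NextMethod()
}

# dense (bias x delta) current matrix, row names = bias, col names = delta
iv_current_matrix <- function(iv) {
  bias <- attr(iv, "bias_grid")
  delta <- attr(iv, "delta_grid")
  m <- matrix(NA_real_, length(bias), length(delta))
  bi <- match(iv$bias_V, bias)
  di <- match(iv$delta_eV, delta)
  m[cbind(bi, di)] <- iv$current_A
  if (anyNA(m)) {
    abort("I-V table is not a complete bias x delta grid.",
      class = "dnarom_input_error"
    )
  }
  list(bias = bias, delta = delta, I = m)
}

#' Interpolate a current-voltage table
#'
#' Bilinear interpolation of the current surface in (bias, Fermi offset).
#' Bias values beyond the tabulated range are linearly extrapolated from the
#' outermost segment; offsets must be bracketed by the table.
#'
#' @param iv An `iv_table`.
#' @param bias Vector of biases (V).
#' @param delta Vector of Fermi offsets (eV), recycled against `bias`.
#' @return Currents (A).
#' @export
iv_interpolate <- function(iv, bias, delta = 0) {
  g <- iv_current_matrix(iv)
  n <- max(length(bias), length(delta))
  bias <- rep_len(bias, n)
  delta <- rep_len(delta, n)
  if (min(delta) < min(g$delta) - 1e-12 || max(delta) > max(g$delta) + 1e-12) {
    abort("Fermi offset outside the tabulated delta grid.",
      class = "dnarom_input_error"
    )
  }
  di <- pmin(pmax(findInterval(delta, g$delta), 1L), length(g$delta) - 1L)
  wd <- (delta - g$delta[di]) / (g$delta[di + 1L] - g$delta[di])
  bi <- pmin(pmax(findInterval(bias, g$bias), 1L), length(g$bias) - 1L)
  wb <- (bias - g$bias[bi]) / (g$bias[bi + 1L] - g$bias[bi])
  i00 <- g$I[cbind(bi, di)]
  i10 <- g$I[cbind(bi + 1L, di)]
  i01 <- g$I[cbind(bi, di + 1L)]
  i11 <- g$I[cbind(bi + 1L, di + 1L)]
  (1 - wd) * ((1 - wb) * i00 + wb * i10) + wd * ((1 - wb) * i01 + wb * i11)
}

#' Zero-bias secant resistance of an I-V table
#'
#' `V / I(V)` at the smallest positive tabulated bias, at the given offset.
#'
#' @param iv An `iv_table`.
#' @param delta Fermi offset (eV).
#' @return Resistance (Ohm).
#' @export
iv_secant_resistance <- function(iv, delta = 0) {
  v <- min(attr(iv, "bias_grid")[attr(iv, "bias_grid") > 0])
  v / iv_interpolate(iv, v, delta)
}

#' Write / read an I-V table
#'
#' CSV with header `bias_V, delta_eV, current_A`, values printed with 17
#' significant digits so the round trip is bit-stable, plus a sidecar
#' `<path>.meta.json` holding species, Fermi anchor, grids, and a provenance
#' string.
#'
#' @param iv An `iv_table`.
#' @param path Output CSV path.
#' @param provenance Free-form provenance string stored in the sidecar.
#' @return `path`, invisibly (`write_iv`); an `iv_table` (`read_iv`).
#' @export
write_iv <- function(iv, path, provenance = "dnarom") {
  stopifnot(inherits(iv, "iv_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bias_V,delta_eV,current_A", con)
  writeLines(
    sprintf("%.17g,%.17g,%.17g", iv$bias_V, iv$delta_eV, iv$current_A),
    con
  )
  meta <- list(
    species = attr(iv, "species"),
    E_fL_anchor = attr(iv, "E_fL_anchor"),
    bias_grid = attr(iv, "bias_grid"),
    delta_grid = attr(iv, "delta_grid"),
    provenance = provenance
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_iv
#' @export
read_iv <- function(path) {
  df <- read.csv(path)
  expected <- c("bias_V", "delta_eV", "current_A")
  if (!identical(names(df), expected)) {
    abort(
      sprintf(
        "Malformed I-V table %s: expected columns %s.",
        path, paste(expected, collapse = ", ")
      ),
      class = "dnarom_format_error"
    )
  }
  if (anyNA(df)) {
    abort(sprintf("I-V table %s contains missing values.", path),
      class = "dnarom_format_error"
    )
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- list(species = "unknown", E_fL_anchor = NA_real_)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  # grids are rebuilt from the data columns: the CSV carries 17 significant
  # digits and is the bit-stable source of truth
  new_iv_table(df,
    species = meta$species, E_fL_anchor = meta$E_fL_anchor,
    bias_grid = sort(unique(df$bias_V)),
    delta_grid = sort(unique(df$delta_eV))
  )
}
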