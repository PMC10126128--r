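#' Configuration for the Fermi-energy variability Monte Carlo
#'
#' Each simulation draws a random bit matrix (equiprobable by default), draws
#' uniform Fermi-energy offsets on `[0, delta_max]` - one per memory cell by
#' default, or one per simulation - shifts each cell's I-V table by its
#' offset, solves the array read-out, and scores the optimal-threshold bit
#' error rate, mean cell voltage, and (optionally) read power. All
#' randomness flows from one master seed through per-simulation substreams,
#' so runs are reproducible and order-independent.
#'
#' @param n_sims Number of simulations.
#' @param delta_max Upper bound of the uniform Fermi offset (eV).
#' @param r_int Interconnect resistance (Ohm).
#' @param m,n Array size (default 64 x 64).
#' @param v_in Read bias (V).
#' @param seed Master RNG seed.
#' @param sampling `"per_cell"` or `"per_simulation"` offset granularity.
#' @param p_one Probability of a logic-1 cell.
#' @param solver Array solver; the parametric model (default) makes
#'   thousand-simulation studies tractable, `"kirchhoff"` runs the oracle.
#' @param compute_power Also evaluate the Kirchhoff read power per
#'   simulation (adds one oracle solve sweep per simulation).
#' @param tol Solver tolerance (V).
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_sims = 1000L, delta_max = 0.1, r_int = 1e5,
                      m = 64L, n = 64L, v_in = 1, seed = 1L,
                      sampling = c("per_cell", "per_simulation"),
                      p_one = 0.5, solver = c("parametric", "kirchhoff"),
                      compute_power = FALSE, tol = 1e-6) {
  if (n_sims < 1L) abort("`n_sims` must be >= 1.", class = "dnarom_input_error")
  if (delta_max < 0) abort("`delta_max` must be >= 0.", class = "dnarom_input_error")
  structure(
    list(
      n_sims = as.integer(n_sims), delta_max = delta_max, r_int = r_int,
      m = as.integer(m), n = as.integer(n), v_in = v_in,
      seed = as.integer(seed), sampling = match.arg(sampling),
      p_one = p_one, solver = match.arg(solver),
      compute_power = compute_power, tol = tol
    ),
    class = "mc_config"
  )
}

#' Draw Fermi-energy offsets
#'
#' Uniform draws on `[0, delta_max]`: one offset per memory cell
#' (`per_cell`) or a single offset for the whole array (`per_simulation`).
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config An [mc_config()].
#' @return `m x n` matrix of offsets (eV).
#' @export
sample_fermi_offsets <- function(config) {
  if (config$delta_max == 0) {
    return(matrix(0, config$m, config$n))
  }
  if (config$sampling == "per_cell") {
    matrix(runif(config$m * config$n, 0, config$delta_max), config$m, config$n)
  } else {
    matrix(runif(1, 0, config$delta_max), config$m, config$n)
  }
}

#' Run the Fermi-variability Monte Carlo
#'
#' @param config An [mc_config()].
#' @param iv0,iv1 `iv_table`s of the logic-0 and logic-1 species; their delta
#'   grids must bracket `config$delta_max`.
#' @param max_pooled Cap on the pooled per-class current samples retained for
#'   plotting.
#' @return A `ber_report`: `per_sim` tibble (one row per simulation: BER,
#'   threshold, mean cell voltage, class means/extremes, power when
#'   requested), pooled `class0`/`class1` current samples, the config, and
#'   summary statistics. Simulations whose solver fails are recorded with
#'   `NA` scores and counted in `n_failed`.
#' @export
run_monte_carlo <- function(config, iv0, iv1, max_pooled = 200000L) {
  stopifnot(inherits(config, "mc_config"))
  dmax <- max(attr(iv0, "delta_grid"))
  if (config$delta_max > dmax + 1e-12) {
    abort("I-V tables do not bracket `delta_max`.", class = "dnarom_input_error")
  }
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_sims)
  sneak <- NULL
  if (config$solver == "parametric") {
    sneak <- mc_sneak_calibration(config, iv0, iv1)
  }
  rows <- vector("list", config$n_sims)
  pooled0 <- list()
  pooled1 <- list()
  n_pooled <- 0L
  n_failed <- 0L
  for (s in seq_len(config$n_sims)) {
    set.seed(sub_seeds[s])
    bits <- random_bits(config$m, config$n, config$p_one)
    delta <- sample_fermi_offsets(config)
    res <- tryCatch(
      mc_one_sim(config, bits, delta, iv0, iv1, sneak),
      dnarom_convergence_error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      rows[[s]] <- tibble(
        sim = s, ber_pct = NA_real_, threshold_A = NA_real_,
        mean_V = NA_real_, mean_I0_A = NA_real_, mean_I1_A = NA_real_,
        max_I0_A = NA_real_, min_I1_A = NA_real_, power_W = NA_real_,
        failed = TRUE
      )
      next
    }
    rows[[s]] <- tibble(
      sim = s, ber_pct = res$ber$ber_pct, threshold_A = res$ber$threshold_A,
      mean_V = res$mean_V, mean_I0_A = mean(res$ber$class0),
      mean_I1_A = mean(res$ber$class1), max_I0_A = max(res$ber$class0),
      min_I1_A = min(res$ber$class1), power_W = res$power_W, failed = FALSE
    )
    if (n_pooled < max_pooled) {
      pooled0[[length(pooled0) + 1L]] <- res$ber$class0
      pooled1[[length(pooled1) + 1L]] <- res$ber$class1
      n_pooled <- n_pooled + length(res$ber$class0) + length(res$ber$class1)
    }
  }
  per_sim <- bind_rows(rows)
  structure(
    list(
      per_sim = per_sim,
      class0 = unlist(pooled0) %||% numeric(),
      class1 = unlist(pooled1) %||% numeric(),
      config = config,
      mean_ber_pct = mean(per_sim$ber_pct, na.rm = TRUE),
      max_ber_pct = if (all(is.na(per_sim$ber_pct))) NA_real_ else max(per_sim$ber_pct, na.rm = TRUE),
      mean_voltage_V = mean(per_sim$mean_V, na.rm = TRUE),
      mean_power_W = mean(per_sim$power_W, na.rm = TRUE),
      n_failed = n_failed
    ),
    class = "ber_report"
  )
}

# alpha/beta calibrated once per configuration at the average conductance of
# an equiprobable array with the expected offset delta_max/2
mc_sneak_calibration <- function(config, iv0, iv1) {
  d <- config$delta_max / 2
  g_avg <- mean(c(
    iv_interpolate(iv0, config$v_in, d),
    iv_interpolate(iv1, config$v_in, d)
  )) / config$v_in
  ref_bits <- matrix(0L, config$m, config$n)
  ref <- crossbar_spec(ref_bits, iv0, iv1,
    r_int = config$r_int,
    v_in = config$v_in, delta = d
  )
  estimate_sneak_parameters(ref, G_avg = g_avg)
}

mc_one_sim <- function(config, bits, delta, iv0, iv1, sneak) {
  spec <- crossbar_spec(bits, iv0, iv1,
    r_int = config$r_int,
    v_in = config$v_in, delta = delta
  )
  rm <- readout_map(spec,
    solver = config$solver, sneak = sneak,
    tol = config$tol
  )
  ber <- readout_ber(rm)
  power <- rm$power_W
  if (config$compute_power && config$solver != "kirchhoff") {
    power <- array_power(spec, tol = config$tol)
  }
  list(ber = ber, mean_V = mean(rm$V), power_W = power)
}

#' @export
print.ber_report <- function(x, ...) {
  cat(
    "<ber_report> ", x$config$n_sims, " simulations, ", x$config$m, " x ",
    x$config$n, ", R_int = ", format(x$config$r_int), " Ohm, delta_max = ",
    x$config$delta_max, " eV (", x$config$sampling, ")\n  mean BER = ",
    format(x$mean_ber_pct, digits = 4), "%, max BER = ",
    format(x$max_ber_pct, digits = 4), "%, mean cell voltage = ",
    format(x$mean_voltage_V, digits = 4), " V\n",
    sep = ""
  )
  if (x$n_failed > 0) cat("  ", x$n_failed, " simulations failed to converge\n")
  invisible(x)
}
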