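#' Image-storage benchmark: BER and power versus array size and interconnect
#'
#' Loads each image onto each array size, reads the array back with the
#' chosen solver at each interconnect resistance, thresholds the read
#' currents optimally per array, and tabulates the bit error rate by bit
#' load plus the average Kirchhoff read power per condition.
#'
#' @param images List of gray-level matrices (0-255) or file paths; see
#'   [synthetic_images()] and [read_image()].
#' @param sizes Integer vector of square array sizes (default `c(64, 128)`).
#' @param r_int_list Interconnect resistances to sweep (Ohm).
#' @param iv0,iv1 Species `iv_table`s.
#' @param v_in Read bias (V).
#' @param solver Array solver (Kirchhoff reference by default).
#' @param binarization,threshold Passed to [image_to_bits()]; the default
#'   `"fixed"` mid-gray threshold recovers the bit loads encoded by
#'   [synthetic_images()].
#' @param delta Fermi offset (eV) applied to every cell.
#' @param tol Solver tolerance (V).
#' @return A `storage_result`: list of tibbles `ber` (size, r_int_ohm,
#'   job_id, bit_load_pct, ber_pct, threshold_A, power_W) and `power` (size,
#'   r_int_ohm, power_W averaged over jobs).
#' @export
evaluate_storage <- function(images, sizes = c(64L, 128L), r_int_list = 1e4,
                             iv0, iv1, v_in = 1,
                             solver = c("kirchhoff", "parametric"),
                             binarization = "fixed", threshold = 127.5,
                             delta = 0, tol = 1e-6) {
  solver <- match.arg(solver)
  if (length(images) == 0L) {
    abort("`images` must be non-empty.", class = "dnarom_input_error")
  }
  rows <- list()
  for (size in sizes) {
    jobs <- lapply(seq_along(images), function(k) {
      job <- image_to_bits(images[[k]], size, size,
        binarization = binarization, threshold = threshold,
        source_id = paste0("img", k)
      )
      job
    })
    for (r_int in r_int_list) {
      sneak <- NULL
      if (solver == "parametric") {
        ref <- crossbar_spec(matrix(0L, size, size), iv0, iv1,
          r_int = r_int, v_in = v_in, delta = delta
        )
        g_avg <- mean(c(
          iv_interpolate(iv0, v_in, delta),
          iv_interpolate(iv1, v_in, delta)
        )) / v_in
        sneak <- estimate_sneak_parameters(ref, G_avg = g_avg)
      }
      for (k in seq_along(jobs)) {
        job <- jobs[[k]]
        spec <- crossbar_spec(job$bits, iv0, iv1,
          r_int = r_int,
          v_in = v_in, delta = delta
        )
        rm <- readout_map(spec, solver = solver, sneak = sneak, tol = tol)
        ber <- readout_ber(rm)
        rows[[length(rows) + 1L]] <- tibble(
          size = size, r_int_ohm = r_int, job_id = job$source_id,
          bit_load_pct = job$bit_load_pct, ber_pct = ber$ber_pct,
          threshold_A = ber$threshold_A, power_W = rm$power_W
        )
      }
    }
  }
  ber_tbl <- bind_rows(rows)
  power_tbl <- ber_tbl |>
    group_by(.data$size, .data$r_int_ohm) |>
    summarise(power_W = mean(.data$power_W), .groups = "drop")
  structure(
    list(ber = ber_tbl, power = power_tbl, solver = solver),
    class = "storage_result"
  )
}

#' @export
print.storage_result <- function(x, ...) {
  cat("<storage_result> ", nrow(x$ber), " array reads (", x$solver, ")\n",
    sep = ""
  )
  s <- x$ber |>
    group_by(.data$size, .data$r_int_ohm) |>
    summarise(
      mean_ber_pct = mean(.data$ber_pct),
      max_ber_pct = max(.data$ber_pct), .groups = "drop"
    )
  print(s)
  invisible(x)
}

#' Group storage BERs by integer-rounded bit load
#'
#' Box-plot-ready view of a [evaluate_storage()] result; the job counts of
#' the groups always sum to the number of array reads.
#'
#' @param result A `storage_result`.
#' @return Tibble `size, r_int_ohm, bit_load, n_jobs, mean_ber_pct,
#'   max_ber_pct`.
#' @export
storage_ber_by_load <- function(result) {
  result$ber |>
    mutate(bit_load = round(.data$bit_load_pct)) |>
    group_by(.data$size, .data$r_int_ohm, .data$bit_load) |>
    summarise(
      n_jobs = n(),
      mean_ber_pct = mean(.data$ber_pct),
      max_ber_pct = max(.data$ber_pct),
      .groups = "drop"
    )
}
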