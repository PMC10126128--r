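#' Full read-out current map by driving rows sequentially
#'
#' Reads the whole array: each row in turn receives `v_in` while all bitlines
#' stay grounded, and the bitline current under the driven cell's column is
#' recorded. `I_out[i, j]` is the measured current for cell `(i, j)` during
#' the read of row `i`.
#'
#' @param spec A [crossbar_spec()].
#' @param solver `"kirchhoff"` (reference nodal analysis; default) or
#'   `"parametric"` (fast alpha/beta model).
#' @param sneak Optional precomputed [estimate_sneak_parameters()]
#'   (parametric solver only).
#' @param tol,max_iter,damping Iteration controls, see [solve_kirchhoff()].
#' @param form Parametric profile form, see [voltage_distribution()].
#' @return A `readout_map`: list with `I_out` (m x n), `V` (m x n driven-row
#'   cell voltages), `solver`, `power_W` (mean dissipated power over the row
#'   reads; Kirchhoff only, otherwise `NA`), `max_kcl_residual`, and the bit
#'   matrix for downstream error counting.
#' @export
readout_map <- function(spec, solver = c("kirchhoff", "parametric"),
                        sneak = NULL, tol = 1e-6, max_iter = 200L,
                        damping = 0.5, form = "calibrated") {
  solver <- match.arg(solver)
  m <- spec$m
  n <- spec$n
  I_out <- matrix(NA_real_, m, n)
  V <- matrix(NA_real_, m, n)
  power <- NA_real_
  max_resid <- NA_real_
  if (solver == "kirchhoff") {
    G_warm <- NULL
    p <- numeric(m)
    resid <- numeric(m)
    for (i in seq_len(m)) {
      st <- solve_kirchhoff(spec, i,
        tol = tol, max_iter = max_iter,
        damping = damping, G_init = G_warm
      )
      G_warm <- st$G
      I_out[i, ] <- st$I_out
      V[i, ] <- st$V[i, ]
      p[i] <- st$power_W
      resid[i] <- st$kcl_residual
    }
    power <- mean(p)
    max_resid <- max(resid)
  } else {
    sneak <- sneak %||% estimate_sneak_parameters(spec)
    res <- parametric_fixed_point(
      spec,
      rows = seq_len(m), sneak = sneak, tol = tol,
      max_iter = max_iter, damping = damping, form = form
    )
    V <- res$V
    I_out <- res$I * matrix(sneak$beta, m, n, byrow = TRUE)
  }
  structure(
    list(
      I_out = I_out, V = V, bits = spec$bits, solver = solver,
      power_W = power, max_kcl_residual = max_resid,
      m = m, n = n, r_int = spec$r_int, v_in = spec$v_in
    ),
    class = "readout_map"
  )
}

#' @export
print.readout_map <- function(x, ...) {
  cat(
    "<readout_map> ", x$m, " x ", x$n, " (", x$solver, "), currents ",
    format(min(x$I_out), digits = 3), " .. ",
    format(max(x$I_out), digits = 3), " A\n",
    sep = ""
  )
  invisible(x)
}

#' Optimal read threshold and bit error rate for two current classes
#'
#' Scans every decision boundary between consecutive values of the pooled,
#' sorted read currents (plus the two all-one-class extremes) and returns
#' the threshold minimizing total misclassifications, with currents at or
#' above the threshold read as logic 1. Ties are broken toward the lower
#' threshold.
#'
#' @param class0 Read currents of true logic-0 cells (A).
#' @param class1 Read currents of true logic-1 cells (A).
#' @return List with `threshold_A`, `ber_pct` (misclassified percentage),
#'   `n_errors`, `n_total`.
#' @export
optimal_threshold <- function(class0, class1) {
  n0 <- length(class0)
  n1 <- length(class1)
  if (n0 == 0L || n1 == 0L) {
    abort("Both classes must be non-empty.", class = "dnarom_input_error")
  }
  pooled <- c(class0, class1)
  lab1 <- c(rep(FALSE, n0), rep(TRUE, n1))
  ord <- order(pooled)
  pooled <- pooled[ord]
  lab1 <- lab1[ord]
  # boundary after position k: errors = (#1 in 1..k) + (#0 in k+1..N);
  # boundaries between tied current values are not realizable by a threshold
  cum1 <- c(0, cumsum(lab1))
  errs <- cum1 + (n0 - (seq_along(cum1) - 1 - cum1))
  realizable <- c(TRUE, diff(pooled) > 0, TRUE)
  errs[!realizable] <- Inf
  k <- which.min(errs) - 1L # first minimum = lowest threshold
  nv <- length(pooled)
  threshold <- if (k == 0L) {
    pooled[1] - abs(pooled[1]) * 1e-6 - 1e-300
  } else if (k == nv) {
    pooled[nv] + abs(pooled[nv]) * 1e-6 + 1e-300
  } else {
    (pooled[k] + pooled[k + 1L]) / 2
  }
  n_err <- errs[k + 1L]
  list(
    threshold_A = threshold, ber_pct = 100 * n_err / (n0 + n1),
    n_errors = as.integer(n_err), n_total = n0 + n1
  )
}

#' Bit error rate of a read-out map
#'
#' Applies [optimal_threshold()] to the read currents of a [readout_map()]
#' split by the true stored bits.
#'
#' @param rm A `readout_map`.
#' @return The [optimal_threshold()] list, with the class current samples
#'   attached as `class0` and `class1`.
#' @export
readout_ber <- function(rm) {
  stopifnot(inherits(rm, "readout_map"))
  class0 <- rm$I_out[rm$bits == 0L]
  class1 <- rm$I_out[rm$bits == 1L]
  out <- optimal_threshold(class0, class1)
  out$class0 <- class0
  out$class1 <- class1
  out
}
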