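#' Write / read a dense real matrix with a dimension header
#'
#' Whitespace-delimited values preceded by a one-line header
#' `# rows cols units`; values printed with 17 significant digits so the
#' round trip is bit-stable.
#'
#' @param m Numeric matrix (`write_matrix`).
#' @param path File path.
#' @param units Unit string recorded in the header.
#' @return `write_matrix`: `path`, invisibly. `read_matrix`: the matrix,
#'   with the units as attribute `"units"`.
#' @export
write_matrix <- function(m, path, units = "eV") {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %s", nrow(m), ncol(m), units), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#")) {
    abort(sprintf("Missing '# rows cols units' header in %s.", path),
      class = "dnarom_format_error"
    )
  }
  hdr <- strsplit(trimws(sub("^#", "", lines[1])), "[[:space:]]+")[[1]]
  if (length(hdr) < 2L) {
    abort(sprintf("Malformed header '%s' in %s.", lines[1], path),
      class = "dnarom_format_error"
    )
  }
  nr <- suppressWarnings(as.integer(hdr[1]))
  nc <- suppressWarnings(as.integer(hdr[2]))
  units <- if (length(hdr) >= 3L) hdr[3] else ""
  if (is.na(nr) || is.na(nc)) {
    abort(sprintf("Non-numeric dimensions in header of %s.", path),
      class = "dnarom_format_error"
    )
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    abort(
      sprintf("%s: expected %d matrix rows, found %d.", path, nr, length(body)),
      class = "dnarom_format_error"
    )
  }
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[[:space:]]+")[[1]]))
    if (length(v) != nc || anyNA(v)) {
      abort(
        sprintf("%s line %d: expected %d numeric values.", path, i + 1L, nc),
        class = "dnarom_format_error"
      )
    }
    v
  })
  m <- do.call(rbind, vals)
  attr(m, "units") <- units
  m
}

#' Read an orbital partition file
#'
#' One line per nucleotide: `name start end`, 0-based half-open orbital
#' index ranges in strand order.
#'
#' @param path File path.
#' @return Named list of 1-based orbital index vectors.
#' @export
read_partition <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 3L) {
      abort(sprintf("%s line %d: expected 'name start end'.", path, i),
        class = "dnarom_format_error"
      )
    }
    a <- suppressWarnings(as.integer(f[2]))
    b <- suppressWarnings(as.integer(f[3]))
    if (is.na(a) || is.na(b) || b <= a) {
      abort(sprintf("%s line %d: invalid range.", path, i),
        class = "dnarom_format_error"
      )
    }
    out[[f[1]]] <- (a + 1L):b
  }
  out
}

#' Read a base-pair grouping file
#'
#' One line per base pair: `pair_index nuc_a nuc_b` (1-based nucleotide
#' indices).
#'
#' @param path File path.
#' @return List of length-2 integer vectors in pair order.
#' @export
read_basepairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pairs <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
    if (length(f) != 3L || anyNA(f)) {
      abort(sprintf("%s line %d: expected 'pair_index nuc_a nuc_b'.", path, i),
        class = "dnarom_format_error"
      )
    }
    f
  })
  ord <- order(vapply(pairs, `[`, integer(1), 1L))
  lapply(pairs[ord], function(f) f[2:3])
}

run_config_defaults <- function() {
  list(
    stage = "transport", out_dir = "dnarom-out", seed = 1L,
    m = 64L, n = 64L, r_int_ohm = 1e4, v_in = 1, tol = 1e-6,
    solver = "kirchhoff", n_sims = 100L, delta_max = 0.1,
    sampling = "per_cell", p_one = 0.5,
    bias_step = 0.05, delta_step = 0.025, energy_step = 0.001,
    n_basepairs = 7L, n_images = 50L, image_size = 64L,
    sizes = c(64L, 128L), r_int_list = c(1e4, 1e5, 1e6),
    fock = NULL, overlap = NULL, partition = NULL, basepairs = NULL,
    image_dir = NULL, log_level = "info"
  )
}

#' Read, validate, and resolve a run configuration
#'
#' Flat YAML key-value file; unknown keys are rejected. Every run writes the
#' fully resolved configuration next to its outputs so any result file is
#' regenerable from that copy alone.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list overriding file values (CLI flags).
#' @return Named list of resolved settings.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- run_config_defaults()
  cfg <- list()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare key `n` as a boolean; restore it
    names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "n"
    unknown <- setdiff(names(cfg), names(defaults))
    if (length(unknown)) {
      abort(
        sprintf("Unknown config keys: %s.", paste(unknown, collapse = ", ")),
        class = "dnarom_config_error"
      )
    }
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  modifyList(modifyList(defaults, cfg), overrides)
}

#' @rdname read_run_config
#' @param config Resolved configuration list.
#' @param out_dir Directory to write `resolved-config.yaml` into.
#' @export
write_resolved_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(
    config[!vapply(config, is.null, logical(1))],
    file.path(out_dir, "resolved-config.yaml")
  )
  invisible(file.path(out_dir, "resolved-config.yaml"))
}
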