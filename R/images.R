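#' Read a grayscale image as a 0-255 matrix
#'
#' PGM (ASCII `P2` or binary `P5`, maxval up to 65535, rescaled to 0-255) is
#' parsed natively; PNG goes through the png package (channels averaged for
#' RGB input).
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return Numeric matrix (rows x cols) of gray levels in 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path), class = "dnarom_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = read_pgm(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        abort("The png package is required to read PNG images.",
          class = "dnarom_io_error"
        )
      }
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
      a * 255
    },
    abort(sprintf("Unsupported image format: .%s", ext),
      class = "dnarom_io_error"
    )
  )
}

#' Read / write portable graymap (PGM) images
#'
#' @param path File path.
#' @param img Numeric matrix of gray levels in 0-255 (`write_pgm`).
#' @param ascii Write ASCII `P2` (default, text-friendly) or binary `P5`.
#' @return `read_pgm`: numeric matrix in 0-255; `write_pgm`: `path`,
#'   invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) {
    abort(sprintf("Not a PGM file (magic '%s') in %s.", magic, path),
      class = "dnarom_format_error"
    )
  }
  tokens <- character(0)
  # header tokens: width, height, maxval; '#' starts a comment to end of line
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") {
      abort(sprintf("Truncated PGM header in %s.", path),
        class = "dnarom_format_error"
      )
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0L || ch %in% c("\n", "")) break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) next
    tok <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch) || ch == "") break
      tok <- paste0(tok, ch)
    }
    tokens <- c(tokens, tok)
  }
  dims <- suppressWarnings(as.integer(tokens))
  if (anyNA(dims) || any(dims <= 0L)) {
    abort(sprintf("Malformed PGM header fields (%s) in %s.",
      paste(tokens, collapse = " "), path
    ), class = "dnarom_format_error")
  }
  w <- dims[1]
  h <- dims[2]
  maxval <- dims[3]
  npix <- w * h
  if (magic == "P5") {
    vals <- readBin(con, "integer",
      n = npix, size = if (maxval < 256) 1L else 2L,
      signed = FALSE, endian = "big"
    )
  } else {
    vals <- suppressWarnings(scan(con, what = integer(), n = npix, quiet = TRUE))
  }
  if (length(vals) < npix || anyNA(vals)) {
    abort(sprintf("Truncated PGM pixel data in %s (%d of %d values).",
      path, length(vals), npix
    ), class = "dnarom_format_error")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, ascii = TRUE) {
  img <- round(pmin(pmax(as.matrix(img), 0), 255))
  h <- nrow(img)
  w <- ncol(img)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    writeLines(apply(img, 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", w, " ", h, "\n255\n"), con, eos = NULL)
    writeBin(as.integer(t(img)), con, size = 1L)
  }
  invisible(path)
}

# nearest-neighbour index resize; center-crop when shrinking to a strictly
# smaller window is requested
resize_indices <- function(from, to) {
  if (from == to) {
    return(seq_len(from))
  }
  round(seq(0.5, from - 0.5, length.out = to) + 0.5)
}

#' Convert a grayscale image to a crossbar bit-load job
#'
#' Resizes the image to `m x n` (nearest neighbour; images larger than the
#' array can instead be center-cropped), binarizes it, and reports the bit
#' load: the percentage of logic-1 (high-conductance species) cells.
#'
#' @param img Numeric gray-level matrix (0-255) or a path readable by
#'   [read_image()].
#' @param m,n Target array size.
#' @param binarization `"median"` (global threshold at the image median),
#'   `"fixed"` (threshold at `threshold`), or `"quantile"` (threshold at the
#'   `threshold` quantile). Pixels strictly above the threshold become 1.
#' @param threshold Threshold value (gray level for `"fixed"`, probability
#'   for `"quantile"`).
#' @param crop Center-crop instead of resizing when the image is larger than
#'   the array.
#' @param source_id Label carried into result tables.
#' @return An `image_job`: list with `bits` (m x n 0/1), `bit_load_pct`,
#'   `source_id`.
#' @export
image_to_bits <- function(img, m, n, binarization = c("median", "fixed", "quantile"),
                          threshold = 127.5, crop = FALSE, source_id = "image") {
  binarization <- match.arg(binarization)
  if (is.character(img)) {
    source_id <- basename(img)
    img <- read_image(img)
  }
  img <- as.matrix(img)
  if (crop && nrow(img) >= m && ncol(img) >= n) {
    r0 <- floor((nrow(img) - m) / 2)
    c0 <- floor((ncol(img) - n) / 2)
    img <- img[r0 + seq_len(m), c0 + seq_len(n), drop = FALSE]
  } else {
    img <- img[resize_indices(nrow(img), m), resize_indices(ncol(img), n),
      drop = FALSE
    ]
  }
  th <- switch(binarization,
    median = median(img),
    fixed = threshold,
    quantile = quantile(img, threshold, names = FALSE)
  )
  bits <- matrix(as.integer(img > th), m, n)
  structure(
    list(
      bits = bits, bit_load_pct = 100 * mean(bits), source_id = source_id
    ),
    class = "image_job"
  )
}

#' Generate synthetic benchmark images with controlled bit loads
#'
#' Draws smoothed random fields (Gaussian-filtered white noise), rank-flattens
#' them, and shifts each so that the fraction of pixels above mid-gray equals
#' a bit load drawn from `bitload_sampler`. The default sampler concentrates
#' loads in the 50-70% band while spanning 40-80%, emulating the bit-load
#' histogram of a natural-image benchmark; pair these images with
#' `image_to_bits(..., binarization = "fixed")` to recover the drawn loads.
#'
#' @param count Number of images.
#' @param size Image side length in pixels (square images).
#' @param bitload_sampler Function `n -> n` target bit loads in percent.
#'   Default `40 + 40 * rbeta(n, 2, 2)`.
#' @param smoothing Gaussian kernel standard deviation in pixels.
#' @param seed Integer seed.
#' @return List of `count` gray-level matrices (0-255) with the target load
#'   stored as attribute `"bit_load_target"`.
#' @export
synthetic_images <- function(count, size = 64,
                             bitload_sampler = function(k) 40 + 40 * rbeta(k, 2, 2),
                             smoothing = size / 8, seed = 1L) {
  set.seed(seed)
  loads <- bitload_sampler(count)
  kernel_r <- ceiling(3 * smoothing)
  kx <- exp(-(seq(-kernel_r, kernel_r))^2 / (2 * smoothing^2))
  kx <- kx / sum(kx)
  lapply(seq_len(count), function(i) {
    z <- matrix(stats::rnorm((size + 2 * kernel_r)^2), size + 2 * kernel_r)
    z <- apply(z, 2, function(col) stats::filter(col, kx, sides = 2))
    z <- t(apply(z, 1, function(row) stats::filter(row, kx, sides = 2)))
    z <- z[kernel_r + seq_len(size), kernel_r + seq_len(size)]
    u <- matrix(rank(z, ties.method = "first") / (size^2 + 1), size)
    # shift so that P(value > 0.5) equals the target load
    q <- quantile(u, 1 - loads[i] / 100, names = FALSE)
    v <- pmin(pmax(u - q + 0.5, 0), 1)
    img <- round(v * 255)
    attr(img, "bit_load_target") <- loads[i]
    img
  })
}
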