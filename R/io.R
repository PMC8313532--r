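# Plain-text file formats.
#
# Everything the pipeline writes is text: ASCII PGM (P2) for images, CSV
# for detector traces, JSON for layouts/configs/metrics. Round trips are
# lossless to the declared precision (16-bit for PGM, ~15 significant
# digits for CSV).

#' Write / read an ASCII PGM (P2) grayscale image
#'
#' Values in [0, 1] are quantized to `maxval` levels (default 16-bit).
#' `read_pgm` returns the raw integer pixels and `maxval`; divide to get
#' transmittance.
#'
#' @param image numeric matrix with values in [0, 1] (or an `spi_phantom`).
#' @param path destination file.
#' @param maxval maximum gray value (quantization depth).
#' @return `write_pgm` returns `path` invisibly; `read_pgm` a list with
#'   `pixels` (integer matrix) and `maxval`.
#' @export
write_pgm <- function(image, path, maxval = 65535L) {
  if (inherits(image, "spi_phantom")) image <- image$image
  if (any(image < 0 | image > 1)) stop("image values must be in [0, 1]")
  q <- round(image * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
  # one image row per line
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- scan(text = paste(lines[-1L], collapse = " "), quiet = TRUE)
  if (trimws(lines[1L]) != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[1L]); h <- as.integer(toks[2L]); maxval <- as.integer(toks[3L])
  px <- toks[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: expected ", w * h, " pixels, got ", length(px))
  list(pixels = matrix(as.integer(px), nrow = h, ncol = w, byrow = TRUE),
       maxval = maxval)
}

#' Write / read a detector trace as CSV
#'
#' Two columns `time,value`; the time axis is `sample_index * time_step`
#' when the trace carries geometry-derived timing, else the sample index.
#' A JSON sidecar `<path>.json` stores N, M, seed/noise metadata.
#'
#' @param trace an `spi_trace` (see [acquire()]).
#' @param path destination CSV file.
#' @return `write_trace` returns `path` invisibly; `read_trace` an
#'   `spi_trace`.
#' @export
write_trace <- function(trace, path) {
  dt <- if (is.null(trace$time_step)) 1 else trace$time_step
  t_axis <- (seq_along(trace$samples) - 1) * dt
  con <- file(path, "w")
  writeLines("time,value", con)
  writeLines(sprintf("%.15g,%.15g", t_axis, trace$samples), con)
  close(con)
  jsonlite::write_json(
    list(order = trace$order, M = trace$M, time_step = trace$time_step,
         frame_index = trace$frame_index, noise = trace$noise),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing trace metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (length(df$value) != meta$order * meta$M)
    stop("trace length ", length(df$value), " != M*N = ", meta$order * meta$M)
  structure(list(samples = df$value, order = as.integer(meta$order),
                 M = as.integer(meta$M),
                 time_step = if (is.null(meta$time_step)) NULL else meta$time_step,
                 frame_index = meta$frame_index, noise = meta$noise),
            class = "spi_trace")
}
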