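#' @keywords internal
"_PACKAGE"

# Classed error helper: every user-facing failure gets a distinct condition
# class "blinkcount_error_<what>" so callers can condition on it.
bc_stop <- function(what, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("blinkcount_error_", what), "blinkcount_error",
              "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

SUPPORTED_DTYPES <- c("uint8", "uint16", "float32")
DTYPE_MAX <- c(uint8 = 255, uint16 = 65535, float32 = Inf)

#' Construct an image stack
#'
#' An `ImageStack` holds a fluorescence movie as a 3-D intensity array plus
#' spatial and temporal metadata. The internal axis convention is fixed as
#' `(y, x, t)`: `data[y, x, t]` is the intensity of the pixel in row `y`,
#' column `x` of frame `t` (rows from the top, columns from the left,
#' frames 1-based in acquisition order). Intensities are camera ADU.
#'
#' @param data numeric 3-D array with dimensions `(height, width, n_frames)`,
#'   or a matrix (interpreted as a single frame), or a list of equally-sized
#'   matrices (one per frame).
#' @param pixel_size physical pixel size in micrometres per pixel, or `NULL`
#'   if unknown (only grid-density quantification requires it).
#' @param exposure_s frame exposure time in seconds (metadata only).
#' @param is_filtered logical; whether denoising has already been applied.
#'   Freshly loaded raw data must carry `FALSE`.
#' @param dtype storage type used when the stack is written to disk: one of
#'   `"uint8"`, `"uint16"`, `"float32"`. If `NULL` it is inferred: integral
#'   data within \[0, 255\] becomes `"uint8"`, within \[0, 65535\]
#'   `"uint16"`, anything else `"float32"`.
#'
#' @return An object of class `ImageStack`: a list with elements `data`
#'   (numeric array), `n_frames`, `height`, `width`, `pixel_size`,
#'   `exposure_s`, `is_filtered`, `dtype`.
#' @examples
#' s <- image_stack(array(0, c(4, 4, 3)))
#' s$n_frames
#' @export
image_stack <- function(data, pixel_size = NULL, exposure_s = NULL,
                        is_filtered = FALSE, dtype = NULL) {
  if (is.list(data) && !is.array(data)) {
    dims <- unique(lapply(data, dim))
    if (length(data) == 0L)
      bc_stop("empty_stack", "stack must contain at least one frame")
    if (length(dims) != 1L || is.null(dims[[1]]))
      bc_stop("ragged_frames", "all frames must share one (height, width) shape")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dims[[1]], length(data)))
  }
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    bc_stop("bad_shape", "data must be a (height, width, n_frames) array")
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  dim(data) <- unname(dim(data))
  d <- dim(data)
  if (any(d < 1L))
    bc_stop("empty_stack", "stack dimensions must all be >= 1")
  if (is.null(dtype)) {
    if (all(is.finite(data)) && all(data == round(data)) && all(data >= 0)) {
      dtype <- if (max(data) <= 255) "uint8" else
               if (max(data) <= 65535) "uint16" else "float32"
    } else dtype <- "float32"
  }
  dtype <- match.arg(dtype, SUPPORTED_DTYPES)
  structure(list(
    data = data,
    n_frames = d[3L], height = d[1L], width = d[2L],
    pixel_size = pixel_size, exposure_s = exposure_s,
    is_filtered = isTRUE(is_filtered), dtype = dtype
  ), class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("ImageStack: %d frame(s) of %d x %d px (%s%s)\n",
              x$n_frames, x$height, x$width, x$dtype,
              if (x$is_filtered) ", filtered" else ", raw"))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  if (!is.null(x$exposure_s))
    cat(sprintf("  exposure:   %g s/frame\n", x$exposure_s))
  cat(sprintf("  intensity range: [%g, %g] ADU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Load a fluorescence movie from TIFF
#'
#' Reads a multi-page grayscale TIFF (or an explicit vector of single-frame
#' TIFF files, or a directory of them taken in sorted order) into an
#' [image_stack()]. Frames follow file page order; integer intensities are
#' preserved bit-exactly. The result always has `is_filtered = FALSE`.
#'
#' @param path path to a multi-page TIFF file, a character vector of TIFF
#'   files (one frame each, in the given order), or a directory whose
#'   `*.tif`/`*.tiff` files are read in lexicographic order.
#' @param pixel_size,exposure_s optional metadata forwarded to
#'   [image_stack()].
#' @return An `ImageStack`.
#' @section Errors:
#' Distinct conditions are raised for a missing file
#' (`blinkcount_error_missing_file`), multi-channel/RGB pages
#' (`blinkcount_error_multichannel`), pages of unequal shape
#' (`blinkcount_error_ragged_frames`), a file with no pages or an empty
#' directory (`blinkcount_error_empty_stack`), and unsupported bit depths
#' (`blinkcount_error_unsupported_dtype`).
#' @export
load_stack <- function(path, pixel_size = NULL, exposure_s = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                            full.names = TRUE))
    if (length(path) == 0L)
      bc_stop("empty_stack", "directory contains no TIFF files")
  }
  missing <- path[!file.exists(path)]
  if (length(missing) > 0L)
    bc_stop("missing_file",
            paste0("file not found: ", paste(missing, collapse = ", ")))
  pages <- do.call(c, lapply(path, function(p) {
    pg <- tiff::readTIFF(p, all = TRUE, info = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pg
  }))
  if (length(pages) == 0L)
    bc_stop("empty_stack", "TIFF contains no pages")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    bc_stop("multichannel",
            "multi-channel/RGB pages are not supported; grayscale only")
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L)
    bc_stop("ragged_frames", "all pages must share one (height, width) shape")
  bits <- unique(vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1)))
  if (length(bits) != 1L)
    bc_stop("ragged_frames", "all pages must share one sample bit depth")
  # readTIFF normalises to [0, 1]; rescale integer pages back to ADU.
  if (is.na(bits)) bits <- 16L
  if (bits %in% c(8L, 16L)) {
    scale <- 2^bits - 1
    dtype <- if (bits == 8L) "uint8" else "uint16"
    frames <- lapply(pages, function(p) round(p * scale))
  } else if (bits == 32L) {
    dtype <- "float32"
    frames <- pages
  } else {
    bc_stop("unsupported_dtype",
            sprintf("unsupported bit depth: %d (supported: 8, 16, 32)", bits))
  }
  image_stack(lapply(frames, function(f) { attributes(f) <- list(dim = dim(f)); f }),
              pixel_size = pixel_size, exposure_s = exposure_s,
              is_filtered = FALSE, dtype = dtype)
}

#' Save a stack as a multi-page TIFF
#'
#' Writes the movie as one grayscale page per frame, readable by generic
#' TIFF viewers. For integer dtypes (`uint8`, `uint16`) the written file
#' round-trips bit-exactly through [load_stack()]. `float32` stacks are
#' stored as 32-bit float pages, which the TIFF format (as written by the
#' underlying library) defines only for intensities in \[0, 1\]; values
#' outside that range raise an error rather than being silently clipped.
#'
#' @param stack an `ImageStack`.
#' @param path output file path.
#' @param compression TIFF compression, default `"none"` (maximally
#'   portable); `"LZW"` and `"deflate"` are lossless alternatives.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path, compression = "none") {
  stopifnot(inherits(stack, "ImageStack"))
  if (!all(is.finite(stack$data)))
    bc_stop("nonfinite", "stack contains non-finite intensities; cannot save")
  if (any(stack$data < 0))
    bc_stop("negative_intensity", "stack contains negative intensities; cannot save")
  if (!dir.exists(dirname(path)))
    bc_stop("unwritable_path",
            paste0("output directory does not exist: ", dirname(path)))
  frames <- lapply(seq_len(stack$n_frames),
                   function(t) stack$data[, , t, drop = TRUE])
  if (stack$dtype == "float32") {
    if (max(stack$data) > 1)
      bc_stop("float_range",
              "float32 TIFF storage is defined for [0, 1] only; rescale or use an integer dtype")
    bits <- 32L
  } else {
    mx <- DTYPE_MAX[[stack$dtype]]
    if (max(stack$data) > mx || any(stack$data != round(stack$data)))
      bc_stop("dtype_overflow",
              sprintf("intensities exceed or are not representable in %s", stack$dtype))
    bits <- if (stack$dtype == "uint8") 8L else 16L
    frames <- lapply(frames, function(f) f / mx)
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bits,
                  compression = compression)
  invisible(path)
}

#' Validate an image stack
#'
#' Checks the `ImageStack` invariants and reports violations without ever
#' modifying the data. Advisories flag conditions that are legal for the
#' container but problematic downstream (a movie shorter than three frames
#' cannot feed the three-frame detector).
#'
#' @param stack object to validate.
#' @return A list with character vectors `violations` (empty means valid)
#'   and `advisories`.
#' @export
validate_stack <- function(stack) {
  violations <- character(0)
  advisories <- character(0)
  if (!inherits(stack, "ImageStack") || !is.array(stack$data) ||
      length(dim(stack$data)) != 3L) {
    return(list(violations = "not an ImageStack with 3-D data",
                advisories = advisories))
  }
  d <- dim(stack$data)
  if (!identical(d, c(stack$height, stack$width, stack$n_frames)))
    violations <- c(violations,
                    "data shape does not match (height, width, n_frames) metadata")
  if (any(d < 1L))
    violations <- c(violations, "all dimensions must be >= 1")
  if (!all(is.finite(stack$data)))
    violations <- c(violations, "non-finite intensity values present")
  else if (any(stack$data < 0))
    violations <- c(violations, "negative intensity values present")
  if (!is.logical(stack$is_filtered) || length(stack$is_filtered) != 1L)
    violations <- c(violations, "is_filtered must be a single logical")
  if (!is.null(stack$pixel_size) &&
      (!is.numeric(stack$pixel_size) || stack$pixel_size <= 0))
    violations <- c(violations, "pixel_size must be a positive number (um/px)")
  if (stack$n_frames < 3L)
    advisories <- c(advisories,
                    "too short for detection: the three-frame detector needs n_frames >= 3")
  list(violations = violations, advisories = advisories)
}
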