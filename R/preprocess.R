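#' Median filter parameters
#'
#' The denoising step replaces each pixel by the median over a small
#' neighbourhood. The kernel is a triple of odd window lengths along
#' `(t, y, x)` — note the temporal axis first, matching the conventional
#' way these kernels are quoted. The default `(1, 3, 3)` holds the temporal
#' axis fixed and takes the median over the 3x3 spatial neighbourhood
#' within each frame, which suppresses single-pixel impulse noise without
#' mixing information across frames.
#'
#' @param kernel integer triple of odd window lengths `(t, y, x)`, each
#'   >= 1. Default `c(1, 3, 3)`.
#' @param boundary edge handling: `"reflect"` (mirror about the edge without
#'   repeating the edge sample; the default) or `"replicate"` (repeat the
#'   nearest edge sample).
#' @return A `FilterParams` object.
#' @export
filter_params <- function(kernel = c(1L, 3L, 3L),
                          boundary = c("reflect", "replicate")) {
  boundary <- match.arg(boundary)
  if (length(kernel) != 3L || !is.numeric(kernel) || any(!is.finite(kernel)))
    bc_stop("bad_kernel", "kernel must be a numeric triple (t, y, x)")
  kernel <- as.integer(kernel)
  if (any(kernel < 1L))
    bc_stop("bad_kernel", "kernel lengths must be >= 1")
  if (any(kernel %% 2L == 0L))
    bc_stop("even_kernel",
            paste0("kernel lengths must be odd, got (",
                   paste(kernel, collapse = ", "), ")"))
  structure(list(kernel = kernel, boundary = boundary),
            class = "FilterParams")
}

# Map out-of-range indices along one axis back into 1..n.
pad_index <- function(i, n, boundary) {
  if (boundary == "reflect") {
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
  } else {
    i <- pmin(pmax(i, 1L), n)
  }
  i
}

check_kernel_fits <- function(kernel, dims) {
  # kernel is (t, y, x); dims is (H, W, T)
  lens <- c(dims[3L], dims[1L], dims[2L])
  if (any(kernel > lens))
    bc_stop("kernel_too_large",
            sprintf("kernel (%s) exceeds stack dimensions (t=%d, y=%d, x=%d)",
                    paste(kernel, collapse = ", "), lens[1], lens[2], lens[3]))
}

# Row-wise k-th order statistic of a gathered neighbourhood matrix, via a
# single vectorised sort keyed by row.
row_median_sorted <- function(G) {
  n <- nrow(G); m <- ncol(G)
  o <- order(row(G), G)
  matrix(G[o], n, m, byrow = TRUE)[, (m + 1L) %/% 2L]
}

# Median of nine equal-length vectors by a minimal exchange network
# (19 pmin/pmax pairs); much faster than sorting for the 3x3 kernel.
median9 <- function(p) {
  s <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  p[[5]]
}

#' Median-filter an image stack
#'
#' Applies the running-median denoiser with the given kernel. With the
#' default `(1, 3, 3)` kernel each output pixel is the median of its 3x3
#' spatial neighbourhood within its own frame; no information crosses
#' frames. The input is never modified; the output records
#' `is_filtered = TRUE` and carries the parameters used in its
#' `"filter_params"` attribute. Integer input yields integer output (the
#' median of an odd number of integers is an integer), so the dtype family
#' is preserved.
#'
#' @param stack an [image_stack()].
#' @param params a [filter_params()] object.
#' @return A filtered `ImageStack` of the same shape and dtype.
#' @examples
#' s <- image_stack(array(5, c(8, 8, 3)))
#' f <- median_filter_stack(s)
#' all(f$data == 5)
#' @export
median_filter_stack <- function(stack, params = filter_params()) {
  stopifnot(inherits(stack, "ImageStack"), inherits(params, "FilterParams"))
  if (!all(is.finite(stack$data)))
    bc_stop("nonfinite", "stack contains non-finite intensities")
  k <- params$kernel
  H <- stack$height; W <- stack$width; T <- stack$n_frames
  check_kernel_fits(k, dim(stack$data))
  ht <- (k[1L] - 1L) %/% 2L; hy <- (k[2L] - 1L) %/% 2L; hx <- (k[3L] - 1L) %/% 2L

  if (k[1L] == 1L && k[2L] == 3L && k[3L] == 3L) {
    # fast path: 3x3 spatial median per frame via exchange network
    iy <- lapply(-1:1, function(d) pad_index(seq_len(H) + d, H, params$boundary))
    ix <- lapply(-1:1, function(d) pad_index(seq_len(W) + d, W, params$boundary))
    out <- array(0, dim = c(H, W, T))
    for (t in seq_len(T)) {
      fr <- stack$data[, , t, drop = TRUE]
      p <- vector("list", 9L); n <- 0L
      for (dy in 1:3) for (dx in 1:3) {
        n <- n + 1L
        p[[n]] <- fr[iy[[dy]], ix[[dx]], drop = FALSE]
      }
      out[, , t] <- median9(p)
    }
  } else if (k[1L] == 1L) {
    # per-frame gather + vectorised sort for other spatial kernels
    offs <- expand.grid(dy = -hy:hy, dx = -hx:hx)
    out <- array(0, dim = c(H, W, T))
    for (t in seq_len(T)) {
      fr <- stack$data[, , t, drop = TRUE]
      G <- vapply(seq_len(nrow(offs)), function(i) {
        as.vector(fr[pad_index(seq_len(H) + offs$dy[i], H, params$boundary),
                     pad_index(seq_len(W) + offs$dx[i], W, params$boundary),
                     drop = FALSE])
      }, numeric(H * W))
      out[, , t] <- row_median_sorted(G)
    }
  } else {
    # full spatiotemporal gather
    offs <- expand.grid(dt = -ht:ht, dy = -hy:hy, dx = -hx:hx)
    G <- vapply(seq_len(nrow(offs)), function(i) {
      as.vector(stack$data[
        pad_index(seq_len(H) + offs$dy[i], H, params$boundary),
        pad_index(seq_len(W) + offs$dx[i], W, params$boundary),
        pad_index(seq_len(T) + offs$dt[i], T, params$boundary), drop = FALSE])
    }, numeric(H * W * T))
    out <- array(row_median_sorted(G), dim = c(H, W, T))
  }

  res <- image_stack(out, pixel_size = stack$pixel_size,
                     exposure_s = stack$exposure_s,
                     is_filtered = TRUE, dtype = stack$dtype)
  attr(res, "filter_params") <- params
  res
}

#' Reference median filter (explicit loops)
#'
#' Literal per-pixel implementation used as the equivalence oracle for
#' [median_filter_stack()]: for every `(y, x, t)` it gathers the
#' neighbourhood with the same boundary rule, sorts it, and takes the middle
#' element. Intended for small stacks only (roughly up to 64 x 64 x 16).
#'
#' @inheritParams median_filter_stack
#' @return A filtered `ImageStack`.
#' @export
median_filter_oracle <- function(stack, params = filter_params()) {
  stopifnot(inherits(stack, "ImageStack"), inherits(params, "FilterParams"))
  k <- params$kernel
  H <- stack$height; W <- stack$width; T <- stack$n_frames
  check_kernel_fits(k, dim(stack$data))
  ht <- (k[1L] - 1L) %/% 2L; hy <- (k[2L] - 1L) %/% 2L; hx <- (k[3L] - 1L) %/% 2L
  out <- array(0, dim = c(H, W, T))
  mid <- (prod(k) + 1L) %/% 2L
  for (t in seq_len(T)) {
    it <- pad_index((t - ht):(t + ht), T, params$boundary)
    for (y in seq_len(H)) {
      iy <- pad_index((y - hy):(y + hy), H, params$boundary)
      for (x in seq_len(W)) {
        ix <- pad_index((x - hx):(x + hx), W, params$boundary)
        nb <- as.vector(stack$data[iy, ix, it, drop = FALSE])
        out[y, x, t] <- sort(nb, partial = mid)[mid]
      }
    }
  }
  res <- image_stack(out, pixel_size = stack$pixel_size,
                     exposure_s = stack$exposure_s,
                     is_filtered = TRUE, dtype = stack$dtype)
  attr(res, "filter_params") <- params
  res
}
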