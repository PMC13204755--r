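#' A labelled movie at a known analyte concentration
#'
#' Bundles a movie with the metadata the calibration layer needs: a free-text
#' label (dye, replicate) and the analyte concentration in pg/mL, which must
#' be strictly positive so that `log10(concentration)` is defined.
#'
#' @param label free text identifying the movie (e.g. dye and replicate).
#' @param concentration analyte concentration in pg/mL, > 0.
#' @param stack an [image_stack()], or a TIFF path loaded lazily by
#'   [sweep_thresholds()].
#' @return A `MovieRecord` object.
#' @export
movie_record <- function(label, concentration, stack) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration <= 0)
    bc_stop("bad_concentration",
            "concentration must be a single finite number > 0 (pg/mL)")
  if (!inherits(stack, "ImageStack") && !is.character(stack))
    bc_stop("bad_stack_ref", "stack must be an ImageStack or a TIFF path")
  structure(list(label = as.character(label),
                 concentration = as.numeric(concentration),
                 stack = stack),
            class = "MovieRecord")
}

resolve_stack <- function(ref) {
  if (inherits(ref, "ImageStack")) ref else load_stack(ref)
}

#' Screen detection thresholds across a set of movies
#'
#' Runs the full pipeline (median filter, then threshold detection) for
#' every combination of movie and candidate threshold. Each movie is
#' filtered once and the filtered stack is reused across all thresholds.
#' The resulting count table is checked on construction for the detector's
#' threshold monotonicity: for each movie, `N` is non-increasing in `tau`.
#'
#' @param movies list of [movie_record()] objects.
#' @param taus numeric vector of candidate thresholds (non-empty, >= 0).
#' @param filter_params a [filter_params()] object.
#' @return A `SweepResult`: list with `taus`, `counts` (matrix, one row per
#'   movie, one column per threshold), `labels`, `concentrations`, and
#'   `provenance` (the filter parameters used).
#' @export
sweep_thresholds <- function(movies, taus, filter_params = blinkcount::filter_params()) {
  if (length(movies) == 0L)
    bc_stop("empty_sweep", "movies must be a non-empty list of movie_record")
  if (!all(vapply(movies, inherits, logical(1), "MovieRecord")))
    bc_stop("bad_movie", "every element of movies must be a movie_record")
  if (length(taus) == 0L || !is.numeric(taus) || any(!is.finite(taus)) ||
      any(taus < 0))
    bc_stop("bad_taus", "taus must be a non-empty vector of finite values >= 0")
  taus <- sort(unique(as.numeric(taus)))
  counts <- matrix(NA_real_, nrow = length(movies), ncol = length(taus),
                   dimnames = list(vapply(movies, `[[`, character(1), "label"),
                                   as.character(taus)))
  for (i in seq_along(movies)) {
    filtered <- median_filter_stack(resolve_stack(movies[[i]]$stack),
                                    filter_params)
    for (j in seq_along(taus))
      counts[i, j] <- detect_stack(filtered, detector_params(taus[j]))$count
  }
  res <- structure(list(
    taus = taus,
    counts = counts,
    labels = vapply(movies, `[[`, character(1), "label"),
    concentrations = vapply(movies, `[[`, numeric(1), "concentration"),
    provenance = filter_params
  ), class = "SweepResult")
  # construction-time invariant: per-movie monotonicity in tau
  if (any(apply(counts, 1L, function(r) any(diff(r) > 0))))
    bc_stop("monotonicity_violation",
            "internal error: counts increased with tau for some movie")
  res
}

#' @export
print.SweepResult <- function(x, ...) {
  cat(sprintf("SweepResult: %d movie(s) x %d threshold(s)\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Select the operating threshold from a sweep
#'
#' Operationalises the screening rationale — low thresholds over-count by
#' admitting noise, high thresholds under-detect — as a documented
#' lexicographic score over the candidate thresholds. For each `tau`,
#' counts are first averaged over movies sharing a concentration, then
#' scored by:
#'
#' 1. **monotone**: counts strictly increase with concentration (equivalent
#'    to a Spearman rank correlation of exactly 1); thresholds achieving
#'    this are preferred outright;
#' 2. **r_squared**: R-squared of the [fit_log_linear()] fit of counts on
#'    log10 concentration (larger is better);
#' 3. **blank_count**: the count at the lowest concentration (smaller is
#'    better — it proxies the false-positive floor);
#' 4. the smallest `tau` as the final tie-break.
#'
#' @param sweep a `SweepResult` from [sweep_thresholds()].
#' @param concentrations optional per-movie concentrations overriding those
#'   in the sweep.
#' @return A list with `tau_star` (the selected threshold), `diagnostics`
#'   (a data frame with one row per `tau`: monotone flag, Spearman rho,
#'   R-squared, blank count, rank), and `monotone_found` (logical; when
#'   `FALSE` no threshold preserved the concentration trend and the
#'   best-ranked one is returned with a warning, never silently).
#' @export
select_threshold <- function(sweep, concentrations = NULL) {
  stopifnot(inherits(sweep, "SweepResult"))
  conc <- if (is.null(concentrations)) sweep$concentrations else concentrations
  if (length(conc) != nrow(sweep$counts))
    bc_stop("bad_concentration", "need one concentration per movie")
  if (length(unique(conc)) < 2L)
    bc_stop("bad_concentration",
            "threshold selection needs >= 2 distinct concentrations")
  uc <- sort(unique(conc))
  diag_rows <- lapply(seq_along(sweep$taus), function(j) {
    cnt <- vapply(uc, function(cc) mean(sweep$counts[conc == cc, j]),
                  numeric(1))
    monotone <- all(diff(cnt) > 0)
    rho <- suppressWarnings(stats::cor(cnt, uc, method = "spearman"))
    r2 <- tryCatch({
      fit <- fit_log_linear(uc, cnt)
      if (fit$r_squared_defined) fit$r_squared else NA_real_
    }, error = function(e) NA_real_)
    data.frame(tau = sweep$taus[j], monotone = monotone,
               spearman = rho, r_squared = r2, blank_count = cnt[1L])
  })
  diagnostics <- do.call(rbind, diag_rows)
  r2key <- ifelse(is.na(diagnostics$r_squared), -Inf, diagnostics$r_squared)
  ord <- order(-diagnostics$monotone, -r2key, diagnostics$blank_count,
               diagnostics$tau)
  diagnostics$rank <- match(seq_len(nrow(diagnostics)), ord)
  monotone_found <- any(diagnostics$monotone)
  if (!monotone_found)
    warning(structure(
      class = c("blinkcount_warning_no_monotone_tau", "warning", "condition"),
      list(message = paste("no threshold preserves a strictly increasing",
                           "concentration response; returning best-ranked tau"),
           call = NULL)))
  list(tau_star = diagnostics$tau[ord[1L]],
       diagnostics = diagnostics,
       monotone_found = monotone_found)
}

#' Grid specification for areal density
#'
#' The manual-counting protocol overlays a grid of square regions of fixed
#' physical area (36 square micrometres by default) and reports events per
#' square micrometre. The square side in pixels is
#' `round(sqrt(square_area) / pixel_size)` and must be >= 1.
#'
#' @param pixel_size physical pixel size in micrometres per pixel, > 0.
#' @param square_area grid square area in square micrometres, default 36.
#' @return A `GridSpec` with the derived `side_px`.
#' @export
grid_spec <- function(pixel_size, square_area = 36) {
  if (missing(pixel_size) || !is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    bc_stop("unknown_pixel_size", "pixel_size (um/px) must be a positive number")
  if (!is.numeric(square_area) || square_area <= 0)
    bc_stop("bad_grid_area", "square_area must be > 0 (um^2)")
  side <- as.integer(round(sqrt(square_area) / pixel_size))
  if (side < 1L)
    bc_stop("bad_grid_area",
            "grid square smaller than one pixel at this pixel size")
  structure(list(square_area = as.numeric(square_area),
                 pixel_size = as.numeric(pixel_size),
                 side_px = side),
            class = "GridSpec")
}

#' Grid-based areal density of detections
#'
#' Partitions the field of view into non-overlapping squares of the
#' specified physical area, starting at the image origin (top-left) and
#' discarding partial squares at the right/bottom edges. Counts detected
#' (or manually marked) pixels per square and normalises by the square area
#' to give densities in counts per square micrometre. Grids are numbered
#' column-major: grid `(gy, gx)` has index `(gx - 1) * n_grid_rows + gy`.
#'
#' @param mask a `DetectionResult`, or a logical/0-1 matrix of marks.
#' @param spec a [grid_spec()].
#' @param selected_grids optional integer vector of grid indices over which
#'   the mean density is taken (e.g. the protocol's three inspected
#'   regions); default all grids.
#' @param n_select alternatively, the number of grids to select uniformly at
#'   random (requires `seed` for reproducibility).
#' @param seed RNG seed used only when `n_select` is given.
#' @return A `DensityResult`: `per_grid_counts` (matrix, grid rows x grid
#'   cols), `densities` (same shape, counts per um^2), `mean_density`,
#'   `n_grids`, `selected_grids`.
#' @export
grid_density <- function(mask, spec, selected_grids = NULL,
                         n_select = NULL, seed = NULL) {
  stopifnot(inherits(spec, "GridSpec"))
  if (inherits(mask, "DetectionResult")) mask <- mask$mask
  if (!is.matrix(mask))
    bc_stop("bad_mask", "mask must be a matrix or DetectionResult")
  m <- mask != 0
  H <- nrow(m); W <- ncol(m); side <- spec$side_px
  if (side > H || side > W)
    bc_stop("grid_too_large",
            sprintf("grid square (%d px) exceeds image (%d x %d px)",
                    side, H, W))
  ny <- H %/% side; nx <- W %/% side
  cropped <- m[seq_len(ny * side), seq_len(nx * side), drop = FALSE]
  arr <- array(cropped, dim = c(side, ny, side, nx))
  per_grid <- apply(arr, c(2L, 4L), sum)
  densities <- per_grid / spec$square_area
  n_grids <- ny * nx
  if (!is.null(selected_grids) && !is.null(n_select))
    bc_stop("bad_grid_selection",
            "give either selected_grids or n_select, not both")
  if (!is.null(n_select)) {
    if (n_select < 1L || n_select > n_grids)
      bc_stop("bad_grid_selection",
              sprintf("n_select must be in 1..%d", n_grids))
    selected_grids <- with_seed(seed, sample.int(n_grids, n_select))
  }
  if (is.null(selected_grids)) selected_grids <- seq_len(n_grids)
  if (any(selected_grids < 1L) || any(selected_grids > n_grids))
    bc_stop("bad_grid_selection",
            sprintf("selected_grids indices must be in 1..%d", n_grids))
  structure(list(per_grid_counts = per_grid,
                 densities = densities,
                 mean_density = mean(densities[selected_grids]),
                 n_grids = n_grids,
                 selected_grids = sort(unique(as.integer(selected_grids)))),
            class = "DensityResult")
}

#' Linear calibration against log10 concentration
#'
#' Ordinary least-squares fit of a response (count or density) on
#' `x = log10(concentration in pg/mL)`, the standard dose-response
#' transform for digital immunoassay calibration. The intercept is
#' therefore the predicted response at 1 pg/mL. Fitted with [stats::lm()];
#' R-squared is `1 - SS_res / SS_tot`, reported as undefined (never
#' silently 0 or 1) when the responses are constant (`SS_tot = 0`).
#'
#' @param concentration concentrations in pg/mL, all > 0, at least two
#'   distinct values.
#' @param response numeric responses, same length.
#' @return A `CalibrationFit`: `slope`, `intercept`, `r_squared`,
#'   `r_squared_defined`, `n_points`, `x_definition`.
#' @examples
#' fit_log_linear(c(1, 10, 100), c(1, 3, 5)) # slope 2, intercept 1, R^2 = 1
#' @export
fit_log_linear <- function(concentration, response) {
  if (length(concentration) != length(response))
    bc_stop("length_mismatch", "concentration and response lengths differ")
  if (length(concentration) < 2L)
    bc_stop("too_few_points", "need at least 2 points for a calibration fit")
  if (!all(is.finite(concentration)) || any(concentration <= 0))
    bc_stop("bad_concentration",
            "all concentrations must be finite and > 0 (log10 must be defined)")
  if (!all(is.finite(response)))
    bc_stop("nonfinite", "responses must be finite")
  x <- log10(concentration)
  if (length(unique(x)) < 2L)
    bc_stop("degenerate_x", "all concentrations identical: slope undefined")
  fit <- stats::lm(response ~ x)
  coefs <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  defined <- ss_tot > 0
  structure(list(
    slope = unname(coefs[2L]),
    intercept = unname(coefs[1L]),
    r_squared = if (defined) 1 - ss_res / ss_tot else NA_real_,
    r_squared_defined = defined,
    n_points = length(response),
    x_definition = "x = log10(concentration in pg/mL)"
  ), class = "CalibrationFit")
}

#' @export
print.CalibrationFit <- function(x, ...) {
  cat(sprintf("CalibrationFit (n = %d): y = %.4g x + %.4g   [%s]\n",
              x$n_points, x$slope, x$intercept, x$x_definition))
  if (x$r_squared_defined) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  else cat("  R^2 undefined (constant responses)\n")
  invisible(x)
}

#' Compare manual and automated counting series
#'
#' Fits the log-linear calibration to a manual series (grid densities) and
#' an automated series (threshold-based counts) over the same
#' concentrations and reports both fits with the per-concentration values
#' side by side. The two series need not share a scale (densities are per
#' um^2, automated counts are per field), so slopes are comparable only up
#' to that scale; R-squared is scale-free.
#'
#' @param manual,auto data frames with columns `concentration` (pg/mL) and
#'   `response`, covering the same set of concentrations.
#' @return A `MethodComparison`: `manual_fit`, `auto_fit` (both
#'   [fit_log_linear()] results) and `table` (per-concentration responses).
#' @export
compare_methods <- function(manual, auto) {
  need <- c("concentration", "response")
  if (!all(need %in% names(manual)) || !all(need %in% names(auto)))
    bc_stop("bad_series",
            "manual and auto need columns 'concentration' and 'response'")
  manual <- manual[order(manual$concentration), , drop = FALSE]
  auto <- auto[order(auto$concentration), , drop = FALSE]
  if (!isTRUE(all.equal(manual$concentration, auto$concentration)))
    bc_stop("mismatched_concentrations",
            "manual and auto must cover the same concentrations")
  structure(list(
    manual_fit = fit_log_linear(manual$concentration, manual$response),
    auto_fit = fit_log_linear(auto$concentration, auto$response),
    table = data.frame(concentration = manual$concentration,
                       manual = manual$response,
                       auto = auto$response)
  ), class = "MethodComparison")
}

#' @export
print.MethodComparison <- function(x, ...) {
  cat("Method comparison (response vs log10 concentration):\n")
  cat("  manual:   "); print(x$manual_fit)
  cat("  automated:"); print(x$auto_fit)
  print(x$table, row.names = FALSE)
  invisible(x)
}
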