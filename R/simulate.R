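# Evaluate expr under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for a synthetic blinking movie
#'
#' Describes a ground-truthed movie of sparse point emitters that switch
#' stochastically between an emissive (ON) and a dark (OFF) state over a
#' noisy background — the temporal signature the threshold detector
#' exploits. Defaults describe the package's reference operating regime: a
#' 60-frame, 256 x 256 px movie with bright, well-separated emitters
#' (amplitude 200 ADU over background 10 ADU, read noise 2 ADU, Poisson
#' shot noise) blinking with per-frame switching probabilities
#' `p_on = 0.2`, `p_off = 0.5`.
#'
#' @param n_frames number of frames, default 60.
#' @param height,width field size in pixels, default 256 x 256.
#' @param pixel_size micrometres per pixel, default 0.1.
#' @param n_emitters number of emitters (the concentration proxy).
#' @param psf_sigma Gaussian point-spread-function width in pixels;
#'   `0` deposits all intensity in the centre pixel.
#' @param amplitude peak emitter intensity in ADU when ON.
#' @param background constant background level in ADU.
#' @param p_on per-frame OFF-to-ON switching probability in \[0, 1\].
#' @param p_off per-frame ON-to-OFF switching probability in \[0, 1\].
#' @param initial_on_prob probability an emitter starts ON; default the
#'   stationary probability `p_on / (p_on + p_off)` (0 when both are 0).
#' @param shot_noise logical; apply Poisson noise to the noiseless image.
#' @param read_noise_sd additive Gaussian read noise, ADU, >= 0.
#' @param min_separation minimum pairwise distance between emitter centres
#'   in pixels; default `4 * psf_sigma + 2`. Set `enforce_separation =
#'   FALSE` to allow arbitrary placement.
#' @param enforce_separation logical, default `TRUE`.
#' @param seed RNG seed; fixed seed gives a bit-identical movie and truth.
#' @param dtype output intensity type, default `"uint16"`.
#' @return A `SimulationConfig` object.
#' @export
simulation_config <- function(n_frames = 60L, height = 256L, width = 256L,
                              pixel_size = 0.1, n_emitters = 50L,
                              psf_sigma = 1.3, amplitude = 200,
                              background = 10, p_on = 0.2, p_off = 0.5,
                              initial_on_prob = NULL,
                              shot_noise = TRUE, read_noise_sd = 2,
                              min_separation = NULL,
                              enforce_separation = TRUE,
                              seed = NULL, dtype = "uint16") {
  chk_prob <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      bc_stop("bad_probability", sprintf("%s must be in [0, 1]", nm))
  }
  chk_prob(p_on, "p_on"); chk_prob(p_off, "p_off")
  if (is.null(initial_on_prob))
    initial_on_prob <- if (p_on + p_off > 0) p_on / (p_on + p_off) else 0
  chk_prob(initial_on_prob, "initial_on_prob")
  for (nm in c("amplitude", "background", "read_noise_sd", "psf_sigma")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || !is.finite(v))
      bc_stop("bad_config", sprintf("%s must be finite and >= 0", nm))
  }
  if (n_frames < 1L || height < 1L || width < 1L || n_emitters < 0L)
    bc_stop("bad_config", "n_frames, height, width >= 1; n_emitters >= 0")
  if (is.null(min_separation)) min_separation <- 4 * psf_sigma + 2
  dtype <- match.arg(dtype, SUPPORTED_DTYPES)
  structure(list(
    n_frames = as.integer(n_frames), height = as.integer(height),
    width = as.integer(width), pixel_size = pixel_size,
    n_emitters = as.integer(n_emitters), psf_sigma = psf_sigma,
    amplitude = amplitude, background = background,
    p_on = p_on, p_off = p_off, initial_on_prob = initial_on_prob,
    shot_noise = isTRUE(shot_noise), read_noise_sd = read_noise_sd,
    min_separation = min_separation,
    enforce_separation = isTRUE(enforce_separation),
    seed = seed, dtype = dtype
  ), class = "SimulationConfig")
}

#' Simulate ON/OFF blinking state traces
#'
#' Each emitter's trace is an independent two-state Markov (telegraph)
#' chain: an OFF emitter turns ON with per-frame probability `p_on`, an ON
#' emitter turns OFF with probability `p_off`. The stationary ON
#' probability is `p_on / (p_on + p_off)`.
#'
#' @param n_emitters number of emitters (rows).
#' @param n_frames number of frames (columns), >= 1.
#' @param p_on,p_off per-frame switching probabilities in \[0, 1\].
#' @param initial_on_prob probability of starting ON; default the
#'   stationary probability.
#' @param seed optional RNG seed for reproducibility.
#' @return Logical matrix `n_emitters x n_frames`; `TRUE` = ON.
#' @export
simulate_states <- function(n_emitters, n_frames, p_on, p_off,
                            initial_on_prob = NULL, seed = NULL) {
  for (p in list(p_on, p_off))
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      bc_stop("bad_probability", "p_on and p_off must be in [0, 1]")
  if (is.null(initial_on_prob))
    initial_on_prob <- if (p_on + p_off > 0) p_on / (p_on + p_off) else 0
  if (initial_on_prob < 0 || initial_on_prob > 1)
    bc_stop("bad_probability", "initial_on_prob must be in [0, 1]")
  if (n_frames < 1L)
    bc_stop("bad_config", "n_frames must be >= 1")
  if (n_emitters == 0L)
    return(matrix(FALSE, nrow = 0L, ncol = n_frames))
  with_seed(seed, {
    states <- matrix(FALSE, nrow = n_emitters, ncol = n_frames)
    states[, 1L] <- stats::runif(n_emitters) < initial_on_prob
    if (n_frames > 1L) {
      for (t in 2L:n_frames) {
        u <- stats::runif(n_emitters)
        on <- states[, t - 1L]
        states[, t] <- ifelse(on, u >= p_off, u < p_on)
      }
    }
    states
  })
}

place_emitters <- function(n, H, W, min_sep, enforce, retry_budget = 1000L) {
  pos <- matrix(NA_real_, nrow = n, ncol = 2L,
                dimnames = list(NULL, c("y", "x")))
  if (n == 0L) return(pos)
  accepted <- 0L
  tries <- 0L
  budget <- retry_budget * n
  while (accepted < n) {
    tries <- tries + 1L
    if (tries > budget)
      bc_stop("placement_failed",
              sprintf(paste0("could not place %d emitters with min separation",
                             " %.2f px in a %d x %d field after %d tries"),
                      n, min_sep, H, W, budget))
    cand <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    if (enforce && accepted > 0L) {
      d2 <- (pos[seq_len(accepted), 1L] - cand[1L])^2 +
            (pos[seq_len(accepted), 2L] - cand[2L])^2
      if (min(d2) < min_sep^2) next
    }
    accepted <- accepted + 1L
    pos[accepted, ] <- cand
  }
  pos
}

#' Render a synthetic blinking movie with ground truth
#'
#' Generates the movie defined by a [simulation_config()]: emitters are
#' placed uniformly at random (subject to the minimum-separation rule),
#' their ON/OFF traces are drawn from the telegraph model, and each frame
#' is `background` plus, for every ON emitter, a 2-D Gaussian of peak
#' `amplitude` and width `psf_sigma` sampled at pixel centres
#' (`psf_sigma = 0` puts all amplitude in the centre pixel). Optional
#' Poisson shot noise is applied to the noiseless image, then additive
#' Gaussian read noise; intensities are clipped at 0, rounded for integer
#' dtypes and saturated at the dtype maximum (the number of saturated
#' pixels is recorded in the stack's `"n_saturated"` attribute).
#'
#' @param config a [simulation_config()].
#' @return A list with `stack` (an [image_stack()]) and `truth` (a
#'   `GroundTruth`: `positions` — real-valued emitter centres `(y, x)` in
#'   pixels, `states` — logical emitter x frame ON matrix, `center_pixels`
#'   — rounded integer centres).
#' @export
render_movie <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  H <- config$height; W <- config$width; T <- config$n_frames
  with_seed(config$seed, {
    pos <- place_emitters(config$n_emitters, H, W, config$min_separation,
                          config$enforce_separation)
    states <- simulate_states(config$n_emitters, T, config$p_on,
                              config$p_off, config$initial_on_prob)
    # per-emitter static footprint: pixel indices + intensity contribution
    footprints <- lapply(seq_len(config$n_emitters), function(i) {
      cy <- pos[i, 1L]; cx <- pos[i, 2L]
      if (config$psf_sigma == 0) {
        py <- min(max(round(cy), 1L), H); px <- min(max(round(cx), 1L), W)
        return(list(idx = (px - 1L) * H + py, val = config$amplitude))
      }
      r <- ceiling(4 * config$psf_sigma)
      yy <- max(1L, floor(cy) - r):min(H, ceiling(cy) + r)
      xx <- max(1L, floor(cx) - r):min(W, ceiling(cx) + r)
      g <- outer(yy, xx, function(y, x)
        exp(-((y - cy)^2 + (x - cx)^2) / (2 * config$psf_sigma^2)))
      idx <- as.vector(outer(yy, xx, function(y, x) (x - 1L) * H + y))
      list(idx = idx, val = config$amplitude * as.vector(g))
    })
    data <- array(0, dim = c(H, W, T))
    n_sat <- 0L
    dmax <- DTYPE_MAX[[config$dtype]]
    for (t in seq_len(T)) {
      fr <- rep(config$background, H * W)
      for (i in seq_len(config$n_emitters)) {
        if (states[i, t]) {
          fp <- footprints[[i]]
          fr[fp$idx] <- fr[fp$idx] + fp$val
        }
      }
      if (config$shot_noise) fr <- stats::rpois(H * W, fr)
      if (config$read_noise_sd > 0)
        fr <- fr + stats::rnorm(H * W, 0, config$read_noise_sd)
      fr <- pmax(fr, 0)
      if (config$dtype != "float32") {
        fr <- round(fr)
        n_sat <- n_sat + sum(fr > dmax)
        fr <- pmin(fr, dmax)
      }
      data[, , t] <- fr
    }
    stack <- image_stack(data, pixel_size = config$pixel_size,
                         is_filtered = FALSE, dtype = config$dtype)
    attr(stack, "n_saturated") <- n_sat
    truth <- structure(list(
      positions = pos,
      states = states,
      center_pixels = cbind(y = pmin(pmax(round(pos[, 1L]), 1L), H),
                            x = pmin(pmax(round(pos[, 2L]), 1L), W))
    ), class = "GroundTruth")
    list(stack = stack, truth = truth)
  })
}

#' Score a detection result against simulation ground truth
#'
#' Because the detector counts pixels, not clustered molecules, scoring is
#' pixel-centred: an emitter counts as recovered when some detected pixel
#' lies within `match_radius` (Euclidean, in pixels) of its rounded centre
#' pixel. Recall is taken over the emitters that *blinked* — showed at
#' least one ON/OFF transition within the movie — since an emitter that is
#' constantly ON or OFF produces no three-frame transient to find. The
#' false-positive rate is the fraction of all pixels that are detected yet
#' farther than `match_radius` from every emitter centre.
#'
#' @param result a `DetectionResult`.
#' @param truth a `GroundTruth` from [render_movie()].
#' @param match_radius matching radius in pixels, default 1.
#' @return A list: `recall`, `false_positive_rate` (both in \[0, 1\]),
#'   `n_blinking`, `n_recovered`, `n_false_pixels`.
#' @export
evaluate_detection <- function(result, truth, match_radius = 1) {
  stopifnot(inherits(result, "DetectionResult"),
            inherits(truth, "GroundTruth"))
  mask <- result$mask
  H <- nrow(mask); W <- ncol(mask)
  n_em <- nrow(truth$states)
  if (n_em > 0L &&
      (any(truth$center_pixels[, 1L] > H) || any(truth$center_pixels[, 2L] > W)))
    bc_stop("dimension_mismatch", "truth does not fit the mask dimensions")
  blinked <- if (ncol(truth$states) < 2L) rep(FALSE, n_em) else
    apply(truth$states, 1L, function(s) any(s[-1L] != s[-length(s)]))
  offs <- expand.grid(dy = -ceiling(match_radius):ceiling(match_radius),
                      dx = -ceiling(match_radius):ceiling(match_radius))
  offs <- offs[offs$dy^2 + offs$dx^2 <= match_radius^2, , drop = FALSE]
  near_hit <- function(cy, cx) {
    yy <- cy + offs$dy; xx <- cx + offs$dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    any(mask[cbind(yy[ok], xx[ok])])
  }
  recovered <- logical(n_em)
  for (i in seq_len(n_em))
    recovered[i] <- near_hit(truth$center_pixels[i, 1L],
                             truth$center_pixels[i, 2L])
  near_emitter <- matrix(FALSE, H, W)
  for (i in seq_len(n_em)) {
    yy <- truth$center_pixels[i, 1L] + offs$dy
    xx <- truth$center_pixels[i, 2L] + offs$dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    near_emitter[cbind(yy[ok], xx[ok])] <- TRUE
  }
  n_false <- sum(mask & !near_emitter)
  n_blinking <- sum(blinked)
  list(
    recall = if (n_blinking > 0L) sum(recovered[blinked]) / n_blinking else NA_real_,
    false_positive_rate = n_false / (H * W),
    n_blinking = n_blinking,
    n_recovered = sum(recovered[blinked]),
    n_false_pixels = n_false
  )
}
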