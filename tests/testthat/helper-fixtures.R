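# Programmatic fixtures: all test inputs are generated in code.

# Seeded random integer stack (uint8-range by default).
random_stack <- function(seed, n_frames, height, width, max_val = 255,
                         ...) {
  set.seed(seed)
  image_stack(array(sample(0:max_val, height * width * n_frames,
                           replace = TRUE),
                    c(height, width, n_frames)), ...)
}

# A stack that is zero everywhere except one pixel carrying a given trace.
trace_stack <- function(trace, height = 8, width = 8, y = 4, x = 4) {
  a <- array(0, c(height, width, length(trace)))
  a[y, x, ] <- trace
  image_stack(a)
}

# A stack with a block of pixels all carrying the same trace.
block_stack <- function(trace, height = 9, width = 9, ys = 4:6, xs = 4:6) {
  a <- array(0, c(height, width, length(trace)))
  for (t in seq_along(trace)) a[ys, xs, t] <- trace[t]
  image_stack(a)
}

tmp_tif <- function() tempfile(fileext = ".tif")
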