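test_that("three-frame criterion on single traces: strictness, constants, ramps", {
  r <- detect_pixel_trace(c(0, 10, 0), tau = 5)
  expect_true(r$detected)
  expect_equal(r$first_hit, 1L)

  # strict inequality: 10 > 10 is false
  expect_false(detect_pixel_trace(c(0, 10, 0), tau = 10)$detected)

  # constant traces never fire
  expect_false(detect_pixel_trace(rep(7, 10), tau = 0)$detected)

  # the criterion is on absolute changes: a steep monotone ramp fires too
  expect_true(detect_pixel_trace(c(0, 6, 12), tau = 5)$detected)

  # earliest satisfying window wins
  r2 <- detect_pixel_trace(c(0, 0, 9, 0, 9, 0), tau = 5)
  expect_equal(r2$first_hit, 2L)

  expect_error(detect_pixel_trace(c(0, 1), tau = 1),
               class = "blinkcount_error_trace_too_short")
})

test_that("stack detection composes the trace rule; empty and single-pixel cases", {
  zero <- image_stack(array(0, c(16, 16, 10)))
  d0 <- detect_stack(zero, detector_params(1))
  expect_equal(d0$count, 0L)
  expect_false(any(d0$mask))
  expect_true(all(is.na(d0$first_hit)))

  tr <- trace_stack(c(0, 10, rep(0, 4)), y = 3, x = 5)
  d1 <- detect_stack(tr, detector_params(5))
  expect_equal(d1$count, 1L)
  expect_true(d1$mask[3, 5])
  expect_equal(sum(d1$mask), 1L)
  expect_equal(d1$first_hit[3, 5], 1L)
})

test_that("vectorised detector is identical to the loop oracle", {
  for (seed in 1:10) {
    s <- random_stack(seed, 6, 8, 8)
    for (tau in c(0, 30, 120)) {
      a <- detect_stack(s, detector_params(tau))
      b <- detect_oracle(s, detector_params(tau))
      expect_identical(a$mask, b$mask, info = paste(seed, tau))
      expect_identical(a$first_hit, b$first_hit, info = paste(seed, tau))
      expect_identical(a$count, b$count)
    }
  }
})

test_that("DetectionResult invariants hold", {
  s <- random_stack(77, 8, 12, 10)
  d <- detect_stack(s, detector_params(40))
  expect_equal(d$count, sum(d$mask))
  expect_true(d$count >= 0 && d$count <= 12 * 10)
  fh <- d$first_hit[!is.na(d$first_hit)]
  expect_true(all(fh >= 1 & fh <= s$n_frames - 2))
  expect_identical(is.na(d$first_hit), !d$mask)
})

test_that("threshold monotonicity: masks nest and counts fall as tau rises", {
  s <- random_stack(42, 8, 16, 16)
  taus <- seq(0, 200, length.out = 20)
  prev <- NULL
  for (tau in taus) {
    d <- detect_stack(s, detector_params(tau))
    if (!is.null(prev)) {
      expect_lte(d$count, prev$count)
      expect_true(all(prev$mask | !d$mask))  # mask(tau_b) subset of mask(tau_a)
    }
    prev <- d
  }
  # infinite-threshold limit: no finite stack detects
  expect_equal(detect_stack(s, detector_params(1e18))$count, 0L)
})

test_that("spatial transposition transposes the mask and preserves N", {
  s <- random_stack(13, 6, 7, 9)
  st <- image_stack(aperm(s$data, c(2, 1, 3)))
  a <- detect_stack(s, detector_params(50))
  b <- detect_stack(st, detector_params(50))
  expect_identical(b$mask, t(a$mask))
  expect_identical(b$count, a$count)
})

test_that("temporal locality: constant padding shifts but never removes detections", {
  s <- random_stack(23, 5, 8, 8)
  d <- detect_stack(s, detector_params(60))
  # appending constant frames keeps every detection
  app <- image_stack(array(c(s$data, s$data[, , 5], s$data[, , 5]),
                           c(8, 8, 7)))
  da <- detect_stack(app, detector_params(60))
  expect_true(all(da$mask | !d$mask))
  # prepending one constant copy of frame 1 shifts first hits by one
  pre <- image_stack(array(c(s$data[, , 1], s$data), c(8, 8, 6)))
  dp <- detect_stack(pre, detector_params(60))
  keep <- d$mask
  expect_identical(dp$first_hit[keep], d$first_hit[keep] + 1L)
})

test_that("pipeline: the 3x3 median erases single-pixel transients but keeps blocks", {
  lone <- trace_stack(c(0, 10, 0), height = 9, width = 9, y = 5, x = 5)
  d_lone <- run_pipeline(lone, filter_params(), detector_params(5))
  expect_equal(d_lone$count, 0L)

  blk <- block_stack(c(0, 10, 0))
  d_blk <- run_pipeline(blk, filter_params(), detector_params(5))
  expect_gte(d_blk$count, 1L)
  expect_true(d_blk$mask[5, 5])   # block centre survives the median
  expect_true(d_blk$source_filtered)
})

test_that("pipeline equals the composition of the two oracles on a simulated movie", {
  sim <- render_movie(simulation_config(n_frames = 8, height = 16, width = 16,
                                        n_emitters = 3, psf_sigma = 1,
                                        shot_noise = FALSE, read_noise_sd = 1,
                                        seed = 5))
  got <- run_pipeline(sim$stack, filter_params(), detector_params(40))
  want <- detect_oracle(median_filter_oracle(sim$stack, filter_params()),
                        detector_params(40))
  expect_identical(got$mask, want$mask)
  expect_identical(got$count, want$count)
})

test_that("detector rejects short or non-finite stacks and bad tau", {
  expect_error(detect_stack(image_stack(array(0, c(4, 4, 2))),
                            detector_params(1)),
               class = "blinkcount_error_trace_too_short")
  expect_error(detector_params(-1), class = "blinkcount_error_bad_tau")
  expect_error(detector_params(Inf), class = "blinkcount_error_bad_tau")
})
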