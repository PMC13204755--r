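make_sweep_movies <- function(emitters = c(3, 6, 12), seed0 = 100,
                              side = 28, n_frames = 10) {
  lapply(seq_along(emitters), function(i) {
    sim <- render_movie(simulation_config(
      n_frames = n_frames, height = side, width = side,
      n_emitters = emitters[i], psf_sigma = 1, amplitude = 150,
      background = 5, read_noise_sd = 1, shot_noise = FALSE,
      min_separation = 5, seed = seed0 + i))
    movie_record(paste0("m", i), concentration = emitters[i], sim$stack)
  })
}

test_that("threshold sweeps: zero movies count zero, counts fall with tau", {
  zero <- movie_record("blank", 1,
                       image_stack(array(0, c(12, 12, 6))))
  sw <- sweep_thresholds(list(zero), c(1, 10))
  expect_equal(unname(sw$counts["blank", ]), c(0, 0))

  movies <- make_sweep_movies()
  sw2 <- sweep_thresholds(movies, c(5, 50))
  expect_true(all(sw2$counts[, "5"] >= sw2$counts[, "50"]))
})

test_that("sweep table equals per-cell recomputation through the oracles", {
  movies <- make_sweep_movies(c(2, 4, 8), side = 16, n_frames = 6)
  taus <- c(20, 60, 120)
  sw <- sweep_thresholds(movies, taus)
  for (i in seq_along(movies)) {
    filt <- median_filter_oracle(movies[[i]]$stack, filter_params())
    for (j in seq_along(taus)) {
      expect_identical(sw$counts[i, j],
                       as.numeric(detect_oracle(filt,
                                                detector_params(taus[j]))$count),
                       info = paste(i, taus[j]))
    }
  }
})

test_that("threshold selection prefers the tau preserving the concentration trend", {
  # constructed sweep: tau = 50 non-monotone, tau = 150 strictly increasing
  sw <- structure(list(
    taus = c(50, 150),
    counts = matrix(c(900, 700, 1200,   # tau 50: dips at mid concentration
                      10, 40, 90),      # tau 150: strictly increasing
                    nrow = 3, dimnames = list(c("a", "b", "c"),
                                              c("50", "150"))),
    labels = c("a", "b", "c"),
    concentrations = c(1, 10, 100),
    provenance = filter_params()
  ), class = "SweepResult")
  sel <- select_threshold(sw)
  expect_equal(sel$tau_star, 150)
  expect_true(sel$monotone_found)
  expect_equal(nrow(sel$diagnostics), 2L)

  # a single-tau sweep returns that tau
  sw1 <- sw; sw1$taus <- 150; sw1$counts <- sw$counts[, 2, drop = FALSE]
  expect_equal(select_threshold(sw1)$tau_star, 150)

  # no monotone tau: best-ranked returned with a classed warning, never silently
  swn <- sw
  swn$counts <- matrix(c(900, 700, 1200, 90, 40, 10), nrow = 3,
                       dimnames = dimnames(sw$counts))
  expect_warning(seln <- select_threshold(swn),
                 class = "blinkcount_warning_no_monotone_tau")
  expect_false(seln$monotone_found)
})

test_that("selection equals exhaustive evaluation of the documented score", {
  movies <- make_sweep_movies(c(3, 6, 12), seed0 = 300)
  taus <- c(10, 40, 80, 120)
  sw <- sweep_thresholds(movies, taus)
  sel <- suppressWarnings(select_threshold(sw))
  # independent re-scoring: lexicographic (monotone, R^2, blank count, tau)
  conc <- sw$concentrations
  score <- lapply(seq_along(sw$taus), function(j) {
    cnt <- sw$counts[, j]
    mono <- all(diff(cnt[order(conc)]) > 0)
    r2 <- tryCatch(fit_log_linear(conc, cnt)$r_squared,
                   error = function(e) NA_real_)
    list(mono = mono, r2 = ifelse(is.na(r2), -Inf, r2),
         blank = cnt[which.min(conc)])
  })
  ord <- order(-vapply(score, function(s) as.numeric(s$mono), 1),
               -vapply(score, `[[`, 1, "r2"),
               vapply(score, `[[`, 1, "blank"),
               sw$taus)
  expect_equal(sel$tau_star, sw$taus[ord[1]])
})

test_that("grid density: counts per square, normalisation, edge discard", {
  # 36 um^2 squares at 1 um/px on a 12x12 mask -> four 6x6 grids
  spec <- grid_spec(pixel_size = 1, square_area = 36)
  expect_equal(spec$side_px, 6L)
  m <- matrix(FALSE, 12, 12)
  m[1:3, 1:3] <- TRUE           # 9 marks inside grid (1,1)
  d <- grid_density(m, spec)
  expect_equal(d$n_grids, 4L)
  expect_equal(d$per_grid_counts[1, 1], 9)
  expect_equal(d$densities[1, 1], 0.25)  # 9 / 36 um^2
  expect_equal(sum(d$per_grid_counts), 9)
  expect_equal(d$mean_density, 9 / 36 / 4)

  # empty mask
  d0 <- grid_density(matrix(FALSE, 12, 12), spec)
  expect_true(all(d0$densities == 0))
  expect_equal(d0$mean_density, 0)

  # partial edge squares are discarded: 13th row/col never counted
  m2 <- matrix(FALSE, 13, 13)
  m2[13, ] <- TRUE; m2[, 13] <- TRUE
  expect_equal(sum(grid_density(m2, spec)$per_grid_counts), 0)
})

test_that("per-grid counts match a brute-force tally on random masks", {
  set.seed(9)
  m <- matrix(runif(20 * 17) < 0.2, 20, 17)
  spec <- grid_spec(pixel_size = 1, square_area = 36)
  d <- grid_density(m, spec)
  side <- spec$side_px
  for (gy in 1:(20 %/% side)) for (gx in 1:(17 %/% side)) {
    expect_equal(d$per_grid_counts[gy, gx],
                 sum(m[(gy - 1) * side + 1:side, (gx - 1) * side + 1:side]),
                 info = paste(gy, gx))
  }
  # conservation: full-square tallies never exceed the total mask count
  expect_lte(sum(d$per_grid_counts), sum(m))
  # exact-multiple case: equality
  m3 <- matrix(runif(12 * 12) < 0.3, 12, 12)
  expect_equal(sum(grid_density(m3, spec)$per_grid_counts), sum(m3))
})

test_that("grid selection: explicit subsets and seeded random choice", {
  m <- matrix(FALSE, 12, 12)
  m[1:6, 1:6] <- TRUE   # grid 1 full: density 1 count/um^2
  spec <- grid_spec(pixel_size = 1)
  expect_equal(grid_density(m, spec, selected_grids = 1)$mean_density, 1)
  expect_equal(grid_density(m, spec, selected_grids = c(2, 3, 4))$mean_density, 0)
  a <- grid_density(m, spec, n_select = 3, seed = 4)
  b <- grid_density(m, spec, n_select = 3, seed = 4)
  expect_identical(a$selected_grids, b$selected_grids)
  expect_error(grid_density(m, grid_spec(pixel_size = 0.1)),
               class = "blinkcount_error_grid_too_large")
})

test_that("log-linear calibration: exact line, degenerate cases, OLS oracle", {
  fit <- fit_log_linear(c(1, 10, 100), c(1, 3, 5))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  cst <- fit_log_linear(c(1, 10, 100), c(4, 4, 4))
  expect_equal(cst$slope, 0)
  expect_false(cst$r_squared_defined)
  expect_true(is.na(cst$r_squared))

  expect_error(fit_log_linear(c(1), c(2)),
               class = "blinkcount_error_too_few_points")
  expect_error(fit_log_linear(c(0, 10), c(1, 2)),
               class = "blinkcount_error_bad_concentration")
  expect_error(fit_log_linear(c(5, 5, 5), c(1, 2, 3)),
               class = "blinkcount_error_degenerate_x")

  # closed-form OLS oracle on seeded noisy points
  set.seed(12)
  conc <- 10^runif(5, 0, 3)
  y <- 2.5 * log10(conc) + 1 + rnorm(5)
  f <- fit_log_linear(conc, y)
  x <- log10(conc); n <- 5
  sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  ic <- (sum(y) - sl * sum(x)) / n
  r2 <- 1 - sum((y - ic - sl * x)^2) / sum((y - mean(y))^2)
  expect_equal(f$slope, sl, tolerance = 1e-12)
  expect_equal(f$intercept, ic, tolerance = 1e-12)
  expect_equal(f$r_squared, r2, tolerance = 1e-12)
})

test_that("calibration fit invariances: shift and scale of the response", {
  set.seed(31)
  conc <- c(1, 5, 25, 125, 625)
  y <- 0.8 * log10(conc) + rnorm(5, 0, 0.1)
  base <- fit_log_linear(conc, y)
  sh <- fit_log_linear(conc, y + 3)
  expect_equal(sh$slope, base$slope)
  expect_equal(sh$intercept, base$intercept + 3)
  expect_equal(sh$r_squared, base$r_squared)
  sc <- fit_log_linear(conc, y * 10)
  expect_equal(sc$slope, base$slope * 10)
  expect_equal(sc$intercept, base$intercept * 10)
  expect_equal(sc$r_squared, base$r_squared)
})

test_that("method comparison mirrors the manual-vs-automated table", {
  conc <- c(1, 10, 100)
  manual <- data.frame(concentration = conc, response = c(0.3, 0.4, 0.5))
  auto_same <- data.frame(concentration = conc, response = c(0.3, 0.4, 0.5))
  cmp <- compare_methods(manual, auto_same)
  expect_equal(cmp$manual_fit$slope, cmp$auto_fit$slope)
  expect_equal(cmp$manual_fit$r_squared, cmp$auto_fit$r_squared)

  # scaled series: slope scales, R^2 invariant (the cross-method scale gap)
  auto_scaled <- data.frame(concentration = conc,
                            response = c(0.3, 0.4, 0.5) * 100)
  cmp2 <- compare_methods(manual, auto_scaled)
  expect_equal(cmp2$auto_fit$slope, cmp2$manual_fit$slope * 100)
  expect_equal(cmp2$auto_fit$r_squared, cmp2$manual_fit$r_squared)

  expect_error(compare_methods(manual,
                               data.frame(concentration = c(1, 10, 50),
                                          response = 1:3)),
               class = "blinkcount_error_mismatched_concentrations")
})
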