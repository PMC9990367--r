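# Image pipeline: registration, smoothing, Li masking, trace extraction.

test_that("estimate_drift recovers constructed shifts and flags noise", {
  set.seed(77)
  ref <- matrix(rnorm(48 * 48), 48)
  expect_identical(estimate_drift(ref, ref)[c("dy", "dx")],
                   list(dy = 0L, dx = 0L))
  expect_equal(estimate_drift(ref, ref)$score, 1.0, tolerance = 1e-12)
  # circular shift by (3, -2)
  circ <- function(m, dy, dx) {
    h <- nrow(m); w <- ncol(m)
    m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
  }
  est <- estimate_drift(circ(ref, 3, -2), ref)
  expect_identical(est[c("dy", "dx")], list(dy = 3L, dx = -2L))
  # independent white noise: low peak correlation
  est2 <- estimate_drift(matrix(rnorm(48 * 48), 48), ref)
  expect_true(est2$low_confidence)
  expect_error(estimate_drift(matrix(1, 8, 8), ref[1:8, 1:8]),
               "no structure")
})

test_that("register_stack recovers the renderer's drift truth and is a no-op without drift", {
  ser <- flat_series(lac = 1, duration = 8, dt = 0.5)
  scene <- single_cell_scene()
  still <- render_movie(ser, laconic_sensor(), scene, noise_model(),
                        frame_rate = 4)
  reg <- register_stack(still)
  expect_true(all(reg$drift$dy == 0) && all(reg$drift$dx == 0))
  expect_identical(reg$movie$num, still$num)

  drifted <- render_movie(ser, laconic_sensor(), scene,
                          noise_model(drift_sd = 0.6, seed = 9),
                          frame_rate = 4)
  truth <- drifted$metadata$drift_truth
  expect_true(any(truth$dy != 0 | truth$dx != 0))  # the path actually moved
  reg2 <- register_stack(drifted)
  expect_identical(reg2$drift$dy, truth$dy)
  expect_identical(reg2$drift$dx, truth$dx)

  single <- movie_stack(still$num[1, , , drop = FALSE],
                        still$den[1, , , drop = FALSE], 4)
  expect_error(register_stack(single), "single-frame")
})

test_that("registration reduces trace error under drift with noise", {
  ser <- flat_series(lac = 1, duration = 15, dt = 0.5)
  scene <- single_cell_scene()
  s <- laconic_sensor()
  truth_ratio <- sensor_forward(1, s)
  noisy <- render_movie(ser, s, scene,
                        noise_model(shot = TRUE, read_sd = 0.5,
                                    drift_sd = 0.8, seed = 31),
                        frame_rate = 4)
  mask_static <- build_mask(register_stack(noisy)$movie)
  reg <- register_stack(noisy)
  tr_reg <- extract_ratio_trace(reg$movie, mask_static, window = 1)
  tr_raw <- extract_ratio_trace(noisy, mask_static, window = 1)
  rms <- function(x) sqrt(mean((x - truth_ratio)^2))
  expect_lt(rms(tr_reg$ratio), rms(tr_raw$ratio))
})

test_that("temporal smoothing is a shrinking-window centered mean", {
  expect_identical(temporal_smooth(rep(3, 20), 11), rep(3, 20))
  x <- c(rep(0, 10), 1, rep(0, 10))
  sm <- temporal_smooth(x, 11)
  expect_equal(sm[6:16], rep(1 / 11, 11))
  expect_equal(sum(sm > 0), 11)
  expect_identical(temporal_smooth(x, 1), x)
  expect_error(temporal_smooth(x, 4), "odd")
  expect_error(temporal_smooth(rep(1, 5), 7), "exceeds")
  # variance reduction of an 11-frame mean on iid noise
  set.seed(5)
  z <- rnorm(10000)
  sz <- temporal_smooth(z, 11)[500:9500]
  expect_equal(var(sz), var(z) / 11, tolerance = 0.15)
  # linear and shift-equivariant
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(temporal_smooth(2 * a + 3 * b, 5),
               2 * temporal_smooth(a, 5) + 3 * temporal_smooth(b, 5))
  expect_equal(temporal_smooth(a, 5)[8:45],
               temporal_smooth(c(a[6:50], rnorm(5)), 5)[3:40])
})

test_that("Li threshold matches the closed-form two-level fixed point", {
  img <- matrix(c(rep(10, 128), rep(100, 128)), 16)
  thr <- li_threshold(img)
  expect_equal(thr, 90 / log(10), tolerance = 1e-6)
  expect_true(thr > 10 && thr < 100)
  expect_error(li_threshold(matrix(7, 8, 8)), "constant")
})

test_that("Li iteration minimizes the cross-entropy objective on mixtures", {
  for (seed in 1:10) {
    img <- mixture_image(seed)
    thr <- li_threshold(img)
    thr_scan <- li_bruteforce(img)
    # same partition: both thresholds fall in the same inter-intensity gap
    expect_identical(img > thr, img > thr_scan)
  }
})

test_that("Li handles nonpositive intensities by shifting", {
  img <- matrix(c(rep(-5, 100), rep(40, 100)), 10)
  thr <- li_threshold(img)
  expect_true(thr > -5 && thr < 40)
  expect_identical(img > thr, img > 0)  # separates the two levels
})

test_that("build_mask recovers the phantom geometry exactly", {
  scene <- single_cell_scene(shape = c(40, 40))
  ser <- flat_series(lac = 1, duration = 5, dt = 0.5)
  mv <- render_movie(ser, laconic_sensor(), scene, noise_model(),
                     frame_rate = 4)
  mk <- build_mask(mv)
  truth_mask <- fretflux:::cell_pixels(scene$cells[1, ], scene$shape)
  expect_identical(mk$mask, truth_mask)
  expect_equal(mk$fraction, sum(truth_mask) / (40 * 40))
  # all-background render has no contrast
  flat <- movie_stack(array(5, c(3, 8, 8)), array(5, c(3, 8, 8)), 1)
  expect_error(build_mask(flat), "constant|no tissue")
})

test_that("masked ratio extraction is exact for uniform and rendered input", {
  num <- array(200, c(6, 10, 10)); den <- array(100, c(6, 10, 10))
  mv <- movie_stack(num, den, 2)
  m <- matrix(TRUE, 10, 10)
  tr <- extract_ratio_trace(mv, m, window = 1)
  expect_equal(tr$ratio, rep(2, 6))
  # render-extract round trip at constant concentration
  s <- laconic_sensor()
  ser <- flat_series(lac = 2, duration = 5, dt = 0.5)
  mv2 <- render_movie(ser, s, single_cell_scene(), noise_model(), frame_rate = 4)
  mk <- build_mask(mv2)
  tr2 <- extract_ratio_trace(mv2, mk, window = 11)
  expect_equal(tr2$ratio, rep(sensor_forward(2, s), length(tr2$ratio)),
               tolerance = 1e-9)
  # zero denominator under the mask is an error
  den0 <- den; den0[3, , ] <- 0
  expect_error(extract_ratio_trace(movie_stack(num, den0, 2), m, 1),
               "denominator")
})

test_that("renders are deterministic under a seed and reject bad input", {
  ser <- flat_series(lac = 1, duration = 4, dt = 0.5)
  nm <- noise_model(shot = TRUE, read_sd = 1, drift_sd = 0.5, seed = 123)
  a <- render_movie(ser, laconic_sensor(), single_cell_scene(), nm, frame_rate = 4)
  b <- render_movie(ser, laconic_sensor(), single_cell_scene(), nm, frame_rate = 4)
  expect_identical(a$num, b$num)
  expect_identical(a$den, b$den)
  expect_identical(a$metadata$drift_truth, b$metadata$drift_truth)
  # series too short for the movie duration
  short <- flat_series(lac = 1, duration = 1, dt = 0.5)
  expect_error(render_movie(short, laconic_sensor(), single_cell_scene(),
                            noise_model(), frame_rate = 4, duration = 4),
               "duration")
})
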