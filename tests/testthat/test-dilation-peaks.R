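test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  t <- seq(0, 1, by = 0.005)
  cubic <- 5 + 2 * t - 3 * t^2 + 0.5 * t^3
  tr <- pupil_trace(t, cubic)
  sm <- fill_and_smooth(tr, peak_config())
  expect_equal(sm$value, cubic, tolerance = 1e-9)
  const <- pupil_trace(t, rep(5, length(t)))
  expect_equal(fill_and_smooth(const)$value, rep(5, length(t)), tolerance = 1e-12)
})

test_that("smoothing fills interior gaps but not the edges", {
  t <- seq(0, 1, by = 0.005)
  d <- 4 + 0.1 * t
  valid <- rep(TRUE, length(t))
  valid[1:10] <- FALSE; valid[80:90] <- FALSE; valid[195:201] <- FALSE
  d[!valid] <- NA
  tr <- pupil_trace(t, d, valid)
  sm <- fill_and_smooth(tr)
  expect_true(all(is.na(sm$value[1:10])))      # leading run stays missing
  expect_true(all(is.na(sm$value[195:201])))
  expect_equal(sm$value[80:90], 4 + 0.1 * t[80:90], tolerance = 1e-9)
  few <- pupil_trace(t[1:8], d[11:18])
  expect_error(fill_and_smooth(few), "smoothing window")
})

test_that("smoothing reduces the variance of a noisy signal", {
  set.seed(5)
  t <- seq(0, 10, by = 0.005)
  x <- sin(2 * pi * 0.2 * t) + rnorm(length(t), 0, 0.3)
  tr <- pupil_trace(t, 5 + x)
  sm <- fill_and_smooth(tr)
  expect_lt(var(diff(sm$value)), var(diff(x)))
})

test_that("velocity equals finite differences at the actual spacing", {
  t <- seq(0, 2, by = 0.005)
  ramp <- pupil_trace(t, 5 + 0.2 * t)
  v <- velocity(fill_and_smooth(ramp))
  expect_equal(v$velocity, rep(0.2, length(t)), tolerance = 1e-6)
  const <- velocity(list(time = t, value = rep(3, length(t))))
  expect_true(all(const$velocity == 0))
  set.seed(6)
  for (i in 1:50) {
    x <- cumsum(rnorm(40))
    tt <- seq(0, by = 0.005, length.out = 40)
    v2 <- velocity(list(time = tt, value = x))
    expect_equal(v2$velocity, oracle_derivative(tt, x))
  }
})

test_that("peak detection finds planted dilation events at the steepest rise", {
  cfg <- quiet_config()
  pc <- peak_config()
  # two events 5 s apart -> two peaks at the analytic max-slope times
  pt <- generate_pupil_trace(cfg, 30, event_times = c(5, 10), artifacts = FALSE)
  pk <- detect_velocity_peaks(velocity(fill_and_smooth(pt$trace, pc)), pc)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$time, c(5, 10) + steepest_rise_latency(cfg), tolerance = 0.1)
  # events 1 s apart -> a single peak survives the 1500 ms suppression
  pt2 <- generate_pupil_trace(cfg, 30, event_times = c(5, 6), artifacts = FALSE)
  pk2 <- detect_velocity_peaks(velocity(fill_and_smooth(pt2$trace, pc)), pc)
  expect_equal(nrow(pk2), 1)
  # a monotone ramp has a constant derivative: no local maxima, no peaks
  t <- seq(0, 30, by = 0.005)
  ramp <- pupil_trace(t, 5 + 0.01 * t)
  pk3 <- detect_velocity_peaks(velocity(fill_and_smooth(ramp, pc)), pc)
  expect_equal(nrow(pk3), 0)
})

test_that("suppression spacing, threshold monotonicity and scale equivariance hold", {
  set.seed(7)
  cfg <- synthetic_config()
  for (i in 1:5) {
    ev <- generate_dilation_events(cfg, 90, seed = i)
    pt <- generate_pupil_trace(cfg, 90, ev, artifacts = FALSE)
    vel <- velocity(fill_and_smooth(pt$trace))
    pk <- detect_velocity_peaks(vel, peak_config())
    if (nrow(pk) > 1) expect_true(all(diff(pk$time) >= 1.5))
    pk_hi <- detect_velocity_peaks(vel, peak_config(threshold_sd = 3.5))
    expect_lte(nrow(pk_hi), nrow(pk))
    # scaling the trace leaves peak times unchanged (SD-relative threshold)
    sc <- pt$trace
    sc2 <- pupil_trace(sc$time, sc$diameter * 3.7, sc$valid)
    pk_sc <- detect_velocity_peaks(velocity(fill_and_smooth(sc2)), peak_config())
    expect_equal(pk_sc$time, pk$time)
  }
})

test_that("plateau candidates use the plateau midpoint", {
  t <- seq(0, by = 0.005, length.out = 41)
  v <- c(rep(0, 15), 1, 2, 2, 2, 1, rep(0, 20))
  pk <- detect_velocity_peaks(list(time = t, velocity = v),
                              peak_config(threshold_sd = 0.5))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time, t[18])   # midpoint of the three-sample plateau
})

test_that("per-phase peak counting is half-open", {
  pk <- data.frame(time = c(10, 29.999, 30), velocity = 1)
  class(pk) <- c("peak_train", "data.frame")
  expect_equal(peaks_per_phase(pk, phase_window("baseline", 0, 30)), 2)
  expect_equal(peaks_per_phase(pk, phase_window("audio", 30, 60)), 1)
  none <- data.frame(time = numeric(0), velocity = numeric(0))
  expect_equal(peaks_per_phase(none, phase_window("baseline", 0, 30)), 0)
})

test_that("per-phase mean pupil size averages usable samples only", {
  t <- seq(0, by = 0.005, length.out = 6000)
  expect_equal(mean_pupil_size_per_phase(pupil_trace(t, rep(5, 6000)),
                                         phase_window("baseline", 0, 30)), 5)
  half <- pupil_trace(t, rep(c(4, 6), each = 3000))
  expect_equal(mean_pupil_size_per_phase(half, phase_window("baseline", 0, 30)), 5)
  set.seed(8)
  for (i in 1:20) {
    tr <- random_masked_trace(n = 300)
    w <- phase_window("baseline", 0.2, 1.1)
    sel <- tr$time >= 0.2 & tr$time < 1.1 & ok_mask(tr)
    expect_equal(suppressWarnings(mean_pupil_size_per_phase(tr, w)),
                 mean(tr$diameter[sel]))
  }
  gone <- pupil_trace(t[1:100], rep(NA_real_, 100), rep(FALSE, 100))
  expect_warning(res <- mean_pupil_size_per_phase(gone, phase_window("baseline", 0, 0.5)),
                 "no usable")
  expect_true(is.na(res))
})

test_that("all-missing segments yield an empty peak train with a warning", {
  expect_warning(
    pk <- detect_velocity_peaks(list(time = 1:10 / 200,
                                     velocity = rep(NA_real_, 10)),
                                peak_config()),
    "all-missing")
  expect_equal(nrow(pk), 0)
})
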