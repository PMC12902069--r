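test_that("event-span interpolation reconstructs a linear signal exactly", {
  tr <- make_trace(n = 1000, f = function(t) 4 + 0.1 * t)
  bl <- ocular_events(2.0, 2.2, "blink")
  out <- interpolate_event_spans(tr, bl, pre = 100, post = 150)
  span <- out$time >= 1.9 & out$time <= 2.35
  expect_true(all(out$interpolated[span]))
  expect_false(any(out$interpolated[!span]))
  expect_equal(out$diameter, 4 + 0.1 * out$time, tolerance = 1e-12)
  # identity on an empty event list
  none <- interpolate_event_spans(tr, ocular_events(numeric(0), numeric(0),
                                                    character(0)), 100, 150)
  expect_identical(none$diameter, tr$diameter)
})

test_that("spans without an anchor are invalidated, not extrapolated", {
  tr <- make_trace(n = 200)
  bl <- ocular_events(0.001, 0.05, "blink")
  expect_warning(out <- interpolate_event_spans(tr, bl, 100, 150), "anchor")
  span <- out$time <= 0.2
  expect_true(all(!out$valid[span] & !out$interpolated[span]))
  expect_true(all(is.na(out$diameter[span])))
})

test_that("dilation speed matches its definition and the brute-force oracle", {
  flat <- make_trace(n = 50, f = function(t) rep(5, length(t)))
  expect_true(all(dilation_speed(flat) == 0))

  tr <- pupil_trace(seq(0, by = 0.005, length.out = 4), c(5, 5, 6, 6))
  expect_equal(dilation_speed(tr), c(0, 200, 200, 0))

  set.seed(10)
  for (i in 1:50) {
    tr <- random_masked_trace(n = 60)
    expect_equal(dilation_speed(tr),
                 oracle_speed(tr$time, tr$diameter, ok_mask(tr)))
  }
  tiny <- pupil_trace(c(0, 0.005, 0.01), c(5, NA, 5.1))
  expect_error(dilation_speed(tiny), "at least 3")
})

test_that("MAD speed filtering flags exactly the planted spike", {
  t <- seq(0, by = 0.005, length.out = 2000)
  # smooth sinusoid: its speed distribution is bounded, with median + 3*MAD
  # above the maximum, so only the planted spike exceeds the threshold
  d <- 5 + 0.2 * sin(2 * pi * 0.05 * t)
  d[700] <- d[700] + 10
  tr <- pupil_trace(t, d)
  out <- mad_speed_filter(tr, 3)
  flagged <- which(!ok_mask(out))
  expect_true(700 %in% flagged)
  expect_true(all(abs(flagged - 700) <= 1))   # spike and its direct neighbors
  # degenerate flat trace: nothing flagged, warning raised
  flat <- make_trace(n = 100, f = function(t) rep(5, length(t)))
  expect_warning(same <- mad_speed_filter(flat), "MAD is zero")
  expect_identical(same$valid, flat$valid)
})

test_that("gap-edge trimming pads long gaps and is idempotent", {
  n <- 1000
  valid <- rep(TRUE, n)
  valid[401:420] <- FALSE                      # 100 ms gap at 200 Hz
  tr <- make_trace(n = n, valid = valid)
  out <- trim_gap_edges(tr, pad = 50, min_gap = 75)
  expect_equal(which(!ok_mask(out)), 391:430)  # 10 samples each side
  expect_true(all(out$trimmed[c(391:400, 421:430)]))
  again <- trim_gap_edges(out, pad = 50, min_gap = 75)
  expect_identical(again$valid, out$valid)
  expect_identical(again$trimmed, out$trimmed)

  # 60 ms gap stays untouched under the 75 ms threshold
  valid2 <- rep(TRUE, n); valid2[101:112] <- FALSE
  tr2 <- make_trace(n = n, valid = valid2)
  out2 <- trim_gap_edges(tr2, 50, 75)
  expect_identical(ok_mask(out2), ok_mask(tr2))

  # adjacent gaps with overlapping pads: the union is invalidated
  valid3 <- rep(TRUE, n)
  valid3[301:320] <- FALSE; valid3[331:350] <- FALSE
  tr3 <- make_trace(n = n, valid = valid3)
  out3 <- trim_gap_edges(tr3, 50, 75)
  expect_equal(which(!ok_mask(out3)), 291:360)
  again3 <- trim_gap_edges(out3, 50, 75)
  expect_identical(ok_mask(again3), ok_mask(out3))
})

test_that("sparsity filtering removes flanked islands per the rule", {
  n <- 400
  # 40 ms island (8 samples) between two 50 ms gaps (10 samples)
  valid <- rep(TRUE, n)
  valid[101:110] <- FALSE; valid[119:128] <- FALSE
  tr <- make_trace(n = n, valid = valid)
  out <- sparsity_filter(tr, max_island = 50, flank_gap = 40)
  expect_true(all(!ok_mask(out)[111:118]))

  # a 30 ms flank on one side protects the island
  valid2 <- rep(TRUE, n)
  valid2[101:106] <- FALSE; valid2[115:124] <- FALSE   # 30 ms | island | 50 ms
  tr2 <- make_trace(n = n, valid = valid2)
  out2 <- sparsity_filter(tr2, 50, 40)
  expect_true(all(ok_mask(out2)[107:114]))
})

test_that("sparsity filtering equals the brute-force scan and is idempotent", {
  set.seed(22)
  for (i in 1:60) {
    n <- 150
    valid <- runif(n) > 0.35
    tr <- make_trace(n = n, valid = valid)
    out <- sparsity_filter(tr, 50, 40)
    expect_identical(ok_mask(out), oracle_sparsity(valid, 5, 50, 40))
    again <- sparsity_filter(out, 50, 40)
    expect_identical(ok_mask(again), ok_mask(out))
  }
})

test_that("missing fractions use expected sample counts and strict exclusion", {
  tr <- make_trace(n = 6000, f = function(t) rep(5, length(t)))
  w <- phase_window("baseline", 0, 30)
  expect_equal(missing_fraction(tr, w), 0)
  valid <- rep(TRUE, 6000); valid[1:1800] <- FALSE    # 9 s of 30 s
  tr2 <- make_trace(n = 6000, valid = valid)
  expect_equal(missing_fraction(tr2, w), 0.30)
  cfg <- preprocess_config()
  expect_false(missing_fraction(tr2, w) > cfg$missing_exclusion_threshold)
  expect_error(missing_fraction(tr, phase_window("audio", 10, 10.0001)),
               "empty")
})

test_that("the full chain preserves clean signal and never revalidates", {
  set.seed(33)
  cfg <- quiet_config()
  res <- assemble_dyad(cfg, seed = 33)
  m <- res$dyad$listener
  pp <- preprocess_participant(m, preprocess_config())
  out <- pp$trace
  expect_identical(out$time, m$trace$time)     # timestamps never altered
  # noise-free artifact-free: values outside interpolated spans are unchanged
  same <- out$valid & m$trace$valid
  expect_equal(out$diameter[same], m$trace$diameter[same], tolerance = 0)
  # monotone invalidation: usable-sample set only shrinks after interpolation
  interp_only <- preprocess_pipeline(
    m$trace, events_of_kind(m$events, "blink"),
    events_of_kind(m$events, "saccade"),
    preprocess_config(do_mad = FALSE, do_trim = FALSE, do_sparsity = FALSE))$trace
  expect_true(all(ok_mask(out) <= ok_mask(interp_only)))
  # report counts are consistent with the final mask
  expect_equal(pp$report$final_missing, sum(!ok_mask(out)))
  expect_true(all(pp$report$counts >= 0))
})

test_that("stage switches disable individual stages", {
  set.seed(44)
  tr <- random_masked_trace(n = 2000, p_invalid = 0.05)
  cfg_off <- preprocess_config(do_blink_interp = FALSE,
                               do_saccade_interp = FALSE, do_mad = FALSE,
                               do_trim = FALSE, do_sparsity = FALSE)
  none <- ocular_events(numeric(0), numeric(0), character(0))
  out <- preprocess_pipeline(tr, none, none, cfg_off)
  expect_identical(out$trace$valid, tr$valid)
  expect_identical(out$trace$diameter, tr$diameter)
})
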