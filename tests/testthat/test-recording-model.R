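test_that("pupil trace parsing keeps missing samples missing", {
  f <- write_tmp(c("timestamp,diameter", "0.000,5.0", "0.005,5.1", "0.010,NaN"))
  tr <- read_pupil_trace(f)
  expect_equal(n_samples(tr), 3)
  expect_equal(tr$valid, c(TRUE, TRUE, FALSE))
  expect_true(is.na(tr$diameter[3]))
  expect_equal(tr$diameter[1:2], c(5.0, 5.1))
})

test_that("trace reader rejects malformed files", {
  f <- write_tmp(c("timestamp", "0.000", "0.005"))
  expect_error(read_pupil_trace(f), "diameter")
  f2 <- write_tmp(c("timestamp,diameter", "0.010,5.0", "0.005,5.1"))
  expect_error(read_pupil_trace(f2), "increasing at index 2")
})

test_that("trace write/read round trip is lossless at stated precision", {
  set.seed(1)
  cfg <- synthetic_config()
  pt <- generate_pupil_trace(cfg, 2, event_times = 0.5, artifacts = TRUE)
  f <- tempfile(fileext = ".csv")
  write_pupil_trace(pt$trace, f)
  back <- read_pupil_trace(f)
  # lossless at the stated precision: 1e-6 s timestamps, 1e-9 diameters
  expect_lt(max(abs(back$time - pt$trace$time)), 1e-6)
  expect_lt(max(abs(back$diameter - pt$trace$diameter), na.rm = TRUE), 1e-9)
  expect_identical(back$valid, pt$trace$valid)
  expect_identical(back$interpolated, pt$trace$interpolated)
  # a second write/read cycle is bit-identical
  f2 <- tempfile(fileext = ".csv")
  write_pupil_trace(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("event tables validate intervals and compute ms durations", {
  ev <- ocular_events(c(1.0, 3.0), c(1.2, 3.1), "blink")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration_ms, c(200, 100), tolerance = 1e-9)
  expect_error(ocular_events(2.0, 1.5, "blink"), "offset <= onset at row 1")
  expect_error(ocular_events(c(1, 1.1), c(1.3, 1.4), "blink"), "overlapping")
  expect_error(ocular_events(1, 2, "wink"), "unknown event kind")
})

test_that("event reader handles files and empty inputs", {
  f <- write_tmp(c("onset,offset", "1.0,1.2", "3.0,3.1"))
  ev <- read_events(f, "blink")
  expect_equal(ev$duration_ms, c(200, 100))
  f2 <- write_tmp("onset,offset")
  expect_warning(ev2 <- read_events(f2, "blink"), "no events")
  expect_equal(nrow(ev2), 0)
  ev3 <- ocular_events(c(0.5, 2.5), c(0.6, 2.65), "fixation")
  f3 <- tempfile(fileext = ".tsv")
  write_events(ev3, f3)
  back <- read_events(f3, "fixation")
  expect_equal(back$onset, ev3$onset)
  expect_equal(back$offset, ev3$offset)
})

test_that("phase segmentation is half-open and assigns events by onset", {
  # event straddling the baseline/audio boundary belongs to baseline
  ev <- ocular_events(c(29.9, 31.0), c(30.4, 31.2), "blink")
  base <- phase_window("baseline", 0, 30)
  audio <- phase_window("audio", 30, 60)
  expect_equal(segment_phase(ev, base)$onset, 29.9)
  expect_equal(segment_phase(ev, audio)$onset, 31.0)
  # an onset exactly at the boundary belongs to the next phase
  ev2 <- ocular_events(30.0, 30.2, "blink")
  expect_equal(nrow(segment_phase(ev2, base)), 0)
  expect_equal(segment_phase(ev2, audio)$onset, 30.0)

  tr <- make_trace(n = 12000, fs = 200, f = function(t) rep(5, length(t)))
  seg <- segment_phase(tr, base)
  expect_equal(n_samples(seg), 6000)           # 30 s x 200 Hz
  # a sample exactly at the window end is excluded
  expect_false(any(abs(seg$time - 30) < 1e-12))
  expect_error(segment_phase(tr, phase_window("silence", 50, 80)), "outside")
})

test_that("the three phase views of a trial partition its samples exactly", {
  set.seed(4)
  tr <- random_masked_trace(n = 18000)
  wins <- lapply(list(c(0, 30), c(30, 60), c(60, 90)), function(se)
    phase_window("baseline", se[1], se[2]))
  parts <- lapply(wins, function(w) segment_phase(tr, w))
  expect_equal(sum(vapply(parts, n_samples, numeric(1))), n_samples(tr))
  all_t <- sort(unlist(lapply(parts, function(p) p$time)))
  expect_equal(all_t, tr$time)
})

test_that("schedules enforce the counterbalanced design", {
  sch <- default_schedule(c("negative", "neutral", "positive"))
  expect_equal(nrow(sch), 9)
  expect_equal(unique(sch$end - sch$start), 30)
  expect_equal(sch$phase, rep(c("baseline", "audio", "silence"), 3))
  # contiguity within and across trials
  expect_equal(sch$start[-1], sch$end[-9])
  expect_error(default_schedule(c("neutral", "neutral", "positive")),
               "exactly once")
})

test_that("dyad construction demands matching schedules and roles", {
  set.seed(2)
  res <- assemble_dyad(quiet_config(), seed = 2, with_pupil = FALSE)
  dy <- res$dyad
  expect_s3_class(dy, "dyad_recording")
  other <- dy$observer
  other$schedule$start[1] <- 1
  expect_error(dyad_recording("x", dy$listener, other), "identical schedule")
  expect_error(dyad_recording("x", dy$observer, dy$listener), "roles")
})

test_that("metrics table writing enforces keys and round-trips", {
  tab <- data.frame(dyad = "d1", participant = "p1", role = "listener",
                    trial = 1L, context = "neutral", phase = "baseline",
                    measure = "n_blinks", value = 7)
  f <- tempfile(fileext = ".csv")
  write_metrics_table(tab, f)
  expect_equal(length(readLines(f)), 2)     # header + row
  back <- read_metrics_table(f)
  expect_equal(back$value, 7)
  expect_equal(back$measure, "n_blinks")
  dup <- rbind(tab, tab)
  expect_error(write_metrics_table(dup, f), "duplicate")

  set.seed(3)
  res <- assemble_dyad(synthetic_config(), seed = 3)
  proc <- list(process_dyad(res$dyad))
  big <- build_metrics_table(list(res$dyad), proc)
  expect_equal(nrow(big), 2 * 9 * 7)        # 2 members x 9 phases x 7 measures
  f2 <- tempfile(fileext = ".csv")
  write_metrics_table(big, f2)
  back2 <- read_metrics_table(f2)
  expect_equal(back2$value, big$value, tolerance = 1e-7)
  expect_equal(back2$participant, big$participant)
})
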