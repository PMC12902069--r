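test_that("nearest-event lags follow the definition and tie rule", {
  expect_equal(nearest_event_lag(10.0, c(8.0, 11.0)), 1.0)
  expect_equal(nearest_event_lag(10.0, c(9.0, 11.0)), -1.0)   # tie -> earlier
  expect_equal(nearest_event_lag(c(1, 5), numeric(0)), c(NA_real_, NA_real_))
  expect_error(nearest_event_lag(numeric(0), 1), "empty")
  set.seed(9)
  for (i in 1:100) {
    ref <- sort(runif(sample(1:10, 1), 0, 60))
    test <- sort(runif(sample(0:12, 1), 0, 60))
    expect_equal(nearest_event_lag(ref, test), oracle_nearest_lag(ref, test))
  }
})

test_that("synchronization percentages match hand computations", {
  expect_equal(sync_percentage(5.0, 5.0, 1.5), 100)
  expect_equal(sync_percentage(c(5, 20), c(6, 30), 1.5), 50)
  expect_warning(res <- sync_percentage(numeric(0), c(1, 2), 1.5), "undefined")
  expect_true(is.na(res))
  expect_equal(sync_percentage(c(1, 2), numeric(0), 1.5), 0)
  # inclusive window edge
  expect_equal(sync_percentage(5.0, 6.5, 1.5), 100)
})

test_that("boundedness, perfect coupling and window monotonicity hold", {
  set.seed(12)
  for (i in 1:50) {
    ref <- sort(runif(sample(2:15, 1), 0, 90))
    test <- sort(runif(sample(1:15, 1), 0, 90))
    p1 <- sync_percentage(ref, test, 1.5)
    p2 <- sync_percentage(ref, test, 2.5)
    expect_gte(p1, 0); expect_lte(p1, 100)
    expect_gte(p2, p1)                          # wider window never loses hits
    # planting a partner within the window for every reference forces 100
    coupled <- sort(c(test, ref + runif(length(ref), -1.4, 1.4)))
    expect_equal(sync_percentage(ref, coupled, 1.5), 100)
  }
})

test_that("swapping reference and test roles changes the statistic", {
  ref <- c(10, 20, 30)
  test <- c(10.5, 100)
  expect_equal(sync_percentage(ref, test, 1.5), 100 / 3)
  expect_equal(sync_percentage(test, ref, 1.5), 50)
})

test_that("dyad synchronization tables cover every trial and phase", {
  set.seed(13)
  res <- assemble_dyad(synthetic_config(), seed = 13, with_pupil = FALSE)
  tab <- dyad_sync_table(list(res$dyad), sync_config("blink"))
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$phase), c("baseline", "audio", "silence"))
  ok <- !is.na(tab$sync_pct)
  expect_true(all(tab$sync_pct[ok] >= 0 & tab$sync_pct[ok] <= 100))
  lags <- attr(tab, "lags")
  expect_equal(length(lags), 9)
  expect_equal(lengths(lags), tab$n_ref)
})

test_that("a phase with no reference events yields a missing row", {
  cfg <- quiet_config(blink_rate_listener = 0, blink_rate_observer = 0.2,
                      coupling_prob = 0)
  res <- assemble_dyad(cfg, seed = 14, with_pupil = FALSE)
  tab <- dyad_sync_table(list(res$dyad), sync_config("blink"))
  expect_true(all(is.na(tab$sync_pct)))
  expect_true(all(tab$n_ref == 0))
})

test_that("cross-phase matching can recover partners just over the boundary", {
  sch <- default_schedule()
  mk <- function(onsets, role, id) {
    dt <- 1 / 200
    tr <- pupil_trace(c(0, 270 - dt), c(5, 5))
    participant_recording(id, role, tr, ocular_events(onsets, onsets + 0.1, "blink"), sch)
  }
  dy <- dyad_recording("d1", mk(29.9, "listener", "L"), mk(30.2, "observer", "O"))
  with_cross <- dyad_sync_table(list(dy), sync_config("blink", cross_phase = TRUE))
  no_cross <- dyad_sync_table(list(dy), sync_config("blink", cross_phase = FALSE))
  base <- function(t) t$sync_pct[t$phase == "baseline" & t$trial == 1]
  expect_equal(base(with_cross), 100)
  expect_equal(base(no_cross), 0)
})

test_that("pooled-denominator synchrony scores both members", {
  sch <- default_schedule()
  mk <- function(onsets, role, id) {
    dt <- 1 / 200
    tr <- pupil_trace(c(0, 270 - dt), c(5, 5))
    participant_recording(id, role, tr, ocular_events(onsets, onsets + 0.1, "blink"), sch)
  }
  # listener 2 blinks, observer 1; one pair within the window
  dy <- dyad_recording("d1", mk(c(5, 20), "listener", "L"), mk(6, "observer", "O"))
  ref_only <- dyad_sync_table(list(dy), sync_config("blink"))
  pooled <- dyad_sync_table(list(dy), sync_config("blink", denominator = "pooled"))
  base <- function(t) t$sync_pct[t$phase == "baseline" & t$trial == 1]
  expect_equal(base(ref_only), 50)        # 1 of 2 listener blinks matched
  expect_equal(base(pooled), 100 * 2 / 3) # both matched blinks over 3 total
})

test_that("rank correlation of the two synchrony measures matches cor.test", {
  mk_tab <- function(vals) {
    data.frame(dyad = rep(sprintf("d%02d", 1:8), each = 3),
               trial = rep(1:3, 8), context = "neutral",
               phase = "baseline", n_ref = 5, n_test = 5,
               sync_pct = vals)
  }
  set.seed(15)
  a <- rep(runif(8, 0, 100), each = 3)
  cc <- sync_cross_correlation(mk_tab(a), mk_tab(a))
  expect_equal(cc$rho, 1)
  u <- unique(a)
  rev_ranks <- sort(u)[length(u) + 1 - rank(u)]   # rank-reversed pairing
  cc2 <- sync_cross_correlation(mk_tab(a), mk_tab(rep(rev_ranks, each = 3)))
  expect_equal(cc2$rho, -1)
  b <- rep(runif(8, 0, 100), each = 3)
  cc3 <- sync_cross_correlation(mk_tab(a), mk_tab(b))
  expect_equal(cc3$rho,
               unname(cor(unique(a), unique(b), method = "spearman")),
               tolerance = 1e-12)
  # fewer than 3 dyads: missing
  small <- mk_tab(a)[1:6, ]
  cc4 <- sync_cross_correlation(small, small)
  expect_true(is.na(cc4$rho))
})

test_that("the analytic chance level matches its closed form", {
  expect_equal(chance_sync_level(0.25, 1.5), 100 * (1 - exp(-0.75)))
  expect_equal(round(chance_sync_level(0.25, 1.5), 2), 52.76)
})
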