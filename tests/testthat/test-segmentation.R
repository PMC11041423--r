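test_that("smoothing has unit DC gain and rejects cutoffs at or above Nyquist", {
  sig <- breath_signal(rep(3.3, 500), 100)
  expect_equal(smooth_signal(sig, 2)$value, sig$value, tolerance = 1e-9)
  expect_error(smooth_signal(sig, 50), "Nyquist",
               class = "rhbreath_config_error")
})

test_that("smoothing removes a 50 Hz tone riding on a breathing-band sinusoid", {
  rate <- 200
  t <- seq(0, 30, by = 1 / rate)
  v <- sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 50 * t)
  out <- smooth_signal(breath_signal(v, rate), 2)
  # residual 50 Hz amplitude via the Goertzel-style projection
  resid <- 2 * abs(mean(out$value * exp(-2i * pi * 50 * t)))
  expect_lt(resid, 0.005)   # < 1% of the original 0.5 amplitude
  # and the breathing component survives
  kept <- 2 * abs(mean(out$value * exp(-2i * pi * 0.3 * t)))
  expect_gt(kept, 0.95)
})

test_that("zero-phase smoothing leaves a clean pulse's peak in place", {
  rate <- 100
  t <- seq(0, 4, by = 1 / rate)
  v <- 50 * exp(-((t - 2) / 0.6)^2)
  out <- smooth_signal(breath_signal(v, rate), 2)
  expect_lte(abs(which.max(out$value) - which.max(v)), 1)
})

test_that("extrema detection matches the analytic count for a sinusoid", {
  rate <- 50
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  sig <- breath_signal(sin(2 * pi * 0.25 * t), rate)
  ext <- find_breath_extrema(sig, min_prominence = 0.5, min_separation_s = 1)
  expect_equal(length(ext$maxima), 15)        # maxima at t = 1, 5, ..., 57
  expect_true(length(ext$minima) %in% c(14, 15))
  expect_equal(sig$time_s[ext$maxima], seq(1, 57, by = 4), tolerance = 0.05)
})

test_that("monotone and flat signals contain no reportable extrema", {
  expect_length(find_breath_extrema(breath_signal(1:100, 10), 0.5)$maxima, 0)
  ext <- find_breath_extrema(breath_signal(rep(1, 100), 10), 0.5)
  expect_length(ext$minima, 0)
  expect_length(ext$maxima, 0)
})

test_that("plateau ties resolve to the first sample of the plateau", {
  v <- c(5, 3, 1, 1, 1, 3, 5, 7, 7, 5, 3)
  ext <- find_breath_extrema(breath_signal(v, 10), min_prominence = 1,
                             min_separation_s = 0)
  expect_equal(ext$minima, 3L)
  expect_equal(ext$maxima, 8L)
})

test_that("datasheet-level noise does not change the detected extrema count", {
  rec0 <- quick_noiseless()
  rec <- quick_recording()        # same seed, 0.02 %RH noise + drift
  e0 <- segment_for_test(rec0$rh)$extrema
  e1 <- segment_for_test(rec$rh)$extrema
  expect_equal(length(e1$minima), length(e0$minima))
  expect_equal(length(e1$maxima), length(e0$maxima))
})

test_that("cycles tile consecutive minima with the enclosed maximum as peak", {
  v <- c(0, 5, 0, 7, 0)
  sig <- breath_signal(rep(v, 2)[1:9], 1)
  ext <- find_breath_extrema(sig, min_prominence = 1, min_separation_s = 0)
  seg <- segment_breath_cycles(sig, ext$minima, ext$maxima)
  expect_equal(nrow(seg), length(ext$minima) - 1)
  expect_true(all(seg$start_idx < seg$peak_idx & seg$peak_idx < seg$end_idx))
  expect_equal(seg$end_idx[-nrow(seg)], seg$start_idx[-1])  # non-overlap, tiling
  empty <- segment_breath_cycles(sig, integer(), integer())
  expect_equal(nrow(empty), 0)
})

test_that("noiseless cycle boundaries land within two 100 Hz samples of the truth", {
  rec <- quick_noiseless()
  s <- segment_for_test(rec$rh)
  tc <- rec$truth$cycles
  expect_equal(nrow(s$seg), nrow(tc) - 1)     # first cycle has no left minimum
  m <- match_to_truth(s$seg, tc)
  expect_equal(nrow(m), nrow(s$seg))
  expect_lte(max(abs(s$seg$start_s[m$det] - tc$start_s[m$truth])), 0.02 + 1e-9)
})

test_that("deep-breath detection recovers the protocol's deep events", {
  rec <- quick_recording()
  s <- segment_for_test(rec$rh)
  truth_deep <- sum(rec$truth$cycles$label == "deep")
  expect_equal(sum(s$seg$label == "deep"), truth_deep)
  ev <- deep_events(s$seg)
  expect_equal(nrow(ev), truth_deep)
  # labelled cycles and events agree
  expect_equal(ev$cycle, which(s$seg$label == "deep"))
})

test_that("refined deep boundaries sit on second-derivative sign changes", {
  rec <- quick_noiseless()
  s <- segment_for_test(rec$rh)
  ev <- deep_events(s$seg)
  sc <- rhbreath:::second_derivative_sign_changes(s$signal$value)
  expect_true(all(ev$inhale_onset_idx %in% sc))
  expect_true(all(ev$exhale_end_idx %in% sc))
  # the refined limb boundaries stay inside their own cycle
  expect_true(all(ev$inhale_onset_idx >= ev$start_idx &
                    ev$inhale_onset_idx < ev$peak_idx))
  expect_true(all(ev$exhale_end_idx > ev$peak_idx &
                    ev$exhale_end_idx <= ev$end_idx))
})

test_that("uniform-amplitude breathing yields no deep events", {
  rate <- 100
  t <- seq(0, 120, by = 1 / rate)
  sig <- breath_signal(50 + 20 * (1 - cos(2 * pi * 0.3 * t)) / 2, rate)
  s <- segment_for_test(sig)
  expect_equal(sum(s$seg$label == "deep"), 0)
  expect_equal(nrow(deep_events(s$seg)), 0)
})

test_that("respiratory rate is count x 60 / window", {
  sig <- breath_signal(rep(0, 6000), 100)   # content irrelevant: counts only
  minima <- round(seq(1, 5901, length.out = 18))
  rr <- respiratory_rate(sig, minima, window_s = 60)
  expect_equal(nrow(rr), 1)
  expect_equal(rr$rr_bpm, 18)

  rate <- 50
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  sine <- breath_signal(sin(2 * pi * 0.25 * t), rate)
  ext <- find_breath_extrema(sine, 0.5, 1)
  rr2 <- respiratory_rate(sine, ext$minima, 60)
  expect_equal(rr2$rr_bpm, c(15, 15))

  flat <- respiratory_rate(breath_signal(rep(1, 12000), 100), integer(), 60)
  expect_true(all(flat$rr_bpm == 0))
})

test_that("a window longer than the recording collapses to one flagged window", {
  sig <- breath_signal(rep(0, 3000), 100)    # 30 s
  rr <- respiratory_rate(sig, c(500, 1500, 2500), window_s = 60)
  expect_equal(nrow(rr), 1)
  expect_true(isTRUE(attr(rr, "partial_window")))
  expect_equal(rr$rr_bpm, 3 * 60 / 30)
  expect_error(respiratory_rate(sig, 1L, window_s = 0),
               class = "rhbreath_config_error")
})

test_that("rates counted from minima and maxima agree within 1 breath/min", {
  rec <- quick_recording()
  s <- segment_for_test(rec$rh)
  rr_min <- respiratory_rate(s$signal, s$extrema$minima, 60)
  rr_max <- respiratory_rate(s$signal, s$extrema$maxima, 60)
  expect_lte(max(abs(rr_min$rr_bpm - rr_max$rr_bpm)), 1)
})

test_that("per-minute RR recovers the configured rate on metronomic breathing", {
  rec <- cached_recording("quick_rr0", function() {
    simulate_subject(quick_config(duration_s = 180, rr_sd_bpm = 0,
                                  deep_duration_factor = 1))
  })
  s <- segment_for_test(rec$rh)
  rr <- respiratory_rate(s$signal, s$extrema$minima, 60)
  expect_lt(abs(mean(rr$rr_bpm) - rec$config$rr_mean_bpm), 0.5)
})

test_that("segmentations export to CSV", {
  rec <- quick_recording()
  s <- segment_for_test(rec$rh)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segmentation_csv(s$seg, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("start_s", "peak_s", "end_s", "amplitude", "label"))
  expect_equal(nrow(back), nrow(s$seg))
})
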