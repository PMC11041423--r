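# Shared fixtures, generated once per test run and memoised.

.rec_cache <- new.env(parent = emptyenv())

cached_recording <- function(name, make) {
  if (is.null(.rec_cache[[name]])) .rec_cache[[name]] <- make()
  .rec_cache[[name]]
}

# Short recording at reduced rates: fast, still >= 3 deep events.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(duration_s = 120, rh_sample_rate_hz = 500,
         flow_sample_rate_hz = 250, seed = 11L),
    list(...))
  do.call(breath_config, args)
}

quick_recording <- function() {
  cached_recording("quick", function() simulate_subject(quick_config()))
}

quick_noiseless <- function() {
  cached_recording("quick0", function() {
    simulate_subject(quick_config(noise_sd_rh_pct = 0,
                                  drift_rh_pct_per_min = 0,
                                  flow_noise_sd_l_per_s = 0))
  })
}

# Segment a channel the way the pipeline does (grid -> smooth -> extrema ->
# cycles -> deep refinement) and return all the intermediates.
segment_for_test <- function(signal, grid_hz = 100, cutoff_hz = 2) {
  grid <- resample_signal(signal, grid_hz)
  sm <- smooth_signal(grid, cutoff_hz)
  rng <- stats::quantile(sm$value, c(0.01, 0.99), names = FALSE)
  ext <- find_breath_extrema(sm, min_prominence = 0.2 * (rng[2] - rng[1]),
                             min_separation_s = 1)
  seg <- segment_breath_cycles(sm, ext$minima, ext$maxima)
  seg <- detect_deep_breaths(sm, seg)
  list(signal = sm, extrema = ext, seg = seg)
}

# Match detected cycles to ground-truth cycles on start time.
match_to_truth <- function(seg, truth_cycles, tol = 0.75) {
  m <- vapply(seg$start_s, function(t) {
    k <- which.min(abs(truth_cycles$start_s - t))
    if (abs(truth_cycles$start_s[k] - t) <= tol) k else NA_integer_
  }, integer(1))
  tibble::tibble(det = seq_len(nrow(seg)), truth = m)[!is.na(m), ]
}
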