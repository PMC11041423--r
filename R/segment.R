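#' Zero-phase low-pass smoothing
#'
#' Smooths a signal with a zero-phase (forward-backward) Butterworth
#' low-pass filter with unit DC gain, preserving length, rate, and the
#' position of breath-pulse peaks. Breathing content lives below ~1 Hz, so
#' the default 2 Hz cutoff removes sensor noise while keeping deep-breath
#' morphology intact for second-derivative boundary refinement.
#'
#' @param signal A [breath_signal()].
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist rate.
#' @param order Butterworth order (applied twice by the zero-phase pass).
#' @return The smoothed [breath_signal()].
#' @export
smooth_signal <- function(signal, cutoff_hz = 2, order = 4L) {
  assert_signal(signal)
  rate <- signal_rate(signal)
  if (cutoff_hz >= rate / 2) {
    rlang::abort(sprintf("cutoff_hz (%g) must be below the Nyquist rate (%g Hz)",
                         cutoff_hz, rate / 2),
                 class = "rhbreath_config_error")
  }
  v <- lowpass_zero_phase(signal$value, rate, cutoff_hz, order = order)
  breath_signal(v, rate, units = signal_units(signal),
                start_time_s = signal_start(signal))
}

# Interior local extrema with plateau ties resolved to the first sample of
# the plateau. Returns strictly interior indices.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(minima = integer(), maxima = integer()))
  s <- sign(diff(v))
  s_na <- s; s_na[s_na == 0] <- NA
  right <- zoo::na.locf(s_na, fromLast = TRUE, na.rm = FALSE)
  i <- seq(2L, n - 1L)
  minima <- i[s[i - 1L] == -1 & !is.na(right[i]) & right[i] == 1]
  maxima <- i[s[i - 1L] ==  1 & !is.na(right[i]) & right[i] == -1]
  list(minima = minima, maxima = maxima)
}

# Topographic prominence of peaks (indices into v, assumed local maxima):
# height above the higher of the two valley floors separating the peak
# from the nearest higher terrain (or the signal edge). The search is
# limited to `horizon` samples per side: breathing valleys return to
# baseline within a breath, so a horizon of many periods leaves the
# result unchanged while keeping the cost linear on plateau-heavy signals.
peak_prominence <- function(v, peaks, horizon = Inf) {
  n <- length(v)
  vapply(peaks, function(p) {
    h <- v[[p]]
    lmin <- h
    i <- p - 1L; lim <- max(1L, p - horizon)
    while (i >= lim && v[[i]] <= h) { if (v[[i]] < lmin) lmin <- v[[i]]; i <- i - 1L }
    rmin <- h
    i <- p + 1L; lim <- min(n, p + horizon)
    while (i <= lim && v[[i]] <= h) { if (v[[i]] < rmin) rmin <- v[[i]]; i <- i + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
}

# Keep peaks with prominence >= min_prom, then greedily enforce a minimum
# index separation, preferring the more prominent peak.
filter_peaks <- function(v, peaks, min_prom, min_sep, horizon = Inf) {
  if (length(peaks) == 0L) return(integer())
  prom <- peak_prominence(v, peaks, horizon = horizon)
  keep <- peaks[prom >= min_prom]
  prom <- prom[prom >= min_prom]
  if (length(keep) <= 1L || min_sep <= 1) return(sort(keep))
  ord <- order(-prom, keep)
  accepted <- integer()
  for (p in keep[ord]) {
    if (all(abs(accepted - p) >= min_sep)) accepted <- c(accepted, p)
  }
  sort(accepted)
}

#' Locate breath extrema
#'
#' Finds the inhalation troughs (minima) and exhalation peaks (maxima) of a
#' smoothed breathing signal. Extrema must clear a topographic prominence
#' threshold and a minimum mutual separation, and the returned minima and
#' maxima alternate (runs of same-type extrema are collapsed to the most
#' extreme member). Plateau ties resolve to the first sample of the
#' plateau.
#'
#' @param signal A [breath_signal()] (smooth it first; see
#'   [smooth_signal()]).
#' @param min_prominence Minimum prominence, signal units. The default
#'   1 %RH rejects datasheet-level sensor noise while passing any real
#'   breath excursion.
#' @param min_separation_s Minimum time between same-type extrema, seconds
#'   (1 s caps the detectable rate at 60 breaths/min).
#' @return A list with integer vectors `minima` and `maxima` (1-based
#'   sample indices).
#' @export
find_breath_extrema <- function(signal, min_prominence = 1,
                                min_separation_s = 1.0) {
  assert_signal(signal)
  v <- signal$value
  if (length(v) < 3L) return(list(minima = integer(), maxima = integer()))
  ext <- local_extrema(v)
  rate <- signal_rate(signal)
  sep <- max(1, round(min_separation_s * rate))
  horizon <- max(sep * 30L, round(30 * rate))
  maxima <- filter_peaks(v, ext$maxima, min_prominence, sep, horizon)
  minima <- filter_peaks(-v, ext$minima, min_prominence, sep, horizon)
  alternate_extrema(v, minima, maxima)
}

# Collapse consecutive same-type extrema so minima and maxima alternate.
alternate_extrema <- function(v, minima, maxima) {
  if (length(minima) == 0L || length(maxima) == 0L) {
    return(list(minima = minima, maxima = maxima))
  }
  idx <- c(minima, maxima)
  type <- rep(c("min", "max"), c(length(minima), length(maxima)))
  ord <- order(idx)
  idx <- idx[ord]; type <- type[ord]
  run <- cumsum(c(TRUE, type[-1] != type[-length(type)]))
  kept <- vapply(split(seq_along(idx), run), function(grp) {
    if (length(grp) == 1L) return(idx[[grp]])
    if (type[[grp[[1]]]] == "max") grp_idx <- idx[grp][which.max(v[idx[grp]])]
    else grp_idx <- idx[grp][which.min(v[idx[grp]])]
    grp_idx
  }, integer(1))
  kept_type <- type[!duplicated(run)]
  list(minima = unname(kept[kept_type == "min"]),
       maxima = unname(kept[kept_type == "max"]))
}

#' Segment a signal into breath cycles
#'
#' Each pair of consecutive minima delimits one breath cycle (half-open
#' `[start_idx, end_idx)`), with the enclosed maximum as the cycle peak and
#' amplitude measured as peak value minus the lower of the two trough
#' values. Labels are initialized to `"normal"`; see
#' [detect_deep_breaths()].
#'
#' @param signal The segmented [breath_signal()].
#' @param minima,maxima Extrema indices from [find_breath_extrema()].
#' @return A tibble of class `breath_segmentation` with one row per cycle
#'   (`cycle`, `start_idx`, `peak_idx`, `end_idx`, `start_s`, `peak_s`,
#'   `end_s`, `amplitude`, `label`). Fewer than two minima yield an empty
#'   segmentation.
#' @export
segment_breath_cycles <- function(signal, minima, maxima) {
  assert_signal(signal)
  rate <- signal_rate(signal)
  t0 <- signal_start(signal)
  empty <- tibble::tibble(
    cycle = integer(), start_idx = integer(), peak_idx = integer(),
    end_idx = integer(), start_s = numeric(), peak_s = numeric(),
    end_s = numeric(), amplitude = numeric(), label = character()
  )
  if (length(minima) < 2L) {
    return(new_segmentation(empty, rate, t0))
  }
  v <- signal$value
  n_cyc <- length(minima) - 1L
  s <- minima[-(n_cyc + 1L)]
  e <- minima[-1L]
  p <- vapply(seq_len(n_cyc), function(k) {
    inside <- maxima[maxima > s[[k]] & maxima < e[[k]]]
    if (length(inside) > 0L) inside[[which.max(v[inside])]]
    else s[[k]] + which.max(v[seq.int(s[[k]] + 1L, e[[k]] - 1L)])
  }, numeric(1))
  df <- tibble::tibble(
    cycle = seq_len(n_cyc),
    start_idx = as.integer(s), peak_idx = as.integer(p), end_idx = as.integer(e),
    start_s = t0 + (s - 1) / rate, peak_s = t0 + (p - 1) / rate,
    end_s = t0 + (e - 1) / rate,
    amplitude = v[p] - pmin(v[s], v[e]),
    label = "normal"
  )
  new_segmentation(df, rate, t0)
}

new_segmentation <- function(df, rate, t0, deep_events = NULL) {
  attr(df, "sample_rate_hz") <- rate
  attr(df, "start_time_s") <- t0
  attr(df, "deep_events") <- deep_events %||% tibble::tibble(
    event = integer(), cycle = integer(), start_idx = integer(),
    peak_idx = integer(), end_idx = integer(),
    inhale_onset_idx = integer(), exhale_end_idx = integer()
  )
  class(df) <- unique(c("breath_segmentation", class(df)))
  df
}

#' @rdname segment_breath_cycles
#' @param seg A `breath_segmentation`.
#' @return `deep_events()` returns the tibble of refined deep events (one
#'   row per deep inhale-exhale event: `event`, `cycle`, refined
#'   `start_idx`/`end_idx`, `peak_idx`).
#' @export
deep_events <- function(seg) attr(seg, "deep_events")

# Samples where the central second difference of v changes sign; the first
# index of each transition is reported (ties resolve to the earlier index).
second_derivative_sign_changes <- function(v) {
  d2 <- diff(v, differences = 2L)      # d2[j] ~ curvature at sample j + 1
  s <- sign(d2)
  s_na <- s; s_na[s_na == 0] <- NA
  filled <- zoo::na.locf(s_na, fromLast = TRUE, na.rm = FALSE)
  j <- which(s[-length(s)] != 0 & !is.na(filled[-1]) &
               filled[-1] != s[-length(s)])
  j + 1L                               # first sample of the transition
}

#' Classify deep breaths and refine their limb boundaries
#'
#' A deep inhale-exhale cycle is both longer and larger than tidal
#' breathing, but saturation of the exhaled humidity near 100 %RH
#' compresses amplitude differences (a saturated tidal breath and a deep
#' breath can share the same peak), so duration is the reliable
#' discriminator: tidal cycle durations jitter by a few percent around
#' the subject's breathing period while a full deep inhale-exhale takes
#' on the order of 1.5 tidal periods. A cycle is flagged deep when its
#' duration exceeds `duration_k` times the median cycle duration and its
#' area above the lower trough exceeds `area_k` times the median cycle
#' area (the area floor only guards against long, near-flat pauses being
#' read as deep breaths; a saturated-envelope deep breath can have
#' *less* amplitude than a large tidal breath, so the floor sits below 1). Medians are taken over the whole recording by default —
#' deep breaths are a small minority, so the median tracks tidal
#' breathing — or over a rolling window of `median_window` cycles when
#' the breathing rate drifts within a recording.
#'
#' For each flagged cycle, the onset of the deep inspiration and the end
#' of the deep expiration are refined to the nearest sign change of the
#' smoothed signal's second derivative inside the rising and falling limb
#' respectively; the limbs delimit the reserve-volume estimates while the
#' full trough-to-trough span carries the deep-breathing area.
#'
#' @param signal The smoothed [breath_signal()] the segmentation came from.
#' @param seg A `breath_segmentation`.
#' @param duration_k Duration multiplier over the median cycle duration
#'   (default 1.21: midway between truncated tidal jitter and the 1.5x
#'   deep-breath duration).
#' @param area_k Area floor as a multiple of the median cycle area
#'   (default 0.8).
#' @param median_window Optional odd rolling-median window in cycles;
#'   `NULL` (default) uses recording-wide medians.
#' @return `seg` with deep cycles relabelled `"deep"` and a
#'   [deep_events()] table attached (columns `event`, `cycle`,
#'   `start_idx`/`end_idx` for the full span, `peak_idx`, and the refined
#'   `inhale_onset_idx`/`exhale_end_idx`).
#' @export
detect_deep_breaths <- function(signal, seg, duration_k = 1.21, area_k = 0.8,
                                median_window = NULL) {
  assert_signal(signal)
  stopifnot(inherits(seg, "breath_segmentation"))
  if (nrow(seg) == 0L) return(seg)
  v <- signal$value
  dt <- 1 / signal_rate(signal)
  area <- purrr::map_dbl(seq_len(nrow(seg)), function(k) {
    i <- seq.int(seg$start_idx[[k]], seg$end_idx[[k]] - 1L)
    trough <- min(v[[seg$start_idx[[k]]]], v[[seg$end_idx[[k]]]])
    sum(v[i] - trough) * dt
  })
  dur <- seg$end_s - seg$start_s
  ref <- function(x) {
    if (is.null(median_window)) return(rep(stats::median(x), length(x)))
    k_med <- min(median_window, length(x))
    if (k_med %% 2L == 0L) k_med <- k_med - 1L
    if (k_med >= 3L) stats::runmed(x, k_med, endrule = "constant")
    else rep(stats::median(x), length(x))
  }
  cand <- which(dur > duration_k * ref(dur) & area > area_k * ref(area) &
                  area > 0)
  if (length(cand) == 0L) return(seg)

  sc <- second_derivative_sign_changes(v)
  # refine each limb boundary to the nearest sign change within the limb,
  # so the reserve-volume estimate never swallows an adjacent breath
  nearest_in <- function(i, lo, hi) {
    cands <- sc[sc >= lo & sc <= hi]
    if (length(cands) == 0L) i else cands[[which.min(abs(cands - i))]]
  }
  ev <- purrr::map(seq_along(cand), function(j) {
    k <- cand[[j]]
    p <- seg$peak_idx[[k]]
    tibble::tibble(
      event = j, cycle = k,
      start_idx = seg$start_idx[[k]], peak_idx = as.integer(p),
      end_idx = seg$end_idx[[k]],
      inhale_onset_idx = as.integer(
        nearest_in(seg$start_idx[[k]], seg$start_idx[[k]], p - 1L)),
      exhale_end_idx = as.integer(
        nearest_in(seg$end_idx[[k]], p + 1L, seg$end_idx[[k]]))
    )
  })
  seg$label[cand] <- "deep"
  new_segmentation(seg, signal_rate(signal), signal_start(signal),
                   deep_events = dplyr::bind_rows(ev))
}

#' Respiratory rate from counted extrema
#'
#' Counts breath minima (or maxima) in consecutive non-overlapping windows:
#' RR = count x 60 / window_s, in breaths per minute. The final partial
#' window is dropped; if the recording is shorter than one window, a single
#' full-duration window is used and flagged via the `"partial_window"`
#' attribute.
#'
#' @param signal The segmented [breath_signal()].
#' @param minima Extrema indices to count (conventionally the minima that
#'   delimit cycles; pass `maxima` to count peaks instead).
#' @param window_s Window length, seconds (default 60: per-minute rate).
#' @return A tibble with columns `window_start_s` and `rr_bpm`.
#' @export
respiratory_rate <- function(signal, minima, window_s = 60) {
  assert_signal(signal)
  if (!is.numeric(window_s) || window_s <= 0) {
    rlang::abort("window_s must be > 0", class = "rhbreath_config_error")
  }
  duration <- nrow(signal) / signal_rate(signal)
  t0 <- signal_start(signal)
  times <- t0 + (minima - 1) / signal_rate(signal)
  partial <- FALSE
  if (window_s > duration) {
    window_s <- duration
    partial <- TRUE
  }
  n_win <- max(1L, floor(duration / window_s + 1e-9))
  starts <- t0 + (seq_len(n_win) - 1) * window_s
  counts <- vapply(starts, function(ws) {
    sum(times >= ws & times < ws + window_s)
  }, numeric(1))
  out <- tibble::tibble(window_start_s = starts,
                        rr_bpm = counts * 60 / window_s)
  if (partial) attr(out, "partial_window") <- TRUE
  out
}

#' Export a segmentation as CSV
#'
#' Writes one row per cycle: `start_s,peak_s,end_s,amplitude,label`.
#'
#' @param seg A `breath_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_csv <- function(seg, path) {
  stopifnot(inherits(seg, "breath_segmentation"))
  out <- tibble::as_tibble(seg)[, c("start_s", "peak_s", "end_s",
                                    "amplitude", "label")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
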