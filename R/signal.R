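#' Construct a uniformly sampled physiological signal
#'
#' A `breath_signal` is a tibble with columns `time_s` and `value` plus
#' metadata attributes (`sample_rate_hz`, `units`, `start_time_s`). Sample
#' `i` (1-based) sits at `start_time_s + (i - 1) / sample_rate_hz`.
#'
#' @param values Numeric vector of measurements, in `units`.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param units One of `"%RH"` (relative humidity), `"L/s"` (flow),
#'   `"L"` (volume).
#' @param start_time_s Time of the first sample, seconds.
#'
#' @return A tibble of class `breath_signal` with columns `time_s`, `value`.
#' @export
#' @examples
#' sig <- breath_signal(sin(seq(0, 2 * pi, length.out = 100)), 50)
#' signal_rate(sig)
breath_signal <- function(values, sample_rate_hz, units = "%RH",
                          start_time_s = 0) {
  stopifnot(is.numeric(values), length(sample_rate_hz) == 1L,
            is.finite(sample_rate_hz))
  if (sample_rate_hz <= 0) {
    rlang::abort("`sample_rate_hz` must be > 0.", class = "rhbreath_config_error")
  }
  units <- match.arg(units, c("%RH", "L/s", "L"))
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(values) - 1) / sample_rate_hz,
    value  = as.numeric(values)
  )
  attr(out, "sample_rate_hz") <- as.numeric(sample_rate_hz)
  attr(out, "units") <- units
  attr(out, "start_time_s") <- as.numeric(start_time_s)
  class(out) <- c("breath_signal", class(out))
  out
}

#' @rdname breath_signal
#' @param x A `breath_signal`.
#' @export
signal_rate <- function(x) attr(x, "sample_rate_hz")

#' @rdname breath_signal
#' @export
signal_units <- function(x) attr(x, "units")

#' @rdname breath_signal
#' @export
signal_start <- function(x) attr(x, "start_time_s") %||% x$time_s[[1]]

assert_signal <- function(x, nonempty = TRUE) {
  if (!inherits(x, "breath_signal")) {
    rlang::abort("expected a `breath_signal` (see `breath_signal()`).")
  }
  if (nonempty && nrow(x) == 0L) {
    rlang::abort("signal has no samples.")
  }
  invisible(x)
}

#' @export
print.breath_signal <- function(x, ...) {
  cat(sprintf("<breath_signal> %d samples @ %g Hz [%s], %.3f s\n",
              nrow(x), signal_rate(x), signal_units(x),
              nrow(x) / signal_rate(x)))
  NextMethod()
}

#' Decode IEEE-754 hexadecimal telemetry frames
#'
#' The wearable transmits each sensor reading over Bluetooth as one 32-bit
#' IEEE-754 single-precision float rendered as 8 hexadecimal characters.
#' This decodes a batch of such frames.
#'
#' @param frames Character vector; each element exactly 8 hex characters.
#' @param byte_order `"big"` (network order, default) or `"little"`.
#'
#' @return Numeric vector, one value per frame. Non-finite payloads (NaN,
#'   Inf) are decoded faithfully and their indices recorded in the
#'   `"nonfinite"` attribute.
#' @seealso [encode_ieee754_hex()]
#' @export
#' @examples
#' decode_ieee754_hex("3F800000") # 1.0
decode_ieee754_hex <- function(frames, byte_order = c("big", "little")) {
  byte_order <- match.arg(byte_order)
  frames <- as.character(frames)
  bad <- which(nchar(frames) != 8L | grepl("[^0-9a-fA-F]", frames))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("malformed telemetry frame at index %d: '%s' (need 8 hex characters)",
              bad[[1]], frames[[bad[[1]]]]),
      class = "rhbreath_decode_error"
    )
  }
  bytes <- vapply(
    frames,
    function(f) as.raw(strtoi(substring(f, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L)),
    raw(4), USE.NAMES = FALSE
  )
  vals <- readBin(as.raw(bytes), what = "double", n = length(frames),
                  size = 4L, endian = byte_order)
  nf <- which(!is.finite(vals))
  if (length(nf) > 0L) attr(vals, "nonfinite") <- nf
  vals
}

#' Encode numeric values as IEEE-754 hexadecimal frames
#'
#' Inverse of [decode_ieee754_hex()]: rounds each value to single precision
#' and renders its 4 bytes as 8 uppercase hex characters.
#'
#' @param values Numeric vector.
#' @inheritParams decode_ieee754_hex
#' @return Character vector of 8-character frames.
#' @export
encode_ieee754_hex <- function(values, byte_order = c("big", "little")) {
  byte_order <- match.arg(byte_order)
  vapply(as.numeric(values), function(v) {
    b <- writeBin(v, raw(), size = 4L, endian = byte_order)
    paste(toupper(format(b)), collapse = "")
  }, character(1))
}

#' Read a timestamped CSV time series
#'
#' Expects a `time_s,value` header, optionally preceded by `# units: <u>`
#' comment lines written by [write_timeseries_csv()]. Timestamps must be
#' strictly increasing and uniformly spaced (relative jitter below 0.5% of
#' the median spacing); the sample rate is inferred from the median spacing.
#'
#' @param path CSV file path.
#' @param units Unit tag to attach when the file carries no sidecar
#'   metadata line.
#' @return A [breath_signal()].
#' @export
read_timeseries_csv <- function(path, units = "%RH") {
  head_lines <- readLines(path, n = 5L)
  meta <- grep("^#", head_lines, value = TRUE)
  m <- regmatches(meta, regexec("^#\\s*units:\\s*(\\S+)", meta))
  m <- purrr::compact(purrr::map(m, ~ if (length(.x) == 2) .x[[2]] else NULL))
  if (length(m) > 0) units <- m[[1]]
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    rlang::abort(sprintf("'%s' lacks the required time_s,value columns", path),
                 class = "rhbreath_parse_error")
  }
  if (nrow(df) == 0L) {
    rlang::abort(sprintf("'%s' contains no samples", path),
                 class = "rhbreath_parse_error")
  }
  if (nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) {
      row <- which(dt <= 0)[[1]] + 1L
      rlang::abort(sprintf("non-increasing timestamp at data row %d of '%s'",
                           row, path), class = "rhbreath_parse_error")
    }
    med <- stats::median(dt)
    off <- abs(dt - med) / med
    if (any(off > 0.005)) {
      row <- which(off > 0.005)[[1]] + 1L
      rlang::abort(sprintf(
        "non-uniform sample spacing at data row %d of '%s' (%.3g s vs median %.3g s)",
        row, path, dt[[row - 1L]], med), class = "rhbreath_parse_error")
    }
    rate <- 1 / med
  } else {
    rate <- 1
  }
  breath_signal(df$value, rate, units = units, start_time_s = df$time_s[[1]])
}

#' Write a signal as a timestamped CSV
#'
#' Writes a `# units:` sidecar comment, a `time_s,value` header, and one
#' row per sample with times regenerated from the index formula, so that a
#' read/write round trip reproduces the signal.
#'
#' @param signal A [breath_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(signal, path) {
  if (!inherits(signal, "breath_signal")) assert_signal(signal)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", signal_units(signal)), con)
  writeLines("time_s,value", con)
  if (nrow(signal) > 0L) {
    t <- signal_start(signal) +
      (seq_len(nrow(signal)) - 1) / signal_rate(signal)
    writeLines(sprintf("%.12g,%.12g", t, signal$value), con)
  }
  invisible(path)
}

# Zero-phase Butterworth low-pass with odd-reflection edge padding.
# Padding suppresses the start-up transients of filtfilt, which otherwise
# corrupt roughly 1/cutoff seconds at each end.
lowpass_zero_phase <- function(values, rate, cutoff_hz, order = 4L) {
  n <- length(values)
  if (n < 4L) return(values)
  w <- cutoff_hz / (rate / 2)
  bf <- signal::butter(order, w)
  m <- mean(values)              # filter the AC part only: exact DC gain 1
  v <- values - m
  npad <- min(n - 1L, ceiling(6 * rate / cutoff_hz))
  left <- 2 * v[[1]] - v[seq(npad + 1L, 2L)]
  right <- 2 * v[[n]] - v[seq(n - 1L, n - npad)]
  padded <- c(left, v, right)
  out <- signal::filtfilt(bf, padded)
  out[seq(npad + 1L, npad + n)] + m
}

#' Resample a signal onto a new rate
#'
#' Downsampling anti-aliases before decimation: for an integer decimation
#' factor >= 4 each output sample is the centred moving average of one
#' input block (a zero-phase boxcar whose first spectral null sits at the
#' output rate — appropriate for the heavily oversampled, sub-1-Hz
#' breathing band); otherwise a zero-phase Butterworth low-pass at 0.45 of
#' the target rate is applied before linear interpolation. Upsampling
#' interpolates linearly. The output covers the same time span.
#'
#' @param signal A [breath_signal()].
#' @param target_rate_hz Target sampling rate, Hz (> 0).
#' @return A [breath_signal()] at `target_rate_hz`.
#' @export
resample_signal <- function(signal, target_rate_hz) {
  assert_signal(signal)
  if (!is.numeric(target_rate_hz) || target_rate_hz <= 0) {
    rlang::abort("`target_rate_hz` must be > 0.", class = "rhbreath_config_error")
  }
  r0 <- signal_rate(signal)
  if (isTRUE(all.equal(r0, target_rate_hz))) return(signal)
  v <- signal$value
  n <- length(v)
  span <- (n - 1) / r0
  n_out <- floor(span * target_rate_hz + 1e-9) + 1L
  factor <- r0 / target_rate_hz
  if (factor >= 4 && abs(factor - round(factor)) < 1e-9 && n > 2 * factor) {
    # centred block average at each output instant: zero-phase, DC gain 1
    m <- as.integer(round(factor))
    half <- m %/% 2L
    centre <- (seq_len(n_out) - 1L) * m + 1L
    h_eff <- pmin(half, centre - 1L, n - centre)  # symmetric near the edges
    lo <- centre - h_eff
    hi <- centre + h_eff
    cs <- c(0, cumsum(v))
    v_new <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    if (target_rate_hz < r0 && n > 8L) {
      v <- lowpass_zero_phase(v, r0, 0.45 * target_rate_hz)
    }
    t_old <- (seq_along(v) - 1) / r0
    t_new <- (seq_len(n_out) - 1) / target_rate_hz
    v_new <- stats::approx(t_old, v, xout = pmin(t_new, span))$y
  }
  breath_signal(v_new, target_rate_hz, units = signal_units(signal),
                start_time_s = signal_start(signal))
}
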