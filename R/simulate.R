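#' Configuration for one simulated breathing recording
#'
#' Describes the study protocol the simulator emulates: quiet breathing at
#' `rr_mean_bpm` for `duration_s` seconds with one deep inhale-exhale cycle
#' every `deep_breath_period_s` seconds, recorded simultaneously by a
#' mask-mounted relative-humidity sensor and a reference pneumotach flow
#' channel. Exhalation drives the humidity from the ambient
#' `baseline_rh_pct` toward a per-cycle exhalation peak drawn from the
#' envelope distribution, saturating at `exhale_saturation_rh_pct`; deep
#' cycles scale the excursion by `deep_amplitude_factor` and the cycle
#' duration by `deep_duration_factor`.
#'
#' @param duration_s Recording length, seconds.
#' @param rr_mean_bpm Mean respiratory rate, breaths per minute.
#' @param rr_sd_bpm Within-recording cycle-to-cycle rate variability,
#'   breaths per minute (0 for perfectly periodic breathing).
#' @param deep_breath_period_s Interval between deep breaths, seconds. The
#'   first deep breath is scheduled half a period into the recording.
#' @param baseline_rh_pct Ambient (inhalation trough) relative humidity.
#' @param envelope_mean_rh_pct,envelope_sd_rh_pct Mean and SD of the
#'   per-cycle exhalation peak RH.
#' @param exhale_saturation_rh_pct Physical saturation cap applied to the
#'   waveform, %RH.
#' @param deep_amplitude_factor Deep-breath excursion multiplier (> 1).
#' @param deep_duration_factor Deep-breath duration multiplier (>= 1); a
#'   full deep inhale-exhale takes longer than a tidal breath.
#' @param noise_sd_rh_pct Additive Gaussian sensor noise SD, %RH.
#' @param drift_rh_pct_per_min Linear sensor/ambient drift, %RH per minute.
#' @param rh_sample_rate_hz,flow_sample_rate_hz Channel sampling rates, Hz.
#' @param volume_gain_l_per_rhs Ground-truth link between the noiseless RH
#'   pulse area (%RH*s) and breath volume (liters): true volume = gain *
#'   area above baseline.
#' @param flow_noise_sd_l_per_s Additive noise SD on the reference flow
#'   channel, L/s.
#' @param seed Integer RNG seed; identical configs produce identical
#'   recordings.
#'
#' @return A validated list of class `breath_config`.
#' @export
breath_config <- function(duration_s = 900,
                          rr_mean_bpm = 17.6,
                          rr_sd_bpm = 1.0,
                          deep_breath_period_s = 30,
                          baseline_rh_pct = 40,
                          envelope_mean_rh_pct = 89,
                          envelope_sd_rh_pct = 7.8,
                          exhale_saturation_rh_pct = 100,
                          deep_amplitude_factor = 2,
                          deep_duration_factor = 1.5,
                          noise_sd_rh_pct = 0.02,
                          drift_rh_pct_per_min = 0.05,
                          rh_sample_rate_hz = 5000,
                          flow_sample_rate_hz = 1000,
                          volume_gain_l_per_rhs = 0.006,
                          flow_noise_sd_l_per_s = 0.005,
                          seed = 1L) {
  cfg <- list(
    duration_s = duration_s, rr_mean_bpm = rr_mean_bpm, rr_sd_bpm = rr_sd_bpm,
    deep_breath_period_s = deep_breath_period_s,
    baseline_rh_pct = baseline_rh_pct,
    envelope_mean_rh_pct = envelope_mean_rh_pct,
    envelope_sd_rh_pct = envelope_sd_rh_pct,
    exhale_saturation_rh_pct = exhale_saturation_rh_pct,
    deep_amplitude_factor = deep_amplitude_factor,
    deep_duration_factor = deep_duration_factor,
    noise_sd_rh_pct = noise_sd_rh_pct,
    drift_rh_pct_per_min = drift_rh_pct_per_min,
    rh_sample_rate_hz = rh_sample_rate_hz,
    flow_sample_rate_hz = flow_sample_rate_hz,
    volume_gain_l_per_rhs = volume_gain_l_per_rhs,
    flow_noise_sd_l_per_s = flow_noise_sd_l_per_s,
    seed = as.integer(seed)
  )
  validate_breath_config(cfg)
  structure(cfg, class = "breath_config")
}

validate_breath_config <- function(cfg) {
  fail <- function(msg) rlang::abort(msg, class = "rhbreath_config_error")
  with(cfg, {
    if (!(duration_s > 0)) fail("duration_s must be > 0")
    if (!(rr_mean_bpm > 0)) fail("rr_mean_bpm must be > 0")
    if (rr_sd_bpm < 0) fail("rr_sd_bpm must be >= 0")
    if (!(baseline_rh_pct >= 0 && baseline_rh_pct < envelope_mean_rh_pct)) {
      fail("need 0 <= baseline_rh_pct < envelope_mean_rh_pct")
    }
    if (!(envelope_mean_rh_pct <= 100)) fail("envelope_mean_rh_pct must be <= 100")
    if (!(exhale_saturation_rh_pct > baseline_rh_pct &&
          exhale_saturation_rh_pct <= 100)) {
      fail("exhale_saturation_rh_pct must lie in (baseline_rh_pct, 100]")
    }
    if (!(deep_breath_period_s > 60 / rr_mean_bpm)) {
      fail("deep_breath_period_s must exceed one breath period (60/rr_mean_bpm)")
    }
    if (!(deep_amplitude_factor > 1)) fail("deep_amplitude_factor must be > 1")
    if (!(deep_duration_factor >= 1)) fail("deep_duration_factor must be >= 1")
    if (noise_sd_rh_pct < 0) fail("noise_sd_rh_pct must be >= 0")
    if (!(rh_sample_rate_hz > 0 && flow_sample_rate_hz > 0)) {
      fail("sampling rates must be > 0")
    }
    if (!(volume_gain_l_per_rhs > 0)) fail("volume_gain_l_per_rhs must be > 0")
    if (flow_noise_sd_l_per_s < 0) fail("flow_noise_sd_l_per_s must be >= 0")
  })
  invisible(cfg)
}

# Per-cycle period sampler: truncated normal at +/- 3 SD (degenerate at sd=0).
rtrunc_norm <- function(n, mean, sd, lower = mean - 3 * sd,
                        upper = mean + 3 * sd) {
  if (sd == 0) return(rep(mean, n))
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

#' Simulate one subject's paired RH / flow recording
#'
#' Generates a quasi-periodic train of raised-cosine breath pulses on the
#' humidity channel (trough at ambient baseline, exhalation peak drawn from
#' the envelope distribution and capped at saturation), one deep cycle per
#' `deep_breath_period_s`, plus Gaussian sensor noise and linear drift. The
#' reference flow channel carries one half-sine pulse per cycle whose time
#' integral equals the cycle's ground-truth volume. Ground truth records
#' every cycle boundary, label, and volume.
#'
#' True volumes follow the proportionality between exhaled-humidity pulse
#' area and breath volume: volume = `volume_gain_l_per_rhs` times the
#' noiseless, drift-free pulse area above baseline.
#'
#' @param config A [breath_config()].
#' @return A list of class `breath_recording` with elements `rh` and `flow`
#'   ([breath_signal()]s), `truth` (list with `cycles` tibble, `boundaries`
#'   sample indices of true minima on the RH grid, and an `anomalies`
#'   tibble), and `config`.
#' @export
#' @examples
#' rec <- simulate_subject(breath_config(duration_s = 60, seed = 7))
#' rec$truth$cycles
simulate_subject <- function(config = breath_config()) {
  stopifnot(inherits(config, "breath_config"))
  validate_breath_config(config)
  withr::with_seed(config$seed, simulate_subject_impl(config))
}

simulate_subject_impl <- function(cfg) {
  period_mean <- 60 / cfg$rr_mean_bpm
  period_sd <- 60 * cfg$rr_sd_bpm / cfg$rr_mean_bpm^2

  # --- schedule cycles; deep breaths are due on absolute protocol times
  # (half a period in, then every deep_breath_period_s)
  starts <- numeric(0); durs <- numeric(0); labels <- character(0)
  peaks <- numeric(0)
  t <- 0; n_deep <- 0
  first_deep_at <- cfg$deep_breath_period_s / 2
  # keep >= 0.6 period of tail so the last complete cycle's end boundary is
  # followed by the rise of the next (partial) breath, as in a real
  # recording cut mid-breath
  tail_reserve <- 0.6 * period_mean
  repeat {
    period <- rtrunc_norm(1, period_mean, period_sd)
    period <- max(period, period_mean / 3)
    deep <- t >= first_deep_at + n_deep * cfg$deep_breath_period_s
    dur <- if (deep) period * cfg$deep_duration_factor else period
    if (t + dur > cfg$duration_s - tail_reserve + 1e-9) break
    draw <- max(stats::rnorm(1, cfg$envelope_mean_rh_pct, cfg$envelope_sd_rh_pct),
                cfg$baseline_rh_pct + 5)
    peak <- if (deep) {
      cfg$baseline_rh_pct + cfg$deep_amplitude_factor * (draw - cfg$baseline_rh_pct)
    } else {
      draw
    }
    starts <- c(starts, t); durs <- c(durs, dur)
    labels <- c(labels, if (deep) "deep" else "normal")
    peaks <- c(peaks, peak)
    if (deep) n_deep <- n_deep + 1
    t <- t + dur
  }
  n_cyc <- length(starts)
  if (n_cyc == 0L) {
    rlang::abort("duration_s too short to hold a single breath cycle",
                 class = "rhbreath_config_error")
  }
  ends <- starts + durs

  # phantom partial breath filling the tail (rendered, not in the truth)
  ph_dur <- max(rtrunc_norm(1, period_mean, period_sd), period_mean / 3)
  ph_peak <- max(stats::rnorm(1, cfg$envelope_mean_rh_pct, cfg$envelope_sd_rh_pct),
                 cfg$baseline_rh_pct + 5)
  r_starts <- c(starts, t); r_durs <- c(durs, ph_dur); r_peaks <- c(peaks, ph_peak)
  n_rend <- n_cyc + 1L

  # --- render the noiseless RH waveform (vectorized over samples)
  rate <- cfg$rh_sample_rate_hz
  n_samp <- floor(cfg$duration_s * rate)
  start_idx <- pmin(floor(r_starts * rate + 0.5) + 1L, n_samp)
  last_end <- min(floor((t + ph_dur) * rate + 0.5) + 1L, n_samp + 1L)
  r_bound <- c(start_idx, last_end)
  seg_len <- diff(r_bound)
  cyc_of <- rep.int(seq_len(n_rend), seg_len)
  i_local <- sequence(seg_len) - 1L
  tau <- i_local / (r_durs[cyc_of] * rate)
  pulse <- cfg$baseline_rh_pct +
    (r_peaks[cyc_of] - cfg$baseline_rh_pct) * 0.5 * (1 - cos(2 * pi * tau))
  pulse <- pmin(pulse, cfg$exhale_saturation_rh_pct)
  clean <- rep(cfg$baseline_rh_pct, n_samp)
  clean[seq.int(r_bound[[1]], r_bound[[n_rend + 1L]] - 1L)] <- pulse
  bound_idx <- r_bound[seq_len(n_cyc + 1L)]

  # --- ground-truth areas and volumes from the noiseless waveform
  dt <- 1 / rate
  above <- clean - cfg$baseline_rh_pct
  cum <- c(0, cumsum(above) * dt)
  area_at <- function(i0, i1) cum[i1] - cum[i0]        # [i0, i1) sample sums
  peak_idx <- pmin(floor((starts + durs / 2) * rate + 0.5) + 1L, n_samp)
  area <- area_at(bound_idx[-(n_cyc + 1L)], bound_idx[-1L])
  area_in <- area_at(bound_idx[-(n_cyc + 1L)], peak_idx)
  area_ex <- area - area_in
  gain <- cfg$volume_gain_l_per_rhs
  cycles <- tibble::tibble(
    cycle = seq_len(n_cyc),
    start_s = starts, end_s = ends, peak_s = starts + durs / 2,
    start_idx = as.integer(bound_idx[-(n_cyc + 1L)]),
    end_idx = as.integer(bound_idx[-1L]),
    label = labels,
    area_rhs = area,
    volume_l = gain * area,
    irv_l = ifelse(labels == "deep", gain * area_in, NA_real_),
    erv_l = ifelse(labels == "deep", gain * area_ex, NA_real_),
    vc_l  = ifelse(labels == "deep", gain * area, NA_real_)
  )

  # --- observed RH: drift + sensor noise, clipped to the physical range
  t_s <- (seq_len(n_samp) - 1) * dt
  rh <- clean + cfg$drift_rh_pct_per_min * t_s / 60
  if (cfg$noise_sd_rh_pct > 0) {
    rh <- rh + stats::rnorm(n_samp, 0, cfg$noise_sd_rh_pct)
  }
  rh <- pmin(pmax(rh, 0), 100)

  # --- reference flow channel: half-sine pulse per cycle, unit integral
  # scaled to the true volume (phantom tail breath included)
  frate <- cfg$flow_sample_rate_hz
  fn <- floor(cfg$duration_s * frate)
  f_start <- pmin(floor(r_starts * frate + 0.5) + 1L, fn)
  f_bound <- c(f_start, min(floor((t + ph_dur) * frate + 0.5) + 1L, fn + 1L))
  f_len <- diff(f_bound)
  f_cyc <- rep.int(seq_len(n_rend), f_len)
  f_tau <- (sequence(f_len) - 1L) / (r_durs[f_cyc] * frate)
  ph_vol <- gain * (min(ph_peak, cfg$exhale_saturation_rh_pct) -
                      cfg$baseline_rh_pct) * ph_dur / 2
  vol <- c(cycles$volume_l, ph_vol)
  f_pulse <- vol[f_cyc] * pi / (2 * r_durs[f_cyc]) * sin(pi * pmin(f_tau, 1))
  flow <- numeric(fn)
  flow[seq.int(f_bound[[1]], f_bound[[n_rend + 1L]] - 1L)] <- f_pulse
  if (cfg$flow_noise_sd_l_per_s > 0) {
    flow <- flow + stats::rnorm(fn, 0, cfg$flow_noise_sd_l_per_s)
  }

  structure(list(
    rh = breath_signal(rh, rate, units = "%RH"),
    flow = breath_signal(flow, frate, units = "L/s"),
    truth = list(
      cycles = cycles,
      boundaries = as.integer(bound_idx),
      anomalies = tibble::tibble(kind = character(), start_s = numeric(),
                                 end_s = numeric())
    ),
    config = cfg
  ), class = "breath_recording")
}

#' @export
print.breath_recording <- function(x, ...) {
  dur <- nrow(x$rh) / signal_rate(x$rh)
  if (is.null(x$truth)) {
    cat(sprintf("<breath_recording> %.0f s, RH @ %g Hz, flow @ %g Hz (no truth)\n",
                dur, signal_rate(x$rh), signal_rate(x$flow)))
    return(invisible(x))
  }
  n_deep <- sum(x$truth$cycles$label == "deep")
  cat(sprintf(
    "<breath_recording> %.0f s, %d cycles (%d deep), RH @ %g Hz, flow @ %g Hz\n",
    dur, nrow(x$truth$cycles), n_deep,
    signal_rate(x$rh), signal_rate(x$flow)))
  if (nrow(x$truth$anomalies) > 0) {
    cat(sprintf("  anomalies: %s\n",
                paste(x$truth$anomalies$kind, collapse = ", ")))
  }
  invisible(x)
}

#' Inject a breathing anomaly into a recording
#'
#' Perturbs the humidity waveform locally to emulate the artifacts seen in
#' mask recordings: `"saccade"` superimposes a short mid-cycle oscillation;
#' `"missing_recovery"` suppresses the return to the ambient baseline after
#' an exhalation, so the affected cycle boundary no longer drops to the
#' ambient trough. The anomaly window is appended to the ground-truth
#' annotations. The flow channel is untouched.
#'
#' @param rec A `breath_recording`.
#' @param kind `"saccade"` or `"missing_recovery"`.
#' @param at_s Anomaly centre, seconds (must fall inside the recording).
#' @return A modified copy of `rec`.
#' @export
inject_anomaly <- function(rec, kind = c("saccade", "missing_recovery"), at_s) {
  stopifnot(inherits(rec, "breath_recording"))
  kind <- rlang::arg_match(kind)
  cfg <- rec$config
  if (!is.numeric(at_s) || at_s < 0 || at_s > cfg$duration_s) {
    rlang::abort(sprintf("at_s = %g outside the recording [0, %g] s",
                         at_s, cfg$duration_s),
                 class = "rhbreath_range_error")
  }
  rate <- signal_rate(rec$rh)
  v <- rec$rh$value
  n <- length(v)
  amp_ref <- cfg$envelope_mean_rh_pct - cfg$baseline_rh_pct

  if (kind == "saccade") {
    half <- 1.5
    w0 <- max(at_s - half, 0); w1 <- min(at_s + half, cfg$duration_s)
    idx <- seq.int(floor(w0 * rate) + 1L, min(ceiling(w1 * rate), n))
    t_rel <- ((idx - 1) / rate - at_s) / half
    taper <- cos(pi * pmin(abs(t_rel), 1) / 2)^2
    v[idx] <- v[idx] + 0.15 * amp_ref * taper * sin(2 * pi * 2.5 * (idx - 1) / rate)
    window <- c(w0, w1)
  } else {
    # raise the cycle boundary nearest at_s so ventilatory recovery is lost
    cyc <- rec$truth$cycles
    bnd_s <- c(cyc$start_s, cyc$end_s[[nrow(cyc)]])
    b <- bnd_s[[which.min(abs(bnd_s - at_s))]]
    local_period <- stats::median(cyc$end_s - cyc$start_s)
    half <- 0.6 * local_period
    w0 <- max(b - half, 0); w1 <- min(b + half, cfg$duration_s)
    idx <- seq.int(floor(w0 * rate) + 1L, min(ceiling(w1 * rate), n))
    t_rel <- ((idx - 1) / rate - b) / half
    v[idx] <- v[idx] + 0.35 * amp_ref * cos(pi * pmin(abs(t_rel), 1) / 2)^2
    window <- c(w0, w1)
  }
  v <- pmin(pmax(v, 0), 100)
  rec$rh <- breath_signal(v, rate, units = "%RH")
  rec$truth$anomalies <- dplyr::bind_rows(
    rec$truth$anomalies,
    tibble::tibble(kind = kind, start_s = window[[1]], end_s = window[[2]])
  )
  rec
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject configurations from normal distributions around a base
#' configuration and simulates each subject with a seed derived from the
#' study seed, so the population is reproducible element-wise.
#'
#' @param n Number of subjects (>= 1).
#' @param config Base [breath_config()] giving the population means.
#' @param sd Named list of per-field population SDs (fields of
#'   [breath_config()]); fields not named are held fixed. Defaults emulate
#'   a small healthy cohort: respiratory-rate SD 1.7 breaths/min,
#'   exhalation-envelope SD 3 %RH, and 10% relative spread on the
#'   RH-area-to-volume gain.
#' @param seed Study-level seed for the population draw.
#' @return A list of `breath_recording`s of class `breath_population`.
#' @export
simulate_population <- function(n, config = breath_config(),
                                sd = list(rr_mean_bpm = 1.7,
                                          envelope_mean_rh_pct = 3,
                                          volume_gain_l_per_rhs = 0.0006),
                                seed = config$seed) {
  if (!is.numeric(n) || n < 1) {
    rlang::abort("n must be >= 1", class = "rhbreath_config_error")
  }
  n <- as.integer(n)
  draws <- withr::with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    fields <- purrr::imap(sd, function(s, nm) {
      if (is.null(config[[nm]])) {
        rlang::abort(sprintf("unknown config field '%s' in sd", nm),
                     class = "rhbreath_config_error")
      }
      rtrunc_norm(n, config[[nm]], s)
    })
    list(seeds = subject_seeds, fields = fields)
  })
  recs <- purrr::map(seq_len(n), function(i) {
    cfg <- config
    for (nm in names(draws$fields)) cfg[[nm]] <- draws$fields[[nm]][[i]]
    # guard: population draws must stay inside the config's validity region
    cfg$rr_mean_bpm <- max(cfg$rr_mean_bpm, 60 / cfg$deep_breath_period_s + 1)
    cfg$envelope_mean_rh_pct <- min(max(cfg$envelope_mean_rh_pct,
                                        cfg$baseline_rh_pct + 5), 100)
    cfg$seed <- draws$seeds[[i]]
    simulate_subject(do.call(breath_config, unclass(cfg)))
  })
  structure(recs, class = "breath_population")
}

#' Write / load a recording as plain-text files
#'
#' `write_recording()` writes `rh.csv` and `flow.csv` (`time_s,value` with a
#' units sidecar), `truth.csv`
#' (`cycle_start_s,cycle_end_s,label,volume_l`), and a `config.yaml`
#' snapshot into `dir`. `load_recording()` reads them back; `truth.csv` and
#' `config.yaml` are optional (real recordings have neither).
#'
#' @param rec A `breath_recording`.
#' @param dir Output directory (created if missing).
#' @return `write_recording()` returns `dir` invisibly; `load_recording()`
#'   returns a `breath_recording` (with `truth = NULL` when absent).
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "breath_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_timeseries_csv(rec$rh, file.path(dir, "rh.csv"))
  write_timeseries_csv(rec$flow, file.path(dir, "flow.csv"))
  truth <- rec$truth$cycles |>
    dplyr::transmute(cycle_start_s = .data$start_s, cycle_end_s = .data$end_s,
                     label = .data$label, volume_l = .data$volume_l)
  readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
  yaml::write_yaml(unclass(rec$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_recording
#' @export
load_recording <- function(dir) {
  rh <- read_timeseries_csv(file.path(dir, "rh.csv"))
  flow <- read_timeseries_csv(file.path(dir, "flow.csv"))
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) {
    tc <- readr::read_csv(tp, show_col_types = FALSE, progress = FALSE)
    truth <- list(cycles = tibble::tibble(
      cycle = seq_len(nrow(tc)),
      start_s = tc$cycle_start_s, end_s = tc$cycle_end_s,
      label = tc$label, volume_l = tc$volume_l
    ), anomalies = tibble::tibble(kind = character(), start_s = numeric(),
                                  end_s = numeric()))
  }
  cfg <- NULL
  cp <- file.path(dir, "config.yaml")
  if (file.exists(cp)) {
    cfg <- structure(yaml::read_yaml(cp), class = "breath_config")
  }
  structure(list(rh = rh, flow = flow, truth = truth, config = cfg),
            class = "breath_recording")
}
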