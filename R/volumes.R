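#' Rectangle-method area under the curve
#'
#' Left-endpoint Riemann sum of the baseline-subtracted signal over the
#' half-open sample interval `[start_idx, end_idx)`:
#' `sum(max(f(x_i) - baseline, 0)) * dt` with `dt = 1/sample_rate_hz`.
#' This is the estimator behind every volumetric parameter (TV, IRV, ERV,
#' VC, DBA); its units are signal units times seconds (%RH·s for humidity,
#' liters for flow).
#'
#' @param signal A [breath_signal()].
#' @param start_idx,end_idx 1-based sample indices, `start_idx < end_idx`,
#'   `end_idx <= nrow(signal) + 1`.
#' @param baseline Baseline to subtract (signal units); values below it
#'   contribute zero.
#' @return The area (scalar).
#' @export
#' @examples
#' sig <- breath_signal(rep(2, 30), 10)
#' rectangle_area(sig, 1, 31) # 2 * 3 s = 6
rectangle_area <- function(signal, start_idx, end_idx, baseline = 0) {
  assert_signal(signal)
  n <- nrow(signal)
  if (!(start_idx >= 1 && start_idx < end_idx && end_idx <= n + 1)) {
    rlang::abort(sprintf(
      "invalid sample interval [%s, %s) for a %d-sample signal",
      start_idx, end_idx, n), class = "rhbreath_range_error")
  }
  v <- signal$value[seq.int(start_idx, end_idx - 1L)]
  sum(pmax(v - baseline, 0)) / signal_rate(signal)
}

#' Triangle-method area for one breath cycle
#'
#' Area of the triangle with vertices at the cycle start, peak, and end
#' samples (shoelace formula). Provided only for comparison against the
#' rectangle method, which tracks reference volumes much more closely;
#' collinear vertices give area 0.
#'
#' @param signal A [breath_signal()].
#' @param cycle A one-row `breath_segmentation` slice (or any list with
#'   `start_idx`, `peak_idx`, `end_idx`).
#' @param baseline Kept for interface symmetry with [rectangle_area()]; a
#'   vertical shift does not change the triangle's area.
#' @return The triangle area, signal units times seconds.
#' @export
triangle_area <- function(signal, cycle, baseline = 0) {
  assert_signal(signal)
  s <- cycle$start_idx[[1]]; p <- cycle$peak_idx[[1]]; e <- cycle$end_idx[[1]]
  n <- nrow(signal)
  if (!(s >= 1 && s < p && p < min(e, n + 1) && e <= n + 1)) {
    rlang::abort("cycle indices out of order or outside the signal",
                 class = "rhbreath_range_error")
  }
  e <- min(e, n)
  rate <- signal_rate(signal)
  t <- (c(s, p, e) - 1) / rate
  y <- signal$value[c(s, p, e)] - baseline
  abs(t[[1]] * (y[[2]] - y[[3]]) + t[[2]] * (y[[3]] - y[[1]]) +
        t[[3]] * (y[[1]] - y[[2]])) / 2
}

#' Default integration baseline
#'
#' The per-recording 5th percentile of the signal, taken as the ambient
#' humidity floor the breath pulses rise from.
#'
#' @param signal A [breath_signal()].
#' @return Scalar baseline in signal units.
#' @export
area_baseline <- function(signal) {
  assert_signal(signal)
  unname(stats::quantile(signal$value, 0.05, type = 7))
}

#' Linear calibration from areas to liters
#'
#' Least-squares fit of reference volumes (liters) on estimated areas
#' (%RH·s): `volume = offset + gain * area`. The humidity-to-volume
#' proportionality has no published constant, so the gain is estimated per
#' study (or per subject) against the reference channel.
#'
#' @param estimated_areas Areas from the humidity channel, %RH·s.
#' @param reference_volumes Paired reference volumes, liters.
#' @return A list of class `breath_calibration` with `gain`, `offset`, and
#'   the underlying `lm` fit.
#' @export
fit_calibration <- function(estimated_areas, reference_volumes) {
  if (length(estimated_areas) != length(reference_volumes) ||
      length(estimated_areas) < 2L) {
    rlang::abort("need >= 2 paired (area, volume) points",
                 class = "rhbreath_config_error")
  }
  if (stats::sd(estimated_areas) == 0) {
    rlang::abort("areas are constant; calibration fit is singular",
                 class = "rhbreath_singular_error")
  }
  fit <- stats::lm(reference_volumes ~ estimated_areas)
  gain <- unname(stats::coef(fit)[[2]])
  if (!is.finite(gain) || gain <= 0) {
    rlang::warn("calibration gain is not positive; areas and volumes disagree in sign")
  }
  structure(list(gain = gain, offset = unname(stats::coef(fit)[[1]]),
                 fit = fit), class = "breath_calibration")
}

#' @rdname fit_calibration
#' @param calibration A `breath_calibration`.
#' @param areas Areas to convert, %RH·s.
#' @return `apply_calibration()` returns volumes in liters.
#' @export
apply_calibration <- function(calibration, areas) {
  stopifnot(inherits(calibration, "breath_calibration"))
  calibration$offset + calibration$gain * areas
}

#' Per-recording volumetric parameters
#'
#' Computes the rectangle-method area of every cycle and derives the lung
#' volume proxies: TV (tidal volume) for each normal cycle; for each deep
#' event, IRV from the deep-inhale limb (refined onset to peak), ERV from
#' the deep-exhale limb (peak to refined end), VC = IRV + ERV, and DBA (the
#' deep-breathing area) over the event's full closed span. Areas are in
#' signal units x seconds; when a calibration is supplied, liter-scale
#' columns (`*_l`) are added.
#'
#' @param signal The [breath_signal()] the segmentation came from.
#' @param seg A `breath_segmentation` (run [detect_deep_breaths()] first if
#'   deep events are wanted).
#' @param calibration Optional [fit_calibration()] result.
#' @param baseline Integration baseline; defaults to [area_baseline()].
#' @return A list of class `respiratory_parameters` with tibbles `tv` (one
#'   row per normal cycle) and `deep` (one row per deep event; empty when
#'   the segmentation has none), plus `baseline` and `units`.
#' @export
compute_volumes <- function(signal, seg, calibration = NULL, baseline = NULL) {
  assert_signal(signal)
  stopifnot(inherits(seg, "breath_segmentation"))
  baseline <- baseline %||% area_baseline(signal)
  rate <- signal_rate(signal)
  t0 <- signal_start(signal)

  normal <- tibble::as_tibble(seg)[seg$label == "normal", ]
  tv <- tibble::tibble(
    cycle = normal$cycle,
    start_s = normal$start_s, end_s = normal$end_s,
    area = purrr::map2_dbl(normal$start_idx, normal$end_idx,
                           ~ rectangle_area(signal, .x, .y, baseline))
  )

  ev <- deep_events(seg)
  deep <- tibble::tibble(
    event = ev$event, cycle = ev$cycle,
    start_s = t0 + (ev$start_idx - 1) / rate,
    end_s = t0 + (ev$end_idx - 1) / rate,
    irv = purrr::map2_dbl(ev$inhale_onset_idx, ev$peak_idx,
                          ~ rectangle_area(signal, .x, .y, baseline)),
    erv = purrr::map2_dbl(ev$peak_idx, ev$exhale_end_idx,
                          ~ rectangle_area(signal, .x, .y, baseline))
  ) |>
    dplyr::mutate(
      vc = .data$irv + .data$erv,
      dba = purrr::map2_dbl(ev$start_idx, ev$end_idx,
                            ~ rectangle_area(signal, .x, .y, baseline))
    )

  if (!is.null(calibration)) {
    tv$volume_l <- apply_calibration(calibration, tv$area)
    for (col in c("irv", "erv", "vc", "dba")) {
      deep[[paste0(col, "_l")]] <- apply_calibration(calibration, deep[[col]])
    }
  }
  structure(list(tv = tv, deep = deep, baseline = baseline,
                 units = paste0(signal_units(signal), "·s")),
            class = "respiratory_parameters")
}

#' @export
print.respiratory_parameters <- function(x, ...) {
  cat(sprintf("<respiratory_parameters> %d tidal cycles, %d deep events [%s]\n",
              nrow(x$tv), nrow(x$deep), x$units))
  if (nrow(x$tv) > 0) {
    cat(sprintf("  mean TV area %.3g %s\n", mean(x$tv$area), x$units))
  }
  if (nrow(x$deep) > 0) {
    cat(sprintf("  mean DBA %.3g, mean VC %.3g %s\n",
                mean(x$deep$dba), mean(x$deep$vc), x$units))
  }
  invisible(x)
}

#' Deep-breathing area of one event
#'
#' Rectangle-method area over the closed deep-breath interval, from the
#' refined deep-inhalation onset to the refined deep-exhalation end.
#'
#' @param signal A [breath_signal()].
#' @param event One row of [deep_events()].
#' @param baseline Integration baseline; defaults to [area_baseline()].
#' @return The DBA (signal units x seconds).
#' @export
deep_breathing_area <- function(signal, event, baseline = NULL) {
  assert_signal(signal)
  baseline <- baseline %||% area_baseline(signal)
  rectangle_area(signal, event$start_idx[[1]], event$end_idx[[1]], baseline)
}

#' Tidy per-cycle parameters into a long tibble
#'
#' One row per (cycle, parameter kind) with the area and, when calibrated,
#' the liter-scale volume (`cycle_idx, kind, area_rhs, volume_l` layout).
#'
#' @param x A `respiratory_parameters` object.
#' @param ... Unused.
#' @export
tidy.respiratory_parameters <- function(x, ...) {
  tv_long <- tibble::tibble(
    cycle = x$tv$cycle, kind = "tv", area = x$tv$area,
    volume_l = x$tv[["volume_l"]] %||% rep(NA_real_, nrow(x$tv))
  )
  deep_long <- purrr::map_dfr(c("irv", "erv", "vc", "dba"), function(k) {
    tibble::tibble(
      cycle = x$deep$cycle, kind = k, area = x$deep[[k]],
      volume_l = x$deep[[paste0(k, "_l")]] %||% rep(NA_real_, nrow(x$deep))
    )
  })
  dplyr::bind_rows(tv_long, deep_long) |>
    dplyr::arrange(.data$cycle, .data$kind)
}
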