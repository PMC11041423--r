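#' Configuration for an end-to-end agreement study
#'
#' Collects every knob of the simulate/ingest -> segment -> volumes ->
#' agreement pipeline under one reproducible object. Exactly one input mode
#' is active: `recordings` / `paths` switch the pipeline to supplied data,
#' otherwise `n_subjects` recordings are simulated from `subject_config`.
#'
#' @param n_subjects Cohort size for simulation (default 7).
#' @param subject_config Base [breath_config()] for the simulated cohort.
#' @param population_sd Per-field population SDs (see
#'   [simulate_population()]).
#' @param recordings Optional list of `breath_recording`s to analyze
#'   instead of simulating.
#' @param paths Optional character vector of recording directories for
#'   [load_recording()].
#' @param grid_hz Common analysis grid both channels are resampled to
#'   before segmentation (default 100 Hz; breathing content is < 1 Hz, and
#'   this equalizes the 5 kHz / 1 kHz channel disparity).
#' @param smooth_cutoff_hz Zero-phase low-pass cutoff, Hz.
#' @param window_s Respiratory-rate window, seconds.
#' @param duration_k,area_k Deep-breath duration and area thresholds
#'   (see [detect_deep_breaths()]).
#' @param loa_mode Bland-Altman LoA estimator (see [bland_altman()]).
#' @param seed Study seed; every random draw flows from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 7,
                         subject_config = breath_config(),
                         population_sd = list(rr_mean_bpm = 1.7,
                                              envelope_mean_rh_pct = 3,
                                              volume_gain_l_per_rhs = 0.0006),
                         recordings = NULL,
                         paths = NULL,
                         grid_hz = 100,
                         smooth_cutoff_hz = 2,
                         window_s = 60,
                         duration_k = 1.21,
                         area_k = 0.8,
                         loa_mode = "normal",
                         seed = 1L) {
  if (!is.null(recordings) && !is.null(paths)) {
    rlang::abort("supply at most one of `recordings` and `paths`",
                 class = "rhbreath_config_error")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), subject_config = subject_config,
    population_sd = population_sd, recordings = recordings, paths = paths,
    grid_hz = grid_hz, smooth_cutoff_hz = smooth_cutoff_hz,
    window_s = window_s, duration_k = duration_k, area_k = area_k,
    loa_mode = loa_mode,
    seed = as.integer(seed)
  ), class = "study_config")
}

# Segment one channel on the analysis grid: resample, smooth, find extrema
# with a prominence adapted to the channel's dynamic range, segment, and
# refine deep breaths.
segment_channel <- function(signal, config) {
  grid <- resample_signal(signal, config$grid_hz)
  sm <- smooth_signal(grid, config$smooth_cutoff_hz)
  rng <- stats::quantile(sm$value, c(0.01, 0.99), names = FALSE)
  prom <- 0.2 * (rng[[2]] - rng[[1]])
  ext <- find_breath_extrema(sm, min_prominence = prom, min_separation_s = 1)
  seg <- segment_breath_cycles(sm, ext$minima, ext$maxima)
  seg <- detect_deep_breaths(sm, seg, duration_k = config$duration_k,
                             area_k = config$area_k)
  list(signal = sm, extrema = ext, seg = seg)
}

# Nearest-neighbour matching of two event-time vectors within a tolerance.
# Returns a tibble of index pairs (i into a, j into b).
match_times <- function(a_times, b_times, tol) {
  if (length(a_times) == 0L || length(b_times) == 0L) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  j <- vapply(a_times, function(t) {
    k <- which.min(abs(b_times - t))
    if (abs(b_times[[k]] - t) <= tol) k else NA_integer_
  }, integer(1))
  keep <- !is.na(j) & !duplicated(j)
  tibble::tibble(i = which(keep), j = j[keep])
}

# Analyze one subject: segment both channels, estimate areas/volumes,
# calibrate the RH areas against the flow-integral reference, and emit the
# matched per-cycle, per-deep-event and per-window pairs.
analyze_subject <- function(rec, config, subject_id) {
  rh <- segment_channel(rec$rh, config)
  fl <- segment_channel(rec$flow, config)
  vol_rh <- compute_volumes(rh$signal, rh$seg)
  vol_fl <- compute_volumes(fl$signal, fl$seg, baseline = 0)

  period <- stats::median(rh$seg$end_s - rh$seg$start_s)
  tol <- 0.5 * period

  all_rh <- dplyr::bind_rows(
    dplyr::transmute(vol_rh$tv, start_s = .data$start_s, area = .data$area),
    dplyr::transmute(vol_rh$deep, start_s = .data$start_s, area = .data$dba)
  ) |> dplyr::arrange(.data$start_s)
  all_fl <- dplyr::bind_rows(
    dplyr::transmute(vol_fl$tv, start_s = .data$start_s, volume_l = .data$area),
    dplyr::transmute(vol_fl$deep, start_s = .data$start_s, volume_l = .data$dba)
  ) |> dplyr::arrange(.data$start_s)

  m <- match_times(all_rh$start_s, all_fl$start_s, tol)
  if (nrow(m) < 2L) {
    rlang::abort(sprintf(
      "subject %s: fewer than 2 matched cycles between channels (stage: calibration)",
      subject_id), class = "rhbreath_stage_error")
  }
  calib <- fit_calibration(all_rh$area[m$i], all_fl$volume_l[m$j])

  md <- match_times(vol_rh$deep$start_s, vol_fl$deep$start_s, 2 * tol)
  dba_pairs <- tibble::tibble(
    subject = subject_id,
    rhs = apply_calibration(calib, vol_rh$deep$dba[md$i]),
    pnt = vol_fl$deep$dba[md$j]
  )

  rr_rh <- respiratory_rate(rh$signal, rh$extrema$minima, config$window_s)
  rr_fl <- respiratory_rate(fl$signal, fl$extrema$minima, config$window_s)
  n_win <- min(nrow(rr_rh), nrow(rr_fl))
  rr_pairs <- tibble::tibble(
    subject = subject_id,
    window_start_s = rr_rh$window_start_s[seq_len(n_win)],
    rhs = rr_rh$rr_bpm[seq_len(n_win)],
    pnt = rr_fl$rr_bpm[seq_len(n_win)]
  )

  tv_pairs <- tibble::tibble(
    subject = subject_id,
    area_rhs = all_rh$area[m$i],
    volume_pnt_l = all_fl$volume_l[m$j],
    volume_rhs_l = apply_calibration(calib, all_rh$area[m$i])
  )

  list(subject = subject_id, rh = rh, flow = fl,
       volumes_rh = vol_rh, volumes_flow = vol_fl,
       calibration = calib, dba_pairs = dba_pairs, rr_pairs = rr_pairs,
       tv_pairs = tv_pairs)
}

#' Run the end-to-end agreement study
#'
#' Simulates (or ingests) paired RH/flow recordings, resamples both
#' channels onto the analysis grid, smooths, segments breath cycles,
#' detects deep breaths, estimates volumes on both channels (reference
#' volumes come from the integrated flow), calibrates RH areas to liters,
#' and runs the full agreement battery: Bland-Altman for DBA and RR,
#' one-way ANOVA (device as the grouping factor) for DBA and RR,
#' RMSE/correlation, and box summaries. The same config and seed always
#' reproduce the same report.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, per-subject parameter
#'   CSVs and the JSON report are written there.
#' @return A list of class `study_report`: `subjects` (per-subject
#'   results), `dba_pairs`, `rr_pairs`, `agreement` (two [bland_altman()]
#'   reports), `anova` (two [one_way_anova()] tables), `rmse` (two rows),
#'   `box` (four [box_summary()] rows), and `provenance`.
#' @export
run_experiment <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  recs <- if (!is.null(config$recordings)) {
    config$recordings
  } else if (!is.null(config$paths)) {
    purrr::map(config$paths, load_recording)
  } else {
    simulate_population(config$n_subjects, config$subject_config,
                        sd = config$population_sd, seed = config$seed)
  }

  subjects <- purrr::imap(recs, function(rec, i) {
    tryCatch(
      analyze_subject(rec, config, subject_id = i),
      rhbreath_stage_error = function(e) rlang::abort(conditionMessage(e), parent = e),
      error = function(e) {
        rlang::abort(sprintf("subject %s failed: %s", i, conditionMessage(e)),
                     parent = e)
      })
  })

  dba <- purrr::map_dfr(subjects, "dba_pairs")
  rr <- purrr::map_dfr(subjects, "rr_pairs")
  if (nrow(dba) < 2L || nrow(rr) < 2L) {
    rlang::abort("too few matched pairs pooled across subjects (stage: agreement)",
                 class = "rhbreath_stage_error")
  }

  agreement <- list(
    dba = bland_altman(dba$rhs, dba$pnt, subject = dba$subject,
                       loa = config$loa_mode),
    rr = bland_altman(rr$rhs, rr$pnt, subject = rr$subject,
                      loa = config$loa_mode)
  )
  anova <- list(
    dba = one_way_anova(list(rhs = dba$rhs, pnt = dba$pnt)),
    rr = one_way_anova(list(rhs = rr$rhs, pnt = rr$pnt))
  )
  rmse <- dplyr::bind_rows(
    dplyr::mutate(rmse_and_correlation(dba$rhs, dba$pnt), parameter = "dba"),
    dplyr::mutate(rmse_and_correlation(rr$rhs, rr$pnt), parameter = "rr")
  )
  box <- dplyr::bind_rows(
    dplyr::mutate(box_summary(dba$rhs), parameter = "dba", device = "rhs"),
    dplyr::mutate(box_summary(dba$pnt), parameter = "dba", device = "pnt"),
    dplyr::mutate(box_summary(rr$rhs), parameter = "rr", device = "rhs"),
    dplyr::mutate(box_summary(rr$pnt), parameter = "rr", device = "pnt")
  )

  report <- structure(list(
    subjects = subjects, dba_pairs = dba, rr_pairs = rr,
    agreement = agreement, anova = anova, rmse = rmse, box = box,
    provenance = list(
      seed = config$seed,
      n_subjects = length(subjects),
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("rhbreath"))
    )
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      readr::write_csv(tidy(s$volumes_rh),
                       file.path(out_dir, sprintf("subject%02d_rh_params.csv",
                                                  s$subject)), progress = FALSE)
    }
    writeLines(generate_report(report, "json"),
               file.path(out_dir, "report.json"))
    writeLines(generate_report(report, "text"),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' Render a study report
#'
#' Deterministic rendering of a [run_experiment()] report, as structured
#' JSON or a human-readable text summary (both include the seed and config
#' hash, so a report can be traced to the run that produced it).
#'
#' @param report A `study_report`.
#' @param format `"text"` or `"json"`.
#' @return A character vector (one element per line for text; a single
#'   JSON string for json).
#' @export
generate_report <- function(report, format = c("text", "json")) {
  stopifnot(inherits(report, "study_report"))
  format <- rlang::arg_match(format)
  ba_list <- function(ba) list(
    bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
    rmse = ba$rmse, pearson_r = ba$pearson_r, n = ba$n)
  an_list <- function(an) list(
    ss_between = an$ss[[1]], df_between = an$df[[1]],
    ss_within = an$ss[[2]], df_within = an$df[[2]],
    f = an$f[[1]], p = an$p[[1]])
  payload <- list(
    provenance = report$provenance,
    bland_altman = purrr::map(report$agreement, ba_list),
    anova = purrr::map(report$anova, an_list),
    rmse = purrr::transpose(report$rmse),
    box = purrr::transpose(dplyr::select(report$box, -"outliers"))
  )
  if (format == "json") {
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  fmt_ba <- function(nm, ba) sprintf(
    "  %-4s bias %8.4f  LoA [%8.4f, %8.4f]  r %.3f  (n = %d)",
    nm, ba$bias, ba$loa_lower, ba$loa_upper, ba$pearson_r, ba$n)
  fmt_an <- function(nm, an) sprintf(
    "  %-4s F(%d,%d) = %.4f, P = %.2f", nm, an$df[[1]], an$df[[2]],
    an$f[[1]], round(an$p[[1]], 2))
  c(
    sprintf("rhbreath study report (seed %d, %d subjects, config %s)",
            report$provenance$seed, report$provenance$n_subjects,
            report$provenance$config_hash),
    "Bland-Altman agreement (RHS vs PNT):",
    fmt_ba("DBA", report$agreement$dba),
    fmt_ba("RR", report$agreement$rr),
    "One-way ANOVA (device groups):",
    fmt_an("DBA", report$anova$dba),
    fmt_an("RR", report$anova$rr),
    "RMSE / correlation:",
    sprintf("  %-4s RMSE %.4f  r %.3f", toupper(report$rmse$parameter),
            report$rmse$rmse, report$rmse$pearson_r),
    "Box summaries (median [Q1, Q3]):",
    sprintf("  %-4s %-3s %.3f [%.3f, %.3f]",
            toupper(report$box$parameter), report$box$device,
            report$box$median, report$box$q1, report$box$q3)
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(generate_report(x, "text"), sep = "\n")
  invisible(x)
}
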