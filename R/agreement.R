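#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between a device under test (`a`) and a reference
#' (`b`) from paired measurements. Differences are `a - b` (`mode =
#' "unit"`) or `100 * (a - b) / pairwise mean` (`mode = "percent"`); the
#' bias is the mean difference and the limits of agreement (LoA) are
#' `bias +/- 1.96 * SD(diffs)` (sample SD), bounding ~95% of differences
#' under normality.
#'
#' Optional refinements used for population data: `normalize =
#' "per_subject_mean"` divides each subject's pair by that subject's mean
#' pairwise level first (the normalized-chart construction for
#' heteroscedastic volume data); `loa = "log"` computes bias/LoA on the log
#' scale and back-transforms, giving asymmetric limits; `loa = "mixed"`
#' fits a random-intercept model of the differences per subject (lme4) and
#' keeps the between-subject variance component only when it improves AIC
#' by more than 2 points, widening the LoA by the between-subject spread.
#'
#' @param a,b Equal-length numeric vectors (n >= 2): device and reference.
#' @param mode `"unit"` or `"percent"` differences.
#' @param normalize `"none"` or `"per_subject_mean"` (requires `subject`).
#' @param subject Optional subject id per pair (factor-like), for
#'   `normalize = "per_subject_mean"` and `loa = "mixed"`.
#' @param loa LoA estimator: `"normal"` (default), `"log"`, `"mixed"`.
#' @return A list of class `bland_altman`: `bias`, `loa_lower`,
#'   `loa_upper`, `diffs`, `means`, `mode`, `rmse`, `pearson_r`, `n`.
#' @export
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' ba$bias
bland_altman <- function(a, b, mode = c("unit", "percent"),
                         normalize = c("none", "per_subject_mean"),
                         subject = NULL, loa = c("normal", "log", "mixed")) {
  mode <- rlang::arg_match(mode)
  normalize <- rlang::arg_match(normalize)
  loa <- rlang::arg_match(loa)
  if (length(a) != length(b)) {
    rlang::abort("a and b must have equal length", class = "rhbreath_config_error")
  }
  if (length(a) < 2L) {
    rlang::abort("need at least 2 pairs", class = "rhbreath_config_error")
  }
  if (normalize == "per_subject_mean" || loa == "mixed") {
    if (is.null(subject) || length(subject) != length(a)) {
      rlang::abort("subject ids are required for per-subject normalization or mixed LoA",
                   class = "rhbreath_config_error")
    }
  }
  if (normalize == "per_subject_mean") {
    lvl <- stats::ave((a + b) / 2, subject)
    if (any(lvl == 0)) {
      rlang::abort("a subject mean level is zero; cannot normalize",
                   class = "rhbreath_config_error")
    }
    a <- a / lvl; b <- b / lvl
  }
  means <- (a + b) / 2
  diffs <- switch(mode,
    unit = a - b,
    percent = {
      zero <- which(means == 0)
      if (length(zero) > 0L) {
        rlang::abort(sprintf("pair %d has zero mean; percent difference undefined",
                             zero[[1]]), class = "rhbreath_config_error")
      }
      100 * (a - b) / means
    })

  if (loa == "log") {
    if (any(a <= 0 | b <= 0)) {
      rlang::abort("log LoA requires strictly positive measurements",
                   class = "rhbreath_config_error")
    }
    ld <- log(a) - log(b)
    bias_l <- mean(ld); sd_l <- stats::sd(ld)
    bias <- exp(bias_l)
    lower <- exp(bias_l - 1.96 * sd_l); upper <- exp(bias_l + 1.96 * sd_l)
  } else if (loa == "mixed") {
    rlang::check_installed("lme4")
    df <- data.frame(d = diffs, subject = factor(subject))
    m0 <- stats::lm(d ~ 1, data = df)
    m1 <- suppressMessages(lme4::lmer(d ~ 1 + (1 | subject), data = df,
                                      REML = FALSE))
    # variance component zeroed unless it buys > 2 AIC points
    if (stats::AIC(m0) - stats::AIC(m1) > 2) {
      vc <- as.data.frame(lme4::VarCorr(m1))
      tot_sd <- sqrt(sum(vc$vcov))
      bias <- unname(lme4::fixef(m1)[[1]])
    } else {
      tot_sd <- stats::sd(diffs)
      bias <- mean(diffs)
    }
    lower <- bias - 1.96 * tot_sd; upper <- bias + 1.96 * tot_sd
  } else {
    bias <- mean(diffs)
    sd_d <- stats::sd(diffs)
    lower <- bias - 1.96 * sd_d; upper <- bias + 1.96 * sd_d
  }

  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  structure(list(
    bias = bias, loa_lower = lower, loa_upper = upper,
    diffs = diffs, means = means, mode = mode, loa_method = loa,
    rmse = sqrt(mean((a - b)^2)), pearson_r = r, n = length(a)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d (%s differences, %s LoA)\n",
              x$n, x$mode, x$loa_method))
  cat(sprintf("  bias %.4g, LoA [%.4g, %.4g], RMSE %.4g, r %.3f\n",
              x$bias, x$loa_lower, x$loa_upper, x$rmse, x$pearson_r))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, diff = x$diffs)
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_lower = x$loa_lower,
                 loa_upper = x$loa_upper, rmse = x$rmse,
                 pearson_r = x$pearson_r, n = x$n, mode = x$mode)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition for two or more groups, with the
#' P value from the upper tail of the F distribution. Degenerate inputs
#' are resolved explicitly: zero within-group variance with distinct group
#' means gives P = 0 with a `degenerate` flag; all-identical values give
#' F = 0, P = 1.
#'
#' @param groups A list of numeric vectors (optionally named), one per
#'   group, or a data frame with columns `value` and `group`.
#' @return A tibble of class `breath_anova` with rows `between`, `within`,
#'   `total` and columns `source`, `ss`, `df`, `ms`, `f`, `p`.
#' @export
#' @examples
#' one_way_anova(list(a = c(0, 1), b = c(2, 3)))
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    rlang::abort("need >= 2 groups", class = "rhbreath_config_error")
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L) || sum(sizes) <= length(groups)) {
    rlang::abort("each group needs >= 1 value and total n must exceed the group count",
                 class = "rhbreath_config_error")
  }
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(seq_along(groups), sizes))
  fit <- stats::aov(value ~ group)
  # degenerate decompositions are resolved explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  ss_b <- tab$`Sum Sq`[[1]]; ss_w <- tab$`Sum Sq`[[2]]
  df_b <- tab$Df[[1]]; df_w <- tab$Df[[2]]
  build_anova_table(ss_b, df_b, ss_w, df_w)
}

build_anova_table <- function(ss_b, df_b, ss_w, df_w) {
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  degenerate <- FALSE
  tol <- 1e-12 * max(ss_b + ss_w, 1)
  if (ss_w <= tol && ss_b > tol) {
    f <- Inf; p <- 0; degenerate <- TRUE
  } else if (ss_b <= tol) {
    f <- 0; p <- 1
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  out <- tibble::tibble(
    source = c("between", "within", "total"),
    ss = c(ss_b, ss_w, ss_b + ss_w),
    df = c(df_b, df_w, df_b + df_w),
    ms = c(ms_b, ms_w, NA_real_),
    f = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_)
  )
  attr(out, "degenerate") <- degenerate
  class(out) <- unique(c("breath_anova", class(out)))
  out
}

#' Rebuild a one-way ANOVA from its printed decomposition
#'
#' Given the between/within sums of squares and degrees of freedom as they
#' appear in a published summary table, recomputes the mean squares, F
#' statistic, and P value, and fills in the totals. This makes a printed
#' ANOVA table checkable without the underlying data.
#'
#' @param ss_between,ss_within Sums of squares (>= 0).
#' @param df_between,df_within Degrees of freedom (positive integers).
#' @return A `breath_anova` tibble (see [one_way_anova()]).
#' @export
#' @examples
#' anova_from_summary(0.002, 1, 39.09, 346)
anova_from_summary <- function(ss_between, df_between, ss_within, df_within) {
  if (!(df_between >= 1 && df_within >= 1 &&
        df_between == round(df_between) && df_within == round(df_within))) {
    rlang::abort("degrees of freedom must be positive integers",
                 class = "rhbreath_config_error")
  }
  if (ss_between < 0 || ss_within < 0) {
    rlang::abort("sums of squares must be nonnegative",
                 class = "rhbreath_config_error")
  }
  build_anova_table(ss_between, df_between, ss_within, df_within)
}

#' @export
print.breath_anova <- function(x, ...) {
  cat("<one-way ANOVA>\n")
  df <- tibble::as_tibble(x)
  df$p <- ifelse(is.na(df$p), NA, format(round(df$p, 2), nsmall = 2))
  print(df)
  invisible(x)
}

#' @export
tidy.breath_anova <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.breath_anova <- function(x, ...) {
  tibble::tibble(f = x$f[[1]], p = x$p[[1]],
                 df_between = x$df[[1]], df_within = x$df[[2]])
}

#' RMSE and Pearson correlation of paired measurements
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @return A one-row tibble with `rmse` and `pearson_r`. With a constant
#'   input the correlation is undefined and returned as `NA` with a
#'   warning; the RMSE is still computed.
#' @export
rmse_and_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    rlang::abort("need equal-length vectors with n >= 2",
                 class = "rhbreath_config_error")
  }
  rmse <- sqrt(mean((a - b)^2))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::warn("correlation undefined for a constant input; returning NA")
    r <- NA_real_
  } else {
    r <- stats::cor(a, b)
  }
  tibble::tibble(rmse = rmse, pearson_r = r)
}

#' Box-plot summary of a sample
#'
#' Quartiles by linear interpolation (type 7), whiskers at the most extreme
#' observations within 1.5 IQR of the quartiles, points beyond the fences
#' flagged as outliers.
#'
#' @param values Numeric vector (n >= 1).
#' @return A one-row tibble of class `box_summary` with `median`, `q1`,
#'   `q3`, `iqr`, `whisker_low`, `whisker_high`, `n_outliers`, and an
#'   `outliers` list-column.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) {
    rlang::abort("need at least one value", class = "rhbreath_config_error")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[[3]] - q[[1]]
  lo_fence <- q[[1]] - 1.5 * iqr
  hi_fence <- q[[3]] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  out <- tibble::tibble(
    median = q[[2]], q1 = q[[1]], q3 = q[[3]], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    n_outliers = sum(values < lo_fence | values > hi_fence),
    outliers = list(sort(values[values < lo_fence | values > hi_fence]))
  )
  class(out) <- unique(c("box_summary", class(out)))
  out
}
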