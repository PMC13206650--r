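#' Circadian amplitude of an expression waveform
#'
#' Peak-to-trough range (`max - min`) of a replicate-averaged mean waveform on
#' the original, unnormalized expression scale, with peak and trough times.
#' Ties on the extreme values resolve to the earliest timepoint. A half-range
#' convention (`(max - min) / 2`) is available.
#'
#' @param waveform Numeric vector: the mean expression at each timepoint, in
#'   original units (never min-max normalized).
#' @param timepoints_h Clock times matching `waveform`.
#' @param half_range Return `(max - min) / 2` instead of `max - min`.
#' @return An `"amplitude_record"`: `amplitude`, `peak_time_h`,
#'   `trough_time_h`, `peak_value`, `trough_value`.
#' @export
circadian_amplitude <- function(waveform, timepoints_h, half_range = FALSE) {
  stopifnot(length(waveform) == length(timepoints_h), length(waveform) >= 1)
  ipk <- which.max(waveform)  # which.max/min take the earliest tie
  itr <- which.min(waveform)
  amp <- waveform[ipk] - waveform[itr]
  structure(list(amplitude = if (half_range) amp / 2 else amp,
                 peak_time_h = timepoints_h[ipk],
                 trough_time_h = timepoints_h[itr],
                 peak_value = waveform[ipk], trough_value = waveform[itr],
                 half_range = half_range),
            class = "amplitude_record")
}

#' @export
print.amplitude_record <- function(x, ...) {
  cat(sprintf("<amplitude_record> amplitude = %.4g (peak ZT%g, trough ZT%g)\n",
              x$amplitude, x$peak_time_h, x$trough_time_h))
  invisible(x)
}

#' Relative amplitude change between two conditions
#'
#' @param amplitudeA,amplitudeB Amplitudes (or `"amplitude_record"` objects)
#'   under the reference and comparison condition; the reference must be > 0.
#' @param mode `"ratio"` (B / A, default) or `"log2_ratio"`.
#' @return The amplitude change.
#' @export
amplitude_change <- function(amplitudeA, amplitudeB, mode = c("ratio", "log2_ratio")) {
  mode <- match.arg(mode)
  a <- if (inherits(amplitudeA, "amplitude_record")) amplitudeA$amplitude else amplitudeA
  b <- if (inherits(amplitudeB, "amplitude_record")) amplitudeB$amplitude else amplitudeB
  if (a == 0) stopf("amplitude change undefined: reference amplitude is 0")
  if (mode == "ratio") b / a else log2(b / a)
}

#' One-sample two-tailed t-test
#'
#' Thin, validated wrapper around [stats::t.test()], used on per-tissue log2
#' amplitude ratios against 0.
#'
#' @param values Numeric vector (>= 2 values, nonzero variance).
#' @param mu0 Null mean (default 0).
#' @return A list: `t`, `p_value`, `df`, `mean`.
#' @export
one_sample_ttest <- function(values, mu0 = 0) {
  if (length(values) < 2) stopf("need at least 2 values")
  if (stats::sd(values) == 0) stopf("zero variance: t statistic undefined")
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean = mean(values))
}

#' Unpaired two-tailed t-test
#'
#' Student's (pooled-variance, default) or Welch's two-sample t-test via
#' [stats::t.test()]. When both groups are constant, a zero difference gives
#' `t = 0, p = 1` and a nonzero difference is reported as `t = +/-Inf, p = 0`
#' with a zero-variance warning.
#'
#' @param groupA,groupB Numeric vectors, each with >= 2 values.
#' @param variant `"student"` or `"welch"`.
#' @return A list: `t`, `p_value`, `df`, `mean_A`, `mean_B`.
#' @export
unpaired_ttest <- function(groupA, groupB, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(groupA) < 2 || length(groupB) < 2)
    stopf("each group needs at least 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, p_value = 1, df = NA_real_,
                  mean_A = mean(groupA), mean_B = mean(groupB)))
    warning("both groups have zero variance; reporting t = Inf, p = 0",
            call. = FALSE)
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, p_value = 0,
                df = NA_real_, mean_A = mean(groupA), mean_B = mean(groupB)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_A = mean(groupA), mean_B = mean(groupB))
}
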