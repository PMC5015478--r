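#' Extraction configuration
#'
#' Windows and conventions for the nine-parameter MMN extraction.
#'
#' @param peak_window search window for the negative peak, ms post-onset,
#'   half-open `[start, end)` (default 100..300)
#' @param baseline_window baseline interval used for the threshold, ms,
#'   half-open (default -200..0)
#' @param ampavg_halfwidth half-width of the peak-averaging window, ms;
#'   both endpoints inclusive on the sample grid, so the default 20 ms at
#'   500 Hz averages 21 samples
#' @param area_reference `"zero"` (default) integrates the wave against the
#'   0 uV line between onset and offset; `"threshold"` integrates against Th
#' @return a list of class `mmn_extraction_config`
#' @export
mmn_extraction_config <- function(peak_window = c(100, 300),
                                  baseline_window = c(-200, 0),
                                  ampavg_halfwidth = 20,
                                  area_reference = c("zero", "threshold")) {
  stopifnot(peak_window[1] < peak_window[2],
            baseline_window[1] < baseline_window[2],
            ampavg_halfwidth > 0)
  structure(list(peak_window = peak_window,
                 baseline_window = baseline_window,
                 ampavg_halfwidth = ampavg_halfwidth,
                 area_reference = match.arg(area_reference)),
            class = "mmn_extraction_config")
}

as_wave <- function(wave) {
  if (inherits(wave, "mmn_wave")) return(wave)
  stop("expected an mmn_wave object")
}

#' Baseline-derived rejection threshold
#'
#' `Th = Amp_base - Std_base`: the mean of the baseline samples minus their
#' sample standard deviation (n-1 denominator). A wave that never dips below
#' Th in the peak window carries no deflection distinguishable from its own
#' baseline variability and is rejected as a "fake-MMN".
#'
#' @param wave an `mmn_wave`
#' @param baseline_window baseline interval, ms, half-open (default -200..0)
#' @return Th in uV
#' @export
compute_threshold <- function(wave, baseline_window = c(-200, 0)) {
  wave <- as_wave(wave)
  idx <- which(wave$t_axis >= baseline_window[1] &
               wave$t_axis < baseline_window[2])
  if (length(idx) < 2)
    stop("baseline window must contain at least 2 samples")
  b <- wave$samples[idx]
  mean(b) - stats::sd(b)
}

#' Fake-MMN rejection test
#'
#' A wave is a valid MMN iff some sample in the search window is strictly
#' more negative than the threshold.
#'
#' @param wave an `mmn_wave`
#' @param threshold Th in uV, from [compute_threshold()]
#' @param search_window ms interval to inspect, half-open (default 100..300,
#'   the peak window)
#' @return logical validity flag
#' @export
validate_mmn <- function(wave, threshold, search_window = c(100, 300)) {
  wave <- as_wave(wave)
  idx <- which(wave$t_axis >= search_window[1] &
               wave$t_axis < search_window[2])
  length(idx) > 0 && min(wave$samples[idx]) < threshold
}

#' Negative peak of the MMN wave
#'
#' The most negative sample in the search window; ties are broken by the
#' earliest time.
#'
#' @param wave an `mmn_wave`
#' @param window ms interval, half-open (default 100..300)
#' @return list with `peak_latency` (ms) and `amplitude` (uV, signed)
#' @export
find_peak <- function(wave, window = c(100, 300)) {
  wave <- as_wave(wave)
  idx <- which(wave$t_axis >= window[1] & wave$t_axis < window[2])
  if (length(idx) == 0) stop("peak window contains no samples")
  i <- idx[which.min(wave$samples[idx])]   # which.min: first (earliest) tie
  list(peak_latency = wave$t_axis[i], amplitude = wave$samples[i])
}

#' Averaged peak amplitude (ampavg)
#'
#' Mean voltage in a window of `half_width` ms on both sides of the peak,
#' endpoints inclusive on the sample grid. If the window pokes past the
#' epoch edge it is clipped and flagged.
#'
#' @param wave an `mmn_wave`
#' @param peak_latency peak time, ms
#' @param half_width window half-width, ms (default 20)
#' @return list with `ampavg` (uV, signed) and `clipped` flag
#' @export
compute_ampavg <- function(wave, peak_latency, half_width = 20) {
  wave <- as_wave(wave)
  tol <- 1e-9
  idx <- which(wave$t_axis >= peak_latency - half_width - tol &
               wave$t_axis <= peak_latency + half_width + tol)
  clipped <- (peak_latency - half_width < wave$t_axis[1] - tol) ||
             (peak_latency + half_width > wave$t_axis[length(wave$t_axis)] + tol)
  list(ampavg = mean(wave$samples[idx]), clipped = clipped)
}

#' Threshold-crossing onset and offset of the MMN excursion
#'
#' Starting from the peak sample, scans backward (onset) and forward
#' (offset) through the contiguous run of sub-threshold samples containing
#' the peak, and linearly interpolates the exact crossing time within the
#' first straddling sample pair. Restricting the search to the peak's own
#' excursion means earlier or later sub-threshold dips of a multi-dip wave
#' never capture the onset/offset. If the wave is still below threshold at
#' an epoch edge, the time is clamped to the edge and flagged.
#'
#' @param wave an `mmn_wave`
#' @param threshold Th in uV
#' @param peak_latency peak time, ms (a sample below threshold)
#' @return list with `onset`, `offset` (ms), `onset_clipped`,
#'   `offset_clipped` flags
#' @export
find_onset_offset <- function(wave, threshold, peak_latency) {
  wave <- as_wave(wave)
  t <- wave$t_axis; v <- wave$samples
  ipk <- which.min(abs(t - peak_latency))
  if (v[ipk] >= threshold)
    stop("peak sample is not below threshold; wave is not a valid MMN")
  cross_time <- function(i_out, i_in) {
    # linear interpolation between the sample at/above Th and the one below
    t[i_out] + (threshold - v[i_out]) / (v[i_in] - v[i_out]) * (t[i_in] - t[i_out])
  }
  i <- ipk
  while (i > 1 && v[i - 1] < threshold) i <- i - 1
  if (i == 1) {
    onset <- t[1]; onset_clipped <- TRUE
  } else {
    onset <- cross_time(i - 1, i); onset_clipped <- FALSE
  }
  j <- ipk
  n <- length(v)
  while (j < n && v[j + 1] < threshold) j <- j + 1
  if (j == n) {
    offset <- t[n]; offset_clipped <- TRUE
  } else {
    offset <- cross_time(j + 1, j); offset_clipped <- FALSE
  }
  list(onset = onset, offset = offset,
       onset_clipped = onset_clipped, offset_clipped = offset_clipped)
}

#' Duration and area of the MMN excursion
#'
#' Duration is `offset - onset`. Area is the absolute trapezoidal integral
#' of the wave between onset and offset, with linearly interpolated
#' fractional segments at both ends; by default the integrand is the wave
#' itself (area to the 0 uV line), optionally the wave minus Th.
#'
#' @param wave an `mmn_wave`
#' @param onset,offset excursion bounds, ms
#' @param reference `"zero"` (default) or `"threshold"`
#' @param threshold Th in uV, required when `reference = "threshold"`
#' @return list with `duration` (ms) and `area` (uV*ms, >= 0)
#' @export
compute_duration_area <- function(wave, onset, offset,
                                  reference = c("zero", "threshold"),
                                  threshold = NULL) {
  wave <- as_wave(wave)
  reference <- match.arg(reference)
  if (offset < onset) stop("offset must not precede onset")
  v <- wave$samples
  if (reference == "threshold") {
    if (is.null(threshold)) stop("threshold required for reference='threshold'")
    v <- v - threshold
  }
  duration <- offset - onset
  if (duration == 0) return(list(duration = 0, area = 0))
  t <- wave$t_axis
  inside <- which(t > onset & t < offset)
  knots_t <- c(onset, t[inside], offset)
  v_on <- stats::approx(t, v, xout = onset)$y
  v_off <- stats::approx(t, v, xout = offset)$y
  knots_v <- c(v_on, v[inside], v_off)
  area <- abs(sum(diff(knots_t) * (utils::head(knots_v, -1) + utils::tail(knots_v, -1)) / 2))
  list(duration = duration, area = area)
}

#' Steepest slopes of the ascending and descending MMN sides
#'
#' Derivatives are estimated by central finite differences on the (already
#' low-passed) wave. The upslope is the largest derivative magnitude between
#' onset and peak among samples heading toward the negative peak
#' (dV/dt < 0); the downslope is the largest magnitude between peak and
#' offset among samples returning to baseline (dV/dt > 0). The sign
#' restriction stops residual noise wiggles of the wrong polarity from
#' defining a slope. Segments with fewer than 3 samples fall back to the
#' two-point average slope. Both values are reported as absolute magnitudes.
#'
#' @param wave an `mmn_wave`
#' @param onset,peak_latency,offset segment bounds, ms
#' @return list with `upslope` and `downslope`, uV/ms (>= 0)
#' @export
compute_slopes <- function(wave, onset, peak_latency, offset) {
  wave <- as_wave(wave)
  if (!(onset < peak_latency && peak_latency < offset))
    stop("require onset < peak_latency < offset")
  t <- wave$t_axis; v <- wave$samples
  n <- length(v)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  side_slope <- function(t_lo, t_hi, want_sign, v_lo, v_hi) {
    idx <- which(t >= t_lo & t <= t_hi & !is.na(d))
    cand <- idx[sign(d[idx]) == want_sign]
    if (length(idx) < 3 || length(cand) == 0)
      return(abs((v_hi - v_lo) / (t_hi - t_lo)))
    max(abs(d[cand]))
  }
  v_at <- function(tt) stats::approx(t, v, xout = tt)$y
  list(
    upslope = side_slope(onset, peak_latency, -1, v_at(onset), v_at(peak_latency)),
    downslope = side_slope(peak_latency, offset, 1, v_at(peak_latency), v_at(offset))
  )
}

#' Extract all nine MMN parameters from one difference wave
#'
#' Orchestrates the full extraction: threshold, fake-MMN validity test,
#' peak search, peak-window averaging, threshold-crossing onset/offset,
#' duration, area, and the two side slopes. Invalid (fake-MMN) waves return
#' `valid = FALSE` with all nine parameters missing, and are excluded from
#' downstream correlation analyses.
#'
#' @param wave an `mmn_wave`
#' @param config an [mmn_extraction_config()]
#' @return object of class `mmn_parameters`: a list with the nine parameters
#'   (`amplitude`, `ampavg`, `onset`, `offset`, `peak_latency`, `duration`,
#'   `area`, `upslope`, `downslope`), plus `threshold`, `valid`,
#'   `onset_clipped`, `offset_clipped`, `ampavg_clipped`, and the wave
#'   identifiers. `amplitude`/`ampavg` are stored signed (negative for a
#'   genuine MMN); absolute values are taken at the correlation stage.
#' @export
extract_all <- function(wave, config = mmn_extraction_config()) {
  wave <- as_wave(wave)
  id <- list(subject_id = wave$subject_id, isi_s = wave$isi_s,
             channel = wave$channel)
  th <- tryCatch(compute_threshold(wave, config$baseline_window),
                 error = function(e) stop(sprintf(
                   "threshold failed for subject %s, ISI %s, channel %s: %s",
                   format(id$subject_id), format(id$isi_s), id$channel,
                   conditionMessage(e))))
  if (!validate_mmn(wave, th, config$peak_window)) {
    pars <- stats::setNames(as.list(rep(NA_real_, length(MMN_PARAMETER_NAMES))),
                            MMN_PARAMETER_NAMES)
    return(structure(c(id, pars,
                       list(threshold = th, valid = FALSE,
                            onset_clipped = NA, offset_clipped = NA,
                            ampavg_clipped = NA)),
                     class = "mmn_parameters"))
  }
  pk <- find_peak(wave, config$peak_window)
  av <- compute_ampavg(wave, pk$peak_latency, config$ampavg_halfwidth)
  oo <- find_onset_offset(wave, th, pk$peak_latency)
  da <- compute_duration_area(wave, oo$onset, oo$offset,
                              reference = config$area_reference,
                              threshold = th)
  sl <- compute_slopes(wave, oo$onset, pk$peak_latency, oo$offset)
  structure(c(id, list(
    amplitude = pk$amplitude, ampavg = av$ampavg,
    onset = oo$onset, offset = oo$offset,
    peak_latency = pk$peak_latency,
    duration = da$duration, area = da$area,
    upslope = sl$upslope, downslope = sl$downslope,
    threshold = th, valid = TRUE,
    onset_clipped = oo$onset_clipped, offset_clipped = oo$offset_clipped,
    ampavg_clipped = av$clipped)),
    class = "mmn_parameters")
}

#' @export
print.mmn_parameters <- function(x, ...) {
  cat(sprintf("<mmn_parameters> subject %s, ISI %s, channel %s (valid: %s)\n",
              format(x$subject_id), format(x$isi_s), x$channel, x$valid))
  if (isTRUE(x$valid)) {
    for (p in MMN_PARAMETER_NAMES)
      cat(sprintf("  %-12s %10.4f\n", p, x[[p]]))
    cat(sprintf("  %-12s %10.4f\n", "threshold", x$threshold))
  }
  invisible(x)
}

#' @export
as.data.frame.mmn_parameters <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Extract parameters for every wave in a set
#'
#' @param waves an `mmn_wave_set`
#' @param config an [mmn_extraction_config()]
#' @return a `data.table`, one row per wave, with identifiers, the nine
#'   parameters, threshold, validity and edge flags
#' @export
extract_parameters <- function(waves, config = mmn_extraction_config()) {
  stopifnot(inherits(waves, "mmn_wave_set"))
  if (nrow(waves$meta) == 0) {
    empty <- c(list(subject_id = integer(0), isi_s = numeric(0),
                    channel = character(0)),
               stats::setNames(rep(list(numeric(0)),
                                   length(MMN_PARAMETER_NAMES)),
                               MMN_PARAMETER_NAMES),
               list(threshold = numeric(0), valid = logical(0),
                    onset_clipped = logical(0), offset_clipped = logical(0),
                    ampavg_clipped = logical(0)))
    return(data.table::as.data.table(empty))
  }
  rows <- lapply(seq_len(nrow(waves$meta)), function(i)
    as.data.frame(extract_all(wave_at(waves, i), config)))
  data.table::rbindlist(rows)
}
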