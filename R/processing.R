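#' Baseline-correct an epoch or wave
#'
#' Subtracts the mean voltage over the pre-stimulus baseline window, so the
#' corrected wave averages to zero over that window by construction.
#' Windows are half-open `[start, end)` on the sample grid.
#'
#' @param samples voltage samples, uV (vector, or matrix with one column per
#'   trial and one row per sample)
#' @param t_axis sample times, ms
#' @param window baseline interval `c(start, end)` in ms (default -200..0)
#' @return corrected samples, same shape as input
#' @export
baseline_correct <- function(samples, t_axis = mmn_time_axis(),
                             window = c(-200, 0)) {
  idx <- which(t_axis >= window[1] & t_axis < window[2])
  if (length(idx) == 0)
    stop("baseline window contains no samples")
  if (is.matrix(samples)) {
    stopifnot(nrow(samples) == length(t_axis))
    sweep(samples, 2, colMeans(samples[idx, , drop = FALSE]))
  } else {
    stopifnot(length(samples) == length(t_axis))
    samples - mean(samples[idx])
  }
}

#' Averaged deviant-minus-standard difference wave for one cell
#'
#' Implements the per-participant preprocessing chain: baseline-correct every
#' epoch, average epochs within condition, subtract the standard average from
#' the deviant average, then low-pass the difference at 25 Hz (zero-phase).
#' Filtering the averaged wave rather than single trials is mathematically
#' equivalent for a linear zero-phase filter and much cheaper.
#'
#' @param epochs an `epoch_set` from [synthesize_epochs()]
#' @param subject,isi,electrode cell selector
#' @param baseline_window baseline interval, ms
#' @param filter apply the 25 Hz low-pass (default TRUE)
#' @return an `mmn_wave`
#' @export
average_difference <- function(epochs, subject, isi, electrode,
                               baseline_window = c(-200, 0), filter = TRUE) {
  sel <- function(cond) {
    i <- which(epochs$cells$subject_id == subject &
               epochs$cells$isi_s == isi &
               epochs$cells$electrode == electrode &
               epochs$cells$condition == cond)
    if (length(i) != 1)
      stop(sprintf("missing %s epochs for subject %s, ISI %s, electrode %s",
                   cond, format(subject), format(isi), electrode))
    epochs$epochs[[i]]
  }
  dev <- sel("deviant"); std <- sel("standard")
  if (ncol(dev) < 2 || ncol(std) < 2)
    stop("need at least 2 epochs per condition for averaging")
  dev <- baseline_correct(dev, epochs$t_axis, baseline_window)
  std <- baseline_correct(std, epochs$t_axis, baseline_window)
  d <- rowMeans(dev) - rowMeans(std)
  if (filter) d <- lowpass_25hz(d, epochs$sampling_rate)
  mmn_wave(d, epochs$t_axis, subject, isi, electrode)
}

#' Difference waves for every cell of an epoch set
#'
#' @inheritParams average_difference
#' @return an `mmn_wave_set` with one wave per subject x ISI x electrode
#' @export
difference_waves <- function(epochs, baseline_window = c(-200, 0),
                             filter = TRUE) {
  cells <- unique(epochs$cells[, .(subject_id, isi_s, electrode)])
  samples <- matrix(NA_real_, nrow(cells), length(epochs$t_axis))
  for (i in seq_len(nrow(cells))) {
    w <- average_difference(epochs, cells$subject_id[i], cells$isi_s[i],
                            cells$electrode[i], baseline_window, filter)
    samples[i, ] <- w$samples
  }
  mmn_wave_set(cells[, .(subject_id, isi_s, channel = electrode)],
               samples, epochs$t_axis)
}

#' Region-of-interest averaged waves
#'
#' Sample-wise unweighted mean of each region's electrode waves, computed per
#' subject and ISI. ROI averaging precedes parameter extraction so that the
#' extracted parameters describe the regional mean wave, not a mean of
#' per-electrode parameters.
#'
#' @param waves an `mmn_wave_set` of electrode-level difference waves
#' @param regions named list mapping region name to electrode labels
#'   (default [MMN_ROIS])
#' @return an `mmn_wave_set` with one wave per subject x ISI x region
#' @export
roi_average <- function(waves, regions = MMN_ROIS) {
  stopifnot(inherits(waves, "mmn_wave_set"))
  if (length(regions) == 0) {
    return(mmn_wave_set(
      data.table::data.table(subject_id = integer(0), isi_s = numeric(0),
                             channel = character(0)),
      matrix(numeric(0), 0, length(waves$t_axis)), waves$t_axis))
  }
  have <- unique(waves$meta$channel)
  missing <- setdiff(unique(unlist(regions)), have)
  if (length(missing) > 0)
    stop("unknown electrode label(s) in ROI map: ",
         paste(missing, collapse = ", "))
  keys <- unique(waves$meta[, .(subject_id, isi_s)])
  out_meta <- list(); out_samp <- list()
  for (i in seq_len(nrow(keys))) {
    for (rg in names(regions)) {
      idx <- which(waves$meta$subject_id == keys$subject_id[i] &
                   waves$meta$isi_s == keys$isi_s[i] &
                   waves$meta$channel %in% regions[[rg]])
      if (length(idx) != length(regions[[rg]]))
        stop(sprintf("region %s: expected %d electrode waves, found %d (subject %s, ISI %s)",
                     rg, length(regions[[rg]]), length(idx),
                     format(keys$subject_id[i]), format(keys$isi_s[i])))
      out_meta[[length(out_meta) + 1L]] <- data.table::data.table(
        subject_id = keys$subject_id[i], isi_s = keys$isi_s[i], channel = rg)
      out_samp[[length(out_samp) + 1L]] <-
        colMeans(waves$samples[idx, , drop = FALSE])
    }
  }
  mmn_wave_set(data.table::rbindlist(out_meta), do.call(rbind, out_samp),
               waves$t_axis)
}
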