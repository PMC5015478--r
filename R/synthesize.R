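#' Noise settings for epoch synthesis
#'
#' @param sd additive Gaussian noise SD per sample per trial, uV (default 8,
#'   a typical single-trial EEG residual after preprocessing)
#' @param pink weight of an optional 1/f ("pink") noise component, as a
#'   fraction of `sd` (0 disables it; default 0). When enabled, the total
#'   per-sample SD is still `sd`, split between white and pink parts.
#' @return a named list
#' @export
mmn_noise <- function(sd = 8, pink = 0) {
  stopifnot(sd >= 0, pink >= 0, pink <= 1)
  list(sd = sd, pink = pink)
}

# One matrix of noise trials (n_time x n_trials). Pink noise is built by
# shaping white Gaussian spectra with 1/sqrt(f) and renormalizing to unit SD.
noise_matrix <- function(n_time, n_trials, noise) {
  if (noise$sd == 0) return(matrix(0, n_time, n_trials))
  w <- matrix(stats::rnorm(n_time * n_trials), n_time, n_trials)
  if (noise$pink > 0) {
    pk <- matrix(stats::rnorm(n_time * n_trials), n_time, n_trials)
    f <- c(1, seq_len(n_time - 1))          # pseudo-frequency index, avoid 0
    shape <- 1 / sqrt(pmin(f, n_time - f + 1))
    pk <- apply(pk, 2, function(col) {
      sp <- stats::fft(col) * shape
      Re(stats::fft(sp, inverse = TRUE)) / n_time
    })
    pk <- pk / stats::sd(as.vector(pk))
    w <- sqrt(1 - noise$pink^2) * w + noise$pink * pk
  }
  noise$sd * w
}

#' Synthesize epoched EEG for an oddball cohort
#'
#' Builds per-trial epochs for every subject x ISI x electrode cell of the
#' ground-truth table. The standard-tone response is a shared obligatory ERP
#' template; the deviant-tone response adds the subject's MMN component at
#' its effective (topography-scaled) amplitude. i.i.d. Gaussian noise of
#' `noise$sd` uV is added per sample per trial.
#'
#' Trial counts per condition are taken from `sequences` when given (summing
#' label counts over the blocks of each ISI), otherwise from `n_trials`.
#'
#' @param truth ground-truth table from [draw_ground_truth()]
#' @param sequences optional list of `oddball_sequence` blocks; their `isi_s`
#'   metadata must cover the ISIs in `truth`
#' @param n_trials list with elements `deviant` and `standard` (per-ISI trial
#'   counts) used when `sequences` is NULL; default 60 / 240 (two 150-stimulus
#'   blocks per ISI)
#' @param noise settings from [mmn_noise()]
#' @param seed integer RNG seed for the trial-noise stream (independent of
#'   the truth stream)
#' @param t_axis sample times, ms
#' @param shape MMN component shape, see [mmn_component()]
#' @return object of class `epoch_set`: list with `t_axis`, `sampling_rate`,
#'   `cells` (a `data.table` of subject_id, isi_s, condition, electrode,
#'   n_trials) and `epochs` (list of n_time x n_trials matrices, parallel to
#'   `cells`)
#' @export
synthesize_epochs <- function(truth, sequences = NULL,
                              n_trials = list(deviant = 60, standard = 240),
                              noise = mmn_noise(), seed = 1L,
                              t_axis = mmn_time_axis(), shape = "cosine") {
  isis <- sort(unique(truth$isi_s))
  counts <- trial_counts(sequences, n_trials, isis)
  if (any(unlist(counts) < 2))
    stop("need at least 2 trials per condition for averaging")
  template <- erp_template(t_axis)
  cell_list <- vector("list", 0)
  epochs <- vector("list", 0)
  keys <- unique(truth[, .(subject_id, isi_s)])
  with_seed(seed, {
    for (r in seq_len(nrow(keys))) {
      s <- keys$subject_id[r]; isi <- keys$isi_s[r]
      rows <- truth[subject_id == s & isi_s == isi]
      n_dev <- counts[[isi_key(isi)]][["deviant"]]
      n_std <- counts[[isi_key(isi)]][["standard"]]
      for (j in seq_len(nrow(rows))) {
        comp <- mmn_component(rows$A[j], rows$t_on[j], rows$t_pk[j],
                              rows$t_off[j], t_axis, shape = shape)
        std <- template + noise_matrix(length(t_axis), n_std, noise)
        dev <- template + comp + noise_matrix(length(t_axis), n_dev, noise)
        cell_list[[length(cell_list) + 1L]] <- data.table::data.table(
          subject_id = s, isi_s = isi,
          condition = c("standard", "deviant"),
          electrode = rows$electrode[j],
          n_trials = as.integer(c(n_std, n_dev)))
        epochs[[length(epochs) + 1L]] <- std
        epochs[[length(epochs) + 1L]] <- dev
      }
    }
  })
  cells <- data.table::rbindlist(cell_list)
  structure(list(t_axis = as.numeric(t_axis),
                 sampling_rate = 1000 / diff(t_axis[1:2]),
                 cells = cells, epochs = epochs),
            class = "epoch_set")
}

isi_key <- function(x) sprintf("%g", x)

trial_counts <- function(sequences, n_trials, isis) {
  if (!is.null(sequences)) {
    cnt <- lapply(isi_key(isis), function(k) c(deviant = 0L, standard = 0L))
    names(cnt) <- isi_key(isis)
    for (b in sequences) {
      k <- isi_key(b$isi_s)
      if (!k %in% names(cnt)) next
      cnt[[k]]["deviant"] <- cnt[[k]]["deviant"] + sum(b$labels == "deviant")
      cnt[[k]]["standard"] <- cnt[[k]]["standard"] + sum(b$labels == "standard")
    }
    lapply(cnt, as.list)
  } else {
    cnt <- lapply(isi_key(isis), function(k) n_trials)
    stats::setNames(cnt, isi_key(isis))
  }
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d cells, %d samples/epoch at %g Hz, %d epochs total\n",
              nrow(x$cells), length(x$t_axis), x$sampling_rate,
              sum(x$cells$n_trials)))
  invisible(x)
}

#' Synthesize averaged difference waves directly (summary mode)
#'
#' Distributionally equivalent shortcut to trial-level synthesis followed by
#' condition averaging and subtraction: the averaged deviant-minus-standard
#' difference of `n_dev` + `n_std` i.i.d.-noise trials equals the MMN
#' component plus Gaussian noise of SD `noise$sd * sqrt(1/n_dev + 1/n_std)`
#' per sample. Used by simulation-heavy calibration tests; the trial-level
#' path is exercised (and checked against this identity) separately.
#'
#' Waves are baseline-corrected and low-pass filtered exactly as in the
#' trial-level pipeline.
#'
#' @inheritParams synthesize_epochs
#' @param n_dev,n_std trial counts entering the two condition averages
#' @param filter apply the 25 Hz zero-phase low-pass (default TRUE)
#' @param baseline_window baseline interval, ms (half-open)
#' @return an `mmn_wave_set` of difference waves, one per truth row
#' @export
synthesize_average_waves <- function(truth, n_dev = 60, n_std = 240,
                                     noise = mmn_noise(), seed = 1L,
                                     t_axis = mmn_time_axis(),
                                     shape = "cosine", filter = TRUE,
                                     baseline_window = c(-200, 0)) {
  stopifnot(n_dev >= 2, n_std >= 2)
  sd_eff <- noise$sd * sqrt(1 / n_dev + 1 / n_std)
  n_time <- length(t_axis)
  fs <- 1000 / diff(t_axis[1:2])
  samples <- with_seed(seed, {
    m <- matrix(NA_real_, nrow(truth), n_time)
    for (i in seq_len(nrow(truth))) {
      comp <- mmn_component(truth$A[i], truth$t_on[i], truth$t_pk[i],
                            truth$t_off[i], t_axis, shape = shape)
      m[i, ] <- comp + stats::rnorm(n_time, 0, sd_eff)
    }
    m
  })
  for (i in seq_len(nrow(samples))) {
    w <- baseline_correct(samples[i, ], t_axis, baseline_window)
    if (filter) w <- lowpass_25hz(w, fs)
    samples[i, ] <- w
  }
  mmn_wave_set(truth[, .(subject_id, isi_s, channel = electrode)],
               samples, t_axis)
}
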