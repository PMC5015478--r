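#' Default generator hyperparameters
#'
#' Distribution settings for the subject-level MMN ground truth. Values are
#' chosen to mimic a typical frequency-deviant MMN cohort: peak magnitudes a
#' few microvolts (lognormal, median 3 uV), peak latencies near 170 ms,
#' rise rates drawn independently of amplitude in both coupling modes, and a
#' fronto-central topography with attenuated temporal sites.
#'
#' @param amp_median median true peak magnitude A, uV (> 0)
#' @param amp_sdlog lognormal sd of A on the log scale
#' @param amp_range truncation bounds for A, uV
#' @param lat_mean,lat_sd normal peak-latency distribution, ms
#' @param lat_range truncation bounds for peak latency, ms
#' @param rise_rate_median,rise_rate_sdlog lognormal average rise rate
#'   A / (t_pk - t_on), uV/ms, drawn independently of A
#' @param rise_dur_range admissible rise durations t_pk - t_on, ms
#' @param t_ret fixed return window t_off - t_pk in rubberband mode, ms
#' @param descent_rate_median,descent_rate_sdlog lognormal average descent
#'   rate in null mode, uV/ms, drawn independently of A
#' @param descent_dur_range admissible descent durations in null mode, ms
#' @param topography named per-electrode scale weights
#' @param isi_mod named per-ISI amplitude modulation (default: none)
#' @param t_off_max latest admissible return-to-baseline time, ms
#' @return a named list of hyperparameters
#' @export
mmn_hyperparams <- function(amp_median = 3, amp_sdlog = 0.35,
                            amp_range = c(1, 7.5),
                            lat_mean = 170, lat_sd = 15,
                            lat_range = c(100, 300),
                            rise_rate_median = 0.04, rise_rate_sdlog = 0.15,
                            rise_dur_range = c(30, 160),
                            t_ret = 120,
                            descent_rate_median = 0.025,
                            descent_rate_sdlog = 0.3,
                            descent_dur_range = c(20, NA),
                            topography = NULL,
                            isi_mod = NULL,
                            t_off_max = 780) {
  if (is.null(topography)) {
    topography <- stats::setNames(rep(1, length(MMN_ELECTRODES)), MMN_ELECTRODES)
    topography[c("FT7", "FT8", "T7", "T8")] <- 0.4
  }
  if (is.null(isi_mod)) isi_mod <- stats::setNames(rep(1, length(MMN_ISIS)),
                                                   sprintf("%g", MMN_ISIS))
  hp <- list(amp_median = amp_median, amp_sdlog = amp_sdlog,
             amp_range = amp_range, lat_mean = lat_mean, lat_sd = lat_sd,
             lat_range = lat_range, rise_rate_median = rise_rate_median,
             rise_rate_sdlog = rise_rate_sdlog,
             rise_dur_range = rise_dur_range, t_ret = t_ret,
             descent_rate_median = descent_rate_median,
             descent_rate_sdlog = descent_rate_sdlog,
             descent_dur_range = descent_dur_range,
             topography = topography, isi_mod = isi_mod,
             t_off_max = t_off_max)
  validate_hyperparams(hp)
  hp
}

validate_hyperparams <- function(hp) {
  if (!is.finite(hp$amp_median) || hp$amp_median <= 0)
    stop("amp_median must be positive")
  if (hp$t_ret <= 0) stop("t_ret (return window) must be positive")
  if (hp$descent_rate_median <= 0) stop("descent_rate_median must be positive")
  if (hp$rise_rate_median <= 0) stop("rise_rate_median must be positive")
  if (any(hp$topography <= 0)) stop("topography weights must be positive")
  invisible(TRUE)
}

# Rejection-sample one value from `rfun()` until `ok(x)`; hard iteration cap.
draw_until <- function(rfun, ok, max_iter = 1000) {
  for (i in seq_len(max_iter)) {
    x <- rfun()
    if (ok(x)) return(x)
  }
  stop("could not draw a ground-truth value satisfying the constraints")
}

#' Draw ground-truth MMN parameters for a synthetic cohort
#'
#' Draws subject-level true MMN morphology (peak magnitude A, peak latency,
#' rise dynamics, return dynamics) and expands it over electrodes and ISI
#' conditions via multiplicative topography / ISI weights. Two coupling modes
#' encode the competing hypotheses about the return to baseline:
#'
#' * `"rubberband"`: the return window `t_off - t_pk` is a fixed `t_ret` for
#'   every subject, so the average descent rate `A / t_ret` is proportional
#'   to the amplitude (the stronger the deflection, the faster the return).
#' * `"null"`: the average descent rate is drawn independently of A (shared
#'   attenuation dynamics regardless of peak size), so the return time
#'   `t_off - t_pk = A / rate` varies with A instead.
#'
#' In both modes the rise rate is drawn independently of A, so the rise
#' duration scales with A and the upslope carries no amplitude information.
#'
#' @param mode `"rubberband"` or `"null"`
#' @param n_subjects number of subjects (default 22)
#' @param hyperparams settings from [mmn_hyperparams()]
#' @param seed integer RNG seed (subject-level truth stream)
#' @param electrodes electrode labels (must be named in the topography)
#' @param isis ISI conditions, seconds
#' @return a `data.table` with one row per subject x ISI x electrode:
#'   `subject_id, isi_s, electrode, A, t_on, t_pk, t_off, rise_rate,
#'   descent_rate, topography_weight`. `A` is the effective (topography- and
#'   ISI-scaled) peak magnitude at that electrode; rates are average rates
#'   `A / segment duration` in uV/ms. The hyperparameters and mode are
#'   attached as attributes.
#' @export
draw_ground_truth <- function(mode = c("rubberband", "null"),
                              n_subjects = 22,
                              hyperparams = mmn_hyperparams(),
                              seed = 1L,
                              electrodes = MMN_ELECTRODES,
                              isis = MMN_ISIS) {
  mode <- match.arg(mode)
  hp <- hyperparams
  validate_hyperparams(hp)
  if (!all(electrodes %in% names(hp$topography)))
    stop("missing topography weight for: ",
         paste(setdiff(electrodes, names(hp$topography)), collapse = ", "))
  stopifnot(n_subjects >= 1)

  # mode-independent draws first, on their own stream, so rubberband and
  # null cohorts with the same seed share subjects (A, latency, rise)
  core <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      t_pk <- draw_until(
        function() stats::rnorm(1, hp$lat_mean, hp$lat_sd),
        function(x) x >= hp$lat_range[1] && x <= hp$lat_range[2])
      A <- draw_until(
        function() stats::rlnorm(1, log(hp$amp_median), hp$amp_sdlog),
        function(x) x >= hp$amp_range[1] && x <= hp$amp_range[2])
      rise_lo <- hp$rise_dur_range[1]
      rise_hi <- if (is.na(hp$rise_dur_range[2])) t_pk - 10 else hp$rise_dur_range[2]
      rise_rate <- draw_until(
        function() stats::rlnorm(1, log(hp$rise_rate_median), hp$rise_rate_sdlog),
        function(r) { d <- A / r; d >= rise_lo && d <= rise_hi })
      data.table::data.table(subject_id = s, A_subj = A,
                             t_on = t_pk - A / rise_rate, t_pk = t_pk,
                             rise_rate_subj = rise_rate)
    })
  })
  subj <- data.table::rbindlist(core)
  if (mode == "rubberband") {
    subj[, t_off := t_pk + hp$t_ret]
    if (any(subj$t_off > hp$t_off_max))
      stop("t_ret pushes t_off past t_off_max; shrink t_ret or lat_range")
    subj[, descent_rate_subj := A_subj / hp$t_ret]
  } else {
    descent <- with_seed(seed + 500009L, {
      vapply(seq_len(n_subjects), function(s) {
        dsc_lo <- hp$descent_dur_range[1]
        dsc_hi <- if (is.na(hp$descent_dur_range[2]))
                    hp$t_off_max - subj$t_pk[s]
                  else hp$descent_dur_range[2]
        draw_until(
          function() stats::rlnorm(1, log(hp$descent_rate_median),
                                   hp$descent_rate_sdlog),
          function(r) { d <- subj$A_subj[s] / r; d >= dsc_lo && d <= dsc_hi })
      }, numeric(1))
    })
    subj[, descent_rate_subj := descent]
    subj[, t_off := t_pk + A_subj / descent_rate_subj]
  }

  grid <- data.table::CJ(subject_id = seq_len(n_subjects), isi_s = isis,
                         electrode = electrodes, sorted = FALSE)
  out <- merge(grid, subj, by = "subject_id", sort = FALSE)
  w_elec <- hp$topography[out$electrode]
  w_isi <- hp$isi_mod[sprintf("%g", out$isi_s)]
  if (anyNA(w_isi)) stop("missing isi_mod weight for some ISI")
  scale <- as.numeric(w_elec) * as.numeric(w_isi)
  # voltage scaling leaves segment durations unchanged, so average rates
  # scale with the effective amplitude
  out[, `:=`(A = A_subj * scale,
             rise_rate = rise_rate_subj * scale,
             descent_rate = descent_rate_subj * scale,
             topography_weight = as.numeric(w_elec))]
  out[, c("A_subj", "rise_rate_subj", "descent_rate_subj") := NULL]
  data.table::setcolorder(out, c("subject_id", "isi_s", "electrode", "A",
                                 "t_on", "t_pk", "t_off", "rise_rate",
                                 "descent_rate", "topography_weight"))
  data.table::setattr(out, "mode", mode)
  data.table::setattr(out, "hyperparams", hp)
  data.table::setattr(out, "seed", seed)
  out[]
}
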