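#' Sample an idealized MMN component on a time axis
#'
#' A single negative deflection: zero outside `[t_on, t_off]`, minimum `-A`
#' at `t_pk`. The default shape joins two half-raised-cosine segments
#' (onset to peak, peak to offset), which is C1-smooth at the peak; the
#' `"linear"` shape uses straight ramps and has constant-slope sides, which
#' makes analytic slope/area checks exact.
#'
#' Closed-form maximum slope magnitudes: cosine shape `A * pi / (2 * dur)`
#' per side, linear shape `A / dur` per side, where `dur` is the side's
#' duration.
#'
#' @param A peak magnitude in uV (>= 0); the waveform minimum is `-A`
#' @param t_on,t_pk,t_off onset, peak, offset times in ms; `t_on < t_pk < t_off`
#' @param t_axis sample times in ms (see [mmn_time_axis()])
#' @param shape `"cosine"` (default) or `"linear"`
#' @return numeric vector of voltages (uV), same length as `t_axis`
#' @export
mmn_component <- function(A, t_on, t_pk, t_off, t_axis = mmn_time_axis(),
                          shape = c("cosine", "linear")) {
  shape <- match.arg(shape)
  stopifnot(A >= 0)
  if (!(t_on < t_pk && t_pk < t_off))
    stop("require t_on < t_pk < t_off")
  v <- numeric(length(t_axis))
  if (A == 0) return(v)
  up <- t_axis >= t_on & t_axis <= t_pk
  dn <- t_axis > t_pk & t_axis <= t_off
  if (shape == "cosine") {
    v[up] <- -A / 2 * (1 - cos(pi * (t_axis[up] - t_on) / (t_pk - t_on)))
    v[dn] <- -A / 2 * (1 + cos(pi * (t_axis[dn] - t_pk) / (t_off - t_pk)))
  } else {
    v[up] <- -A * (t_axis[up] - t_on) / (t_pk - t_on)
    v[dn] <- -A * (t_off - t_axis[dn]) / (t_off - t_pk)
  }
  v
}

#' Obligatory auditory ERP template
#'
#' A fixed stimulus-evoked response shared by standard and deviant tones
#' (an N1-like negativity near 100 ms followed by a P2-like positivity near
#' 200 ms, modeled as Gaussian bumps). It cancels exactly in the
#' deviant-minus-standard difference wave; it is included so that raw
#' synthetic epochs look like evoked responses rather than pure noise.
#'
#' @param t_axis sample times in ms
#' @param n1_amp,n1_lat,n1_sd N1 magnitude (uV), latency and width (ms)
#' @param p2_amp,p2_lat,p2_sd P2 magnitude (uV), latency and width (ms)
#' @return numeric vector of voltages (uV)
#' @export
erp_template <- function(t_axis = mmn_time_axis(),
                         n1_amp = 1.5, n1_lat = 100, n1_sd = 20,
                         p2_amp = 1.0, p2_lat = 200, p2_sd = 35) {
  on <- t_axis >= 0
  v <- numeric(length(t_axis))
  v[on] <- -n1_amp * exp(-((t_axis[on] - n1_lat) / n1_sd)^2 / 2) +
            p2_amp * exp(-((t_axis[on] - p2_lat) / p2_sd)^2 / 2)
  v
}
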