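# Independent brute-force reference extraction: exhaustive scans and dense
# linear interpolation instead of the package's algebraic crossing solver.
# Deliberately written from the parameter definitions, not from the
# implementation.

oracle_sd <- function(x) {
  # two-pass sample SD
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_extract <- function(samples, t_axis,
                           peak_window = c(100, 300),
                           baseline_window = c(-200, 0),
                           half_width = 20, step = 0.01) {
  bidx <- which(t_axis >= baseline_window[1] & t_axis < baseline_window[2])
  th <- sum(samples[bidx]) / length(bidx) - oracle_sd(samples[bidx])
  widx <- which(t_axis >= peak_window[1] & t_axis < peak_window[2])
  valid <- min(samples[widx]) < th
  if (!valid) return(list(threshold = th, valid = FALSE))

  # exhaustive earliest-argmin peak scan
  best <- Inf; ipk <- NA
  for (i in widx) if (samples[i] < best) { best <- samples[i]; ipk <- i }
  pk_t <- t_axis[ipk]; pk_v <- samples[ipk]

  aidx <- which(t_axis >= pk_t - half_width - 1e-9 &
                t_axis <= pk_t + half_width + 1e-9)
  ampavg <- mean(samples[aidx])

  # dense scan for threshold crossings of the peak's excursion
  tf <- seq(t_axis[1], t_axis[length(t_axis)], by = step)
  vf <- stats::approx(t_axis, samples, xout = tf)$y
  kpk <- which.min(abs(tf - pk_t))
  k <- kpk
  while (k > 1 && vf[k - 1] < th) k <- k - 1
  onset <- if (k == 1) tf[1] else tf[k] - step / 2
  onset_clipped <- (k == 1)
  k <- kpk
  while (k < length(tf) && vf[k + 1] < th) k <- k + 1
  offset <- if (k == length(tf)) tf[length(tf)] else tf[k] + step / 2
  offset_clipped <- (k == length(tf))

  seg <- tf >= onset & tf <= offset
  area <- abs(sum(vf[seg]) * step)
  duration <- offset - onset

  # central differences, sign-restricted maxima, two-point fallback
  n <- length(samples)
  d <- rep(NA_real_, n)
  for (i in 2:(n - 1)) d[i] <- (samples[i + 1] - samples[i - 1]) /
                               (t_axis[i + 1] - t_axis[i - 1])
  slope_of <- function(lo, hi, want) {
    idx <- which(t_axis >= lo & t_axis <= hi & !is.na(d))
    cand <- idx[!is.na(d[idx]) & sign(d[idx]) == want]
    if (length(idx) < 3 || length(cand) == 0) {
      vlo <- stats::approx(t_axis, samples, xout = lo)$y
      vhi <- stats::approx(t_axis, samples, xout = hi)$y
      return(abs((vhi - vlo) / (hi - lo)))
    }
    mx <- 0
    for (i in cand) mx <- max(mx, abs(d[i]))
    mx
  }
  list(threshold = th, valid = TRUE, amplitude = pk_v, ampavg = ampavg,
       peak_latency = pk_t, onset = onset, offset = offset,
       onset_clipped = onset_clipped, offset_clipped = offset_clipped,
       duration = duration, area = area,
       upslope = slope_of(onset, pk_t, -1),
       downslope = slope_of(pk_t, offset, 1))
}

# average-rank Pearson Spearman oracle (manual ranking by sorting)
oracle_spearman <- function(x, y) {
  manual_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- manual_rank(x); ry <- manual_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
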