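#' Construct a single MMN difference wave
#'
#' @param samples numeric voltage samples, uV
#' @param t_axis sample times, ms
#' @param subject_id,isi_s,channel identifying metadata; `channel` is an
#'   electrode label or ROI name
#' @return object of class `mmn_wave`
#' @export
mmn_wave <- function(samples, t_axis = mmn_time_axis(),
                     subject_id = NA, isi_s = NA_real_, channel = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) == length(t_axis))
  structure(list(subject_id = subject_id, isi_s = isi_s, channel = channel,
                 t_axis = as.numeric(t_axis), samples = as.numeric(samples)),
            class = "mmn_wave")
}

#' @export
print.mmn_wave <- function(x, ...) {
  cat(sprintf("<mmn_wave> subject %s, ISI %s s, channel %s: %d samples [%g, %g] ms\n",
              format(x$subject_id), format(x$isi_s), x$channel,
              length(x$samples), min(x$t_axis), max(x$t_axis)))
  invisible(x)
}

#' Construct a set of MMN waves sharing one time axis
#'
#' @param meta `data.table` with columns `subject_id`, `isi_s`, `channel`,
#'   one row per wave
#' @param samples numeric matrix, one row per wave, one column per sample
#' @param t_axis shared sample times, ms
#' @return object of class `mmn_wave_set`
#' @export
mmn_wave_set <- function(meta, samples, t_axis = mmn_time_axis()) {
  meta <- data.table::as.data.table(meta)
  stopifnot(nrow(meta) == nrow(samples), ncol(samples) == length(t_axis),
            all(c("subject_id", "isi_s", "channel") %in% names(meta)))
  structure(list(meta = meta, samples = samples, t_axis = as.numeric(t_axis)),
            class = "mmn_wave_set")
}

#' @export
print.mmn_wave_set <- function(x, ...) {
  cat(sprintf("<mmn_wave_set> %d waves x %d samples; %d subjects, %d channels, %d ISIs\n",
              nrow(x$samples), ncol(x$samples),
              length(unique(x$meta$subject_id)),
              length(unique(x$meta$channel)),
              length(unique(x$meta$isi_s))))
  invisible(x)
}

#' Extract one wave from a wave set
#' @param x an `mmn_wave_set`
#' @param i row index into `x$meta`
#' @return an `mmn_wave`
#' @export
wave_at <- function(x, i) {
  stopifnot(inherits(x, "mmn_wave_set"), i >= 1, i <= nrow(x$meta))
  m <- x$meta[i]
  mmn_wave(x$samples[i, ], x$t_axis, m$subject_id, m$isi_s, m$channel)
}

#' Bind wave sets that share a time axis
#' @param ... `mmn_wave_set` objects
#' @return a single `mmn_wave_set`
#' @export
bind_wave_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "mmn_wave_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  t_axis <- sets[[1]]$t_axis
  for (s in sets) stopifnot(identical(s$t_axis, t_axis))
  mmn_wave_set(data.table::rbindlist(lapply(sets, `[[`, "meta")),
               do.call(rbind, lapply(sets, `[[`, "samples")), t_axis)
}
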