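# Shared fixtures: waves are always built in code, never stored.

TAX <- mmn_time_axis()

component_wave <- function(A, t_on, t_pk, t_off, shape = "cosine",
                           noise = NULL, ...) {
  v <- mmn_component(A, t_on, t_pk, t_off, TAX, shape = shape)
  if (!is.null(noise)) v <- v + noise
  mmn_wave(v, TAX, ...)
}

# smooth band-limited noise resembling a filtered averaged-EEG residual
smooth_noise <- function(sd_raw = 1, t_axis = TAX) {
  lowpass_25hz(stats::rnorm(length(t_axis), 0, sd_raw), 500)
}

random_component_args <- function() {
  A <- stats::runif(1, 0.5, 6)
  t_pk <- stats::runif(1, 120, 260)
  rise <- stats::runif(1, 24, 100)
  descent <- stats::runif(1, 30, 200)
  list(A = A, t_on = t_pk - rise, t_pk = t_pk, t_off = t_pk + descent,
       shape = sample(c("cosine", "linear"), 1))
}

# small cohort configs used across files
tiny_config <- function(seed = 1, n_subjects = 6, ...) {
  mmn_config(seed = seed, n_subjects = n_subjects,
             electrodes = c("FZ", "F1", "FCZ", "T7"),
             isis = c(1.5, 3),
             rois = list(frontal = c("FZ", "F1")),
             n_stimuli = 50, n_lead = 3,
             ...)
}
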