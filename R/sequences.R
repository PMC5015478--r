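#' Generate a constrained oddball stimulus sequence
#'
#' Produces one block of an auditory oddball sequence: `n_stimuli` tones of
#' which exactly `round(deviant_prob * n_stimuli)` are deviants, under two
#' constraints taken from standard passive-oddball designs: consecutive
#' deviants are separated by at least `min_sep` standards, and the first
#' `n_lead` stimuli are all standards (to establish the standard as such).
#'
#' Deviant positions are drawn uniformly at random among all placements that
#' satisfy the constraints, via the classic gap bijection: positions
#' `p_1 < ... < p_k` with `p_1 > n_lead` and `p_(i+1) - p_i > min_sep` are in
#' one-to-one correspondence with unconstrained combinations of k slots out of
#' `n_stimuli - n_lead - (k-1) * min_sep`.
#'
#' @param n_stimuli number of stimuli in the block (default 150)
#' @param deviant_prob probability mass of deviants; the deviant count is
#'   exact, `round(deviant_prob * n_stimuli)`, not Bernoulli (default 0.2)
#' @param min_sep minimum number of standards between two deviants (default 2)
#' @param n_lead number of leading stimuli forced to be standards (default 5)
#' @param seed integer RNG seed
#' @param block_id identifier stored with the block
#' @param isi_s inter-stimulus interval metadata, seconds
#' @return an object of class `oddball_sequence`: list with `block_id`,
#'   `isi_s`, and `labels` (character vector of "standard"/"deviant")
#' @examples
#' s <- generate_stimulus_sequence(150, 0.2, seed = 1)
#' table(s$labels)
#' @export
generate_stimulus_sequence <- function(n_stimuli = 150, deviant_prob = 0.2,
                                       min_sep = 2, n_lead = 5, seed = NULL,
                                       block_id = 1L, isi_s = NA_real_) {
  stopifnot(n_stimuli >= 1, deviant_prob >= 0, deviant_prob <= 1,
            min_sep >= 0, n_lead >= 0)
  k <- round(deviant_prob * n_stimuli)
  labels <- rep("standard", n_stimuli)
  if (k > 0) {
    # free slots once lead-in and inter-deviant gaps are reserved
    m <- n_stimuli - n_lead - (k - 1L) * min_sep
    if (m < k) {
      stop(sprintf(
        "infeasible oddball sequence: %d deviants cannot be placed in %d stimuli with min_sep=%d, n_lead=%d",
        k, n_stimuli, min_sep, n_lead))
    }
    draw <- function() {
      q <- sort(sample.int(m, k))
      n_lead + q + (seq_len(k) - 1L) * min_sep
    }
    pos <- if (is.null(seed)) draw() else with_seed(seed, draw())
    labels[pos] <- "deviant"
  }
  structure(list(block_id = block_id, isi_s = isi_s, labels = labels),
            class = "oddball_sequence")
}

#' @export
print.oddball_sequence <- function(x, ...) {
  cat(sprintf("<oddball_sequence> block %s, ISI %s s: %d stimuli (%d deviant)\n",
              x$block_id, format(x$isi_s), length(x$labels),
              sum(x$labels == "deviant")))
  invisible(x)
}

#' Check the design constraints of an oddball sequence
#'
#' @param seq_obj an `oddball_sequence`
#' @param min_sep,n_lead constraints to check against
#' @return TRUE if the deviant count positions respect the separation and
#'   lead-in constraints
#' @export
validate_sequence <- function(seq_obj, min_sep = 2, n_lead = 5) {
  pos <- which(seq_obj$labels == "deviant")
  if (length(pos) == 0) return(TRUE)
  all(pos > n_lead) && (length(pos) < 2 || all(diff(pos) > min_sep))
}
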