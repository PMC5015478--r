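#' Write an epoch set as a long-format CSV with a JSON sidecar
#'
#' The CSV has one row per sample: `subject_id, isi_s, condition, electrode,
#' trial, time_ms, amplitude_uv`. The sidecar records the sampling rate,
#' epoch window, electrode labels, generator provenance and (optionally) the
#' ground-truth table, so parameter-recovery checks can be run from files
#' alone. Note the long format is verbose; it is intended for modest subsets,
#' not full cohorts.
#'
#' @param epochs an `epoch_set`
#' @param csv_path output CSV path
#' @param sidecar_path output JSON path (default: CSV path with .json)
#' @param truth optional ground-truth table to embed
#' @param provenance optional named list (mode, seed, ...) to embed
#' @return invisibly, the two paths
#' @export
write_epochs_csv <- function(epochs, csv_path,
                             sidecar_path = sub("\\.csv$", ".json", csv_path),
                             truth = NULL, provenance = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  rows <- lapply(seq_len(nrow(epochs$cells)), function(i) {
    cell <- epochs$cells[i]
    m <- epochs$epochs[[i]]
    data.table::data.table(
      subject_id = cell$subject_id, isi_s = cell$isi_s,
      condition = cell$condition, electrode = cell$electrode,
      trial = rep(seq_len(ncol(m)), each = nrow(m)),
      time_ms = rep(epochs$t_axis, ncol(m)),
      amplitude_uv = as.vector(m))
  })
  data.table::fwrite(data.table::rbindlist(rows), csv_path)
  side <- list(
    sampling_rate_hz = epochs$sampling_rate,
    epoch_window_ms = c(epochs$t_axis[1],
                        epochs$t_axis[length(epochs$t_axis)] +
                          diff(epochs$t_axis[1:2])),
    electrodes = unique(epochs$cells$electrode),
    provenance = provenance,
    ground_truth = if (!is.null(truth)) as.data.frame(truth) else NULL)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv_path, sidecar = sidecar_path))
}

#' Read an epoch set from a long-format CSV
#'
#' Inverse of [write_epochs_csv()].
#'
#' @param csv_path CSV path
#' @return an `epoch_set`
#' @export
read_epochs_csv <- function(csv_path) {
  long <- data.table::fread(csv_path)
  need <- c("subject_id", "isi_s", "condition", "electrode", "trial",
            "time_ms", "amplitude_uv")
  if (!all(need %in% names(long)))
    stop("epoch CSV must have columns: ", paste(need, collapse = ", "))
  t_axis <- sort(unique(long$time_ms))
  cells <- unique(long[, .(subject_id, isi_s, condition, electrode)])
  epochs <- vector("list", nrow(cells))
  n_trials <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- long[subject_id == cells$subject_id[i] & isi_s == cells$isi_s[i] &
                condition == cells$condition[i] &
                electrode == cells$electrode[i]]
    data.table::setorder(sub, trial, time_ms)
    k <- length(unique(sub$trial))
    epochs[[i]] <- matrix(sub$amplitude_uv, nrow = length(t_axis), ncol = k)
    n_trials[i] <- k
  }
  cells[, n_trials := n_trials]
  structure(list(t_axis = t_axis,
                 sampling_rate = 1000 / diff(t_axis[1:2]),
                 cells = cells, epochs = epochs),
            class = "epoch_set")
}
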