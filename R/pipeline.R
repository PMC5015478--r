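#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: cohort design,
#' generator mode and hyperparameters, noise, extraction windows, and
#' significance levels.
#'
#' @param seed master integer seed; the subject-truth stream uses `seed`
#'   and the trial-noise stream `seed + 1000003`, so truth is stable when
#'   only the noise stream changes
#' @param n_subjects cohort size (default 22)
#' @param electrodes electrode labels (default the 13-channel montage)
#' @param isis ISI conditions, seconds (default 1.5/3/4.5/6)
#' @param mode generator coupling mode, `"rubberband"` or `"null"`
#' @param hyperparams generator settings from [mmn_hyperparams()]
#' @param noise noise settings from [mmn_noise()]
#' @param n_blocks_per_isi oddball blocks per ISI condition (default 2,
#'   i.e. 60 deviant / 240 standard epochs per ISI)
#' @param n_stimuli,deviant_prob,min_sep,n_lead oddball block design
#' @param extraction an [mmn_extraction_config()]
#' @param alpha_strict,alpha_combined significance levels (0.05, 0.1)
#' @param rois ROI map (default [MMN_ROIS])
#' @param synthesis `"trials"` for full trial-level synthesis (default) or
#'   `"summary"` for the distributionally equivalent averaged-noise shortcut
#' @return a validated list of class `mmn_config`
#' @export
mmn_config <- function(seed = 1L, n_subjects = 22,
                       electrodes = MMN_ELECTRODES, isis = MMN_ISIS,
                       mode = c("rubberband", "null"),
                       hyperparams = mmn_hyperparams(),
                       noise = mmn_noise(),
                       n_blocks_per_isi = 2,
                       n_stimuli = 150, deviant_prob = 0.2,
                       min_sep = 2, n_lead = 5,
                       extraction = mmn_extraction_config(),
                       alpha_strict = 0.05, alpha_combined = 0.1,
                       rois = MMN_ROIS,
                       synthesis = c("trials", "summary")) {
  mode <- match.arg(mode)
  synthesis <- match.arg(synthesis)
  stopifnot(n_subjects >= 1, length(electrodes) >= 1, length(isis) >= 1,
            alpha_strict <= alpha_combined)
  if (missing(rois)) {
    # restrict the default ROI map to the chosen montage
    rois <- Filter(function(e) length(e) > 0,
                   lapply(MMN_ROIS, intersect, electrodes))
  }
  t_axis <- mmn_time_axis()
  ew <- c(t_axis[1], t_axis[length(t_axis)])
  for (w in list(extraction$peak_window, extraction$baseline_window))
    if (w[1] < ew[1] || w[2] > ew[2] + diff(t_axis[1:2]))
      stop("extraction window outside the epoch")
  if (!all(unlist(rois) %in% electrodes))
    stop("ROI map names electrodes missing from the montage")
  validate_hyperparams(hyperparams)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 electrodes = electrodes, isis = isis, mode = mode,
                 hyperparams = hyperparams, noise = noise,
                 n_blocks_per_isi = n_blocks_per_isi,
                 n_stimuli = n_stimuli, deviant_prob = deviant_prob,
                 min_sep = min_sep, n_lead = n_lead,
                 extraction = extraction,
                 alpha_strict = alpha_strict,
                 alpha_combined = alpha_combined,
                 rois = rois, synthesis = synthesis),
            class = "mmn_config")
}

noise_seed <- function(seed) as.integer(seed) + 1000003L

#' Simulate a cohort of difference waves
#'
#' Draws ground truth, generates oddball sequences, synthesizes epochs
#' subject by subject (to bound memory), and reduces them to averaged,
#' baseline-corrected, low-passed deviant-minus-standard waves. With
#' `config$synthesis = "summary"` the per-trial stage is replaced by its
#' distributional equivalent (see [synthesize_average_waves()]).
#'
#' @param config an [mmn_config()]
#' @return list with `truth` (ground-truth table), `sequences` (oddball
#'   blocks) and `waves` (an `mmn_wave_set`)
#' @export
simulate_cohort_waves <- function(config = mmn_config()) {
  stopifnot(inherits(config, "mmn_config"))
  truth <- draw_ground_truth(config$mode, config$n_subjects,
                             config$hyperparams, config$seed,
                             config$electrodes, config$isis)
  sequences <- list()
  bid <- 0L
  for (isi in config$isis) {
    for (b in seq_len(config$n_blocks_per_isi)) {
      bid <- bid + 1L
      sequences[[bid]] <- generate_stimulus_sequence(
        config$n_stimuli, config$deviant_prob, config$min_sep, config$n_lead,
        seed = (config$seed %% 1000000L) * 1000L + bid,
        block_id = bid, isi_s = isi)
    }
  }
  counts <- trial_counts(sequences, NULL, config$isis)
  bw <- config$extraction$baseline_window
  if (config$synthesis == "summary") {
    k1 <- counts[[1]]
    waves <- synthesize_average_waves(truth, n_dev = k1$deviant,
                                      n_std = k1$standard,
                                      noise = config$noise,
                                      seed = noise_seed(config$seed),
                                      baseline_window = bw)
  } else {
    sets <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      ep <- synthesize_epochs(truth[subject_id == s], sequences = sequences,
                              noise = config$noise,
                              seed = noise_seed(config$seed) + s)
      sets[[s]] <- difference_waves(ep, baseline_window = bw)
    }
    waves <- bind_wave_sets(sets)
  }
  list(truth = truth, sequences = sequences, waves = waves)
}

#' Run the full analysis pipeline
#'
#' Simulation, ROI averaging, nine-parameter extraction, all-pairs
#' electrode-wise Spearman correlations, the electrode-count table, the ROI
#' amplitude-slope table, a ground-truth recovery summary, and a markdown
#' report. Deterministic for a fixed `config$seed`.
#'
#' @param config an [mmn_config()]
#' @param out_dir optional output directory; when given, writes
#'   `parameters.csv`, `roi_parameters.csv`, `correlations.csv`,
#'   `table2_counts.csv`, `table3_roi.csv`, `ground_truth.csv`,
#'   `report.md` and `config.json`
#' @return invisibly, a list with `truth`, `waves`, `roi_waves`, `params`,
#'   `roi_params`, `correlations`, `counts`, `roi_table`, `recovery`,
#'   `normality`
#' @export
run_pipeline <- function(config = mmn_config(), out_dir = NULL) {
  stopifnot(inherits(config, "mmn_config"))
  sim <- simulate_cohort_waves(config)
  roi_waves <- roi_average(sim$waves, config$rois)
  params <- extract_parameters(sim$waves, config$extraction)
  roi_params <- extract_parameters(roi_waves, config$extraction)
  correlations <- all_pairs_correlations(params)
  counts <- count_table(correlations, config$alpha_strict,
                        config$alpha_combined)
  roi_table <- roi_analysis(roi_params)
  recovery <- recovery_summary(sim$truth, params)
  normality <- normality_summary(params)
  res <- list(truth = sim$truth, waves = sim$waves, roi_waves = roi_waves,
              params = params, roi_params = roi_params,
              correlations = correlations, counts = counts,
              roi_table = roi_table, recovery = recovery,
              normality = normality, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

# Correlate extracted magnitudes/latencies with the generating truth.
recovery_summary <- function(truth, params) {
  m <- merge(truth, params,
             by.x = c("subject_id", "isi_s", "electrode"),
             by.y = c("subject_id", "isi_s", "channel"))
  ok <- m[valid == TRUE & is.finite(amplitude)]
  data.table::data.table(
    n_waves = nrow(m),
    n_valid = nrow(ok),
    cor_amplitude = if (nrow(ok) >= 3) stats::cor(ok$A, abs(ok$amplitude)) else NA_real_,
    cor_peak_latency = if (nrow(ok) >= 3) stats::cor(ok$t_pk, ok$peak_latency) else NA_real_,
    cor_downslope = if (nrow(ok) >= 3) stats::cor(ok$descent_rate, ok$downslope) else NA_real_,
    mean_abs_latency_err = if (nrow(ok) >= 1) mean(abs(ok$peak_latency - ok$t_pk)) else NA_real_)
}

# Per-parameter Lilliefors normality log over the pooled valid extractions.
normality_summary <- function(params) {
  ok <- params[valid == TRUE]
  rows <- lapply(MMN_PARAMETER_NAMES, function(pn) {
    v <- ok[[pn]]
    if (sum(is.finite(v)) < 5)
      return(data.table::data.table(parameter = pn, statistic = NA_real_,
                                    p = NA_real_, degenerate = NA))
    nc <- normality_check(v)
    data.table::data.table(parameter = pn, statistic = nc$statistic,
                           p = nc$p, degenerate = nc$degenerate)
  })
  data.table::rbindlist(rows)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f))
  fw(res$params, "parameters.csv")
  fw(res$roi_params, "roi_parameters.csv")
  fw(res$correlations, "correlations.csv")
  fw(res$counts, "table2_counts.csv")
  fw(res$roi_table, "table3_roi.csv")
  fw(res$truth, "ground_truth.csv")
  cfg <- res$config
  cfg_json <- list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                   electrodes = cfg$electrodes, isis = cfg$isis,
                   mode = cfg$mode, noise = cfg$noise,
                   hyperparams = cfg$hyperparams[setdiff(names(cfg$hyperparams),
                                                         c("topography", "isi_mod"))],
                   topography = as.list(cfg$hyperparams$topography),
                   n_blocks_per_isi = cfg$n_blocks_per_isi,
                   synthesis = cfg$synthesis,
                   alpha = c(strict = cfg$alpha_strict,
                             combined = cfg$alpha_combined))
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(render_report(res), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render the pipeline report as markdown lines
#'
#' Mirrors the layout of the study-style summary tables: the electrode-count
#' table per parameter pair and ISI (combined count with the strict count in
#' parentheses) and the ROI amplitude-slope correlation table with
#' significance stars.
#'
#' @param res result list from [run_pipeline()]
#' @return character vector of markdown lines
#' @export
render_report <- function(res) {
  cfg <- res$config
  isis <- sort(unique(res$counts$isi_s))
  lines <- c(
    "# MMN parameter correlation report",
    "",
    sprintf("- mode: %s; subjects: %d; electrodes: %d; ISIs: %s s",
            cfg$mode, cfg$n_subjects, length(cfg$electrodes),
            paste(isis, collapse = ", ")),
    sprintf("- seed: %d; synthesis: %s; single-trial noise SD: %g uV",
            cfg$seed, cfg$synthesis, cfg$noise$sd),
    sprintf("- valid (non-fake) MMN waves: %d of %d",
            res$recovery$n_valid, res$recovery$n_waves),
    "")
  insuff <- res$correlations[flag == "insufficient_n"]
  if (nrow(insuff) > 0)
    lines <- c(lines, sprintf(
      "**Note:** %d correlation cells had fewer than 5 usable subjects and are reported as missing.",
      nrow(insuff)), "")
  lines <- c(lines, "## Electrode counts of significant correlations", "",
             sprintf("Cell entries: electrodes (of %d) with p < %g; in parentheses, p < %g.",
                     length(cfg$electrodes), cfg$alpha_combined, cfg$alpha_strict),
             "",
             paste0("| Pair | ", paste(sprintf("%g s", isis), collapse = " | "), " |"),
             paste0("|", paste(rep("---|", length(isis) + 1), collapse = "")))
  cnt <- res$counts
  for (pr in unique(cnt$pair)) {
    row <- vapply(isis, function(ii) {
      cc <- cnt[pair == pr & isi_s == ii]
      if (nrow(cc) == 0) "" else sprintf("%d (%d)", cc$count_combined, cc$count_strict)
    }, character(1))
    lines <- c(lines, paste0("| ", pr, " | ", paste(row, collapse = " | "), " |"))
  }
  lines <- c(lines, "", "## ROI amplitude-slope correlations", "",
             "Spearman rho; * p < 0.05, ** p < 0.01.", "",
             paste0("| Region | Pair | ", paste(sprintf("%g s", isis), collapse = " | "), " |"),
             paste0("|", paste(rep("---|", length(isis) + 2), collapse = "")))
  rt <- res$roi_table
  for (rg in unique(rt$region)) for (pr in unique(rt$pair)) {
    row <- vapply(isis, function(ii) {
      cc <- rt[region == rg & pair == pr & isi_s == ii]
      if (nrow(cc) == 0 || is.na(cc$rho)) "NA"
      else sprintf("%.4f%s", cc$rho, cc$stars)
    }, character(1))
    lines <- c(lines, paste0("| ", rg, " | ", pr, " | ",
                             paste(row, collapse = " | "), " |"))
  }
  lines <- c(lines, "", "## Ground-truth recovery", "",
             sprintf("- cor(true A, |amplitude|) = %.4f", res$recovery$cor_amplitude),
             sprintf("- cor(true peak latency, extracted) = %.4f", res$recovery$cor_peak_latency),
             sprintf("- cor(true descent rate, downslope) = %.4f", res$recovery$cor_downslope),
             sprintf("- mean |peak latency error| = %.2f ms", res$recovery$mean_abs_latency_err))
  lines
}
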