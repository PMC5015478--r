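#' Lilliefors-type normality check
#'
#' Kolmogorov-Smirnov test against a normal distribution with mean and SD
#' estimated from the data. Because the parameters are estimated, the plain
#' KS null distribution does not apply; the p-value is obtained by Monte
#' Carlo simulation of the statistic under sampling from a fitted normal
#' (Lilliefors' correction), which keeps the test self-contained and exact
#' up to simulation error. The result is reported for the record only: the
#' correlation stage always uses Spearman's rank correlation, which does not
#' assume normal marginals.
#'
#' The Monte Carlo draw uses an internal fixed seed and restores the
#' caller's RNG state, so pipelines stay deterministic.
#'
#' @param values numeric vector (>= 5 finite values)
#' @param n_sim Monte Carlo replicates (default 500)
#' @return list with `statistic` (the KS distance D), `p`, `n`, and a
#'   `degenerate` flag (TRUE for constant input, in which case `p` is NA)
#' @export
normality_check <- function(values, n_sim = 500) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 5) stop("need at least 5 finite values for the normality check")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  lillie_d <- function(z) {
    pr <- stats::pnorm(sort((z - mean(z)) / stats::sd(z)))
    k <- length(z)
    max(max(seq_len(k) / k - pr), max(pr - (seq_len(k) - 1) / k))
  }
  d_obs <- lillie_d(x)
  d_null <- with_seed(104729L + n, {
    vapply(seq_len(n_sim), function(b) lillie_d(stats::rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_sim + 1)
  list(statistic = d_obs, p = p, n = n, degenerate = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (midranks for ties); the
#' two-tailed p-value uses the t approximation with `n - 2` degrees of
#' freedom, adequate at the cohort sizes used here (n near 22). Pairs with a
#' missing member are dropped; fewer than `min_n` complete pairs, or zero
#' rank variance in either variable, yields a missing (flagged) result.
#'
#' @param x,y numeric vectors of equal length
#' @param min_n minimum complete pairs (default 5)
#' @return list with `rho`, `p`, `n_used`, and `flag`
#'   (`"ok"`, `"insufficient_n"`, or `"degenerate"`)
#' @export
spearman <- function(x, y, min_n = 5) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n)
    return(list(rho = NA_real_, p = NA_real_, n_used = n,
                flag = "insufficient_n"))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n_used = n, flag = "degenerate"))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n_used = n, flag = "ok")
}

# Parameters entering correlations as absolute values (peak polarity and
# slope direction are sign conventions, not magnitudes).
ABS_PARAMS <- c("amplitude", "ampavg", "upslope", "downslope")

#' All-pairs Spearman correlations per electrode and ISI
#'
#' For each of the 36 unordered pairs of the nine parameters, each ISI and
#' each channel, computes the Spearman correlation across subjects. Only
#' rows with `valid = TRUE` enter, pairwise-complete; absolute values are
#' substituted for amplitude, ampavg, upslope and downslope.
#'
#' No multiple-testing correction is applied: the downstream counting
#' heuristic deliberately works with per-cell p-values (family size is 36
#' pairs x ISIs x channels).
#'
#' @param params parameter table from [extract_parameters()]
#' @param parameters parameter names to pair (default the canonical nine)
#' @param min_n minimum subjects per correlation (default 5)
#' @return a `data.table` with columns `pair`, `param1`, `param2`, `isi_s`,
#'   `channel`, `rho`, `p`, `n_used`, `flag`
#' @export
all_pairs_correlations <- function(params,
                                   parameters = MMN_PARAMETER_NAMES,
                                   min_n = 5) {
  params <- data.table::as.data.table(params)
  stopifnot(all(parameters %in% names(params)))
  pairs <- utils::combn(parameters, 2, simplify = FALSE)
  keys <- unique(params[, .(isi_s, channel)])
  out <- vector("list", 0)
  for (r in seq_len(nrow(keys))) {
    sub <- params[isi_s == keys$isi_s[r] & channel == keys$channel[r] &
                  valid == TRUE]
    vals <- lapply(stats::setNames(parameters, parameters), function(pn) {
      v <- sub[[pn]]
      if (pn %in% ABS_PARAMS) abs(v) else v
    })
    for (pr in pairs) {
      sp <- spearman(vals[[pr[1]]], vals[[pr[2]]], min_n = min_n)
      out[[length(out) + 1L]] <- data.table::data.table(
        pair = paste(pr, collapse = "-"), param1 = pr[1], param2 = pr[2],
        isi_s = keys$isi_s[r], channel = keys$channel[r],
        rho = sp$rho, p = sp$p, n_used = sp$n_used, flag = sp$flag)
    }
  }
  if (length(out) == 0) {
    return(data.table::data.table(
      pair = character(0), param1 = character(0), param2 = character(0),
      isi_s = numeric(0), channel = character(0), rho = numeric(0),
      p = numeric(0), n_used = integer(0), flag = character(0)))
  }
  data.table::rbindlist(out)
}

#' Electrode-count summary of significant correlations
#'
#' For each parameter pair and ISI, counts the electrodes whose correlation
#' is significant or marginally significant (`p < alpha_combined`, default
#' 0.1) and, in parentheses-style, strictly significant
#' (`p < alpha_strict`, default 0.05). Counts ignore the correlation sign;
#' positive-signed counts are reported alongside for inspection.
#'
#' @param results correlation table from [all_pairs_correlations()]
#' @param alpha_strict,alpha_combined significance levels (0.05, 0.1)
#' @return a `data.table` with `pair`, `isi_s`, `count_combined`,
#'   `count_strict`, `count_pos_combined`, `count_pos_strict`,
#'   `n_electrodes`
#' @export
count_table <- function(results, alpha_strict = 0.05, alpha_combined = 0.1) {
  stopifnot(alpha_strict <= alpha_combined)
  results <- data.table::as.data.table(results)
  results[, .(
    count_combined = sum(p < alpha_combined, na.rm = TRUE),
    count_strict = sum(p < alpha_strict, na.rm = TRUE),
    count_pos_combined = sum(p < alpha_combined & rho > 0, na.rm = TRUE),
    count_pos_strict = sum(p < alpha_strict & rho > 0, na.rm = TRUE),
    n_electrodes = .N
  ), by = .(pair, isi_s)]
}

#' Region-of-interest amplitude-slope correlations
#'
#' Spearman correlations between absolute amplitude and the two slopes,
#' per region and ISI, computed on parameters extracted from ROI-averaged
#' waves. Stars mark p < 0.05 (*) and p < 0.01 (**).
#'
#' @param roi_params parameter table from [extract_parameters()] applied to
#'   ROI-averaged waves ([roi_average()])
#' @param pairs list of parameter pairs to report (default amplitude vs.
#'   upslope and amplitude vs. downslope)
#' @param min_n minimum subjects per correlation
#' @return a `data.table` with `region`, `pair`, `isi_s`, `rho`, `p`,
#'   `n_used`, `stars`
#' @export
roi_analysis <- function(roi_params,
                         pairs = list(c("amplitude", "upslope"),
                                      c("amplitude", "downslope")),
                         min_n = 5) {
  roi_params <- data.table::as.data.table(roi_params)
  res <- all_pairs_correlations(roi_params,
                                parameters = unique(unlist(pairs)),
                                min_n = min_n)
  want <- vapply(pairs, paste, character(1), collapse = "-")
  res <- res[pair %in% want]
  data.table::setnames(res, "channel", "region")
  res[, stars := ifelse(is.na(p), "",
                 ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))]
  res[, .(region, pair, isi_s, rho, p, n_used, stars)]
}
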