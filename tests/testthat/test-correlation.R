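test_that("normality check is calibrated on normal data and rejects skewed data", {
  normal_p <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(rnorm(1000), n_sim = 300)$p
  }, numeric(1))
  expect_gte(mean(normal_p > 0.05), 0.90)
  expo_p <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(rexp(1000), n_sim = 300)$p
  }, numeric(1))
  expect_gte(mean(expo_p < 0.05), 0.99)
})

test_that("degenerate and short inputs are handled", {
  res <- normality_check(rep(3, 30))
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  expect_error(normality_check(c(1, 2, 3)), "at least 5")
})

test_that("normality check restores the caller's RNG state", {
  set.seed(123)
  x <- rnorm(50)
  before <- .Random.seed
  invisible(normality_check(x))
  expect_identical(.Random.seed, before)
})

test_that("spearman matches monotone expectations and the rank oracle", {
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman(1:5, c(10, 8, 6, 4, 2))$rho, -1)
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10))$p, 0)
  # tied data against the average-rank Pearson oracle
  x <- c(1, 1, 2, 3, 7); y <- c(2, 3, 3, 5, 1)
  expect_equal(spearman(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  # random vectors with ties
  set.seed(5)
  for (i in 1:25) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE) + 0.5 * x
    sp <- spearman(x, y)
    expect_equal(sp$rho, oracle_spearman(x, y), tolerance = 1e-12)
    # two-tailed t-approximation p-value recomputed directly
    tt <- sp$rho * sqrt((12 - 2) / (1 - sp$rho^2))
    expect_equal(sp$p, 2 * pt(-abs(tt), 10), tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(22); y <- rnorm(22)
    base <- spearman(x, y)$rho
    expect_equal(spearman(exp(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman(x, y^3)$rho, base, tolerance = 1e-12)
    expect_equal(spearman(1 / (1 + exp(-x)), y)$rho, base, tolerance = 1e-12)
  }
})

test_that("spearman flags insufficient n and degenerate ranks", {
  expect_identical(spearman(c(1, 2, 3, NA, NA), c(1, 2, 3, 4, 5))$flag,
                   "insufficient_n")
  expect_identical(spearman(rep(1, 10), rnorm(10))$flag, "degenerate")
  expect_identical(spearman(rnorm(10), rnorm(10))$flag, "ok")
})

fake_params <- function(n_subj = 22, isis = MMN_ISIS,
                        channels = "FZ", seed = 1) {
  set.seed(seed)
  grid <- data.table::CJ(subject_id = seq_len(n_subj), isi_s = isis,
                         channel = channels)
  for (pn in MMN_PARAMETER_NAMES) grid[[pn]] <- rnorm(nrow(grid))
  grid$valid <- TRUE
  grid
}

test_that("all-pairs enumeration yields 36 pairs and 144 results per electrode", {
  params <- fake_params()
  res <- all_pairs_correlations(params)
  expect_identical(length(unique(res$pair)), 36L)        # C(9,2)
  expect_identical(nrow(res), 144L)                      # 36 x 4 ISIs
  # two parameters, one ISI, one electrode -> exactly one result
  res2 <- all_pairs_correlations(fake_params(isis = 1.5),
                                 parameters = c("amplitude", "downslope"))
  expect_identical(nrow(res2), 1L)
})

test_that("absolute values are substituted for the magnitude parameters", {
  params <- fake_params(isis = 1.5)
  flipped <- data.table::copy(params)
  flipped$amplitude <- -flipped$amplitude
  flipped$upslope <- -flipped$upslope
  r1 <- all_pairs_correlations(params, parameters = c("amplitude", "upslope"))
  r2 <- all_pairs_correlations(flipped, parameters = c("amplitude", "upslope"))
  expect_equal(r1$rho, r2$rho)
})

test_that("count_table applies the two-level threshold arithmetic", {
  ps <- c(0.01, 0.04, 0.07, 0.2, rep(0.5, 9))
  res <- data.table::data.table(
    pair = "amplitude-downslope", param1 = "amplitude", param2 = "downslope",
    isi_s = 1.5, channel = MMN_ELECTRODES, rho = 0.5, p = ps,
    n_used = 22L, flag = "ok")
  ct <- count_table(res)
  expect_identical(ct$count_combined, 3L)
  expect_identical(ct$count_strict, 2L)
  expect_identical(ct$n_electrodes, 13L)
  res$p <- 1
  ct0 <- count_table(res)
  expect_identical(ct0$count_combined, 0L)
  expect_identical(ct0$count_strict, 0L)
})

test_that("counts equal an exhaustive recount on random p-values", {
  params <- fake_params(channels = MMN_ELECTRODES, seed = 3)
  res <- all_pairs_correlations(params)
  ct <- count_table(res)
  for (r in sample(nrow(ct), 20)) {
    sub <- res[pair == ct$pair[r] & isi_s == ct$isi_s[r]]
    expect_identical(ct$count_combined[r], sum(sub$p < 0.1, na.rm = TRUE))
    expect_identical(ct$count_strict[r], sum(sub$p < 0.05, na.rm = TRUE))
    expect_lte(ct$count_strict[r], ct$count_combined[r])
    expect_lte(ct$count_combined[r], 13L)
  }
})

test_that("count cells from a simulated cohort satisfy the ordering invariant", {
  cfg <- tiny_config(seed = 2, synthesis = "summary")
  res <- run_pipeline(cfg)
  expect_true(all(res$counts$count_strict <= res$counts$count_combined))
  expect_true(all(res$counts$count_combined <= length(cfg$electrodes)))
})

test_that("roi correlations are perfect under pure subject scaling", {
  # identical wave scaled by a subject factor: amplitude and downslope are
  # both proportional to the factor (the rubberband construction)
  base <- mmn_component(1, 120, 180, 300, TAX)
  scales <- seq(1, 3, length.out = 12)
  meta <- data.table::data.table(subject_id = seq_along(scales), isi_s = 1.5,
                                 channel = "frontal")
  ws <- mmn_wave_set(meta, outer(scales, base), TAX)
  params <- extract_parameters(ws)
  tab <- roi_analysis(params)
  down <- tab[pair == "amplitude-downslope"]
  expect_equal(down$rho, 1)
  expect_identical(down$stars, "**")
})

test_that("rubberband cohorts show significant frontal amplitude-downslope coupling", {
  hits <- 0L
  n_runs <- 12
  for (s in seq_len(n_runs)) {
    cfg <- mmn_config(seed = 100 + s, synthesis = "summary",
                      electrodes = MMN_ROIS$frontal,
                      rois = MMN_ROIS["frontal"])
    res <- run_pipeline(cfg)
    down <- res$roi_table[region == "frontal" & pair == "amplitude-downslope"]
    if (sum(down$p < 0.05 & down$rho > 0, na.rm = TRUE) >= 3) hits <- hits + 1L
  }
  expect_gte(hits, n_runs - 2L)
})

test_that("normality summary logs one row per parameter", {
  cfg <- tiny_config(seed = 4, synthesis = "summary")
  res <- run_pipeline(cfg)
  expect_identical(res$normality$parameter, MMN_PARAMETER_NAMES)
  expect_true(all(res$normality$p >= 0 & res$normality$p <= 1, na.rm = TRUE))
})
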