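# canonical linear-segment fixture: 0 -> -5 uV over 120..180 ms, back to 0
# over 180..260 ms; with Th = -0.5 the crossings are at 126 and 252 ms
tri_wave <- function() component_wave(5, 120, 180, 260, shape = "linear")

test_that("threshold is baseline mean minus sample SD", {
  z <- mmn_wave(numeric(length(TAX)), TAX)
  expect_equal(compute_threshold(z), 0)
  # constructed baseline with mean 0.2 and SD 0.5 -> Th = -0.3
  v <- numeric(length(TAX))
  bl <- which(TAX >= -200 & TAX < 0)
  v[bl] <- 0.2 + 0.5 * scale(rnorm(length(bl)))[, 1]
  expect_equal(compute_threshold(mmn_wave(v, TAX)), -0.3, tolerance = 1e-12)
  # alternating +-1 baseline: Th = -SD, SD from the two-pass oracle
  v2 <- numeric(length(TAX))
  v2[bl] <- rep(c(1, -1), length.out = length(bl))
  expect_equal(compute_threshold(mmn_wave(v2, TAX)),
               0 - oracle_sd(v2[bl]), tolerance = 1e-12)
})

test_that("fake-MMN rejection uses a strict threshold comparison", {
  z <- mmn_wave(numeric(length(TAX)), TAX)
  expect_false(validate_mmn(z, -0.5))
  expect_true(validate_mmn(tri_wave(), -0.5))
  # a wave dipping exactly to Th is not "more negative than Th"
  exact <- mmn_wave(mmn_component(0.5, 120, 180, 260, TAX, "linear"), TAX)
  expect_identical(min(exact$samples), -0.5)
  expect_false(validate_mmn(exact, -0.5))
})

test_that("peak search is an earliest-tie exhaustive argmin", {
  pk <- find_peak(tri_wave())
  expect_equal(pk$peak_latency, 180)
  expect_equal(pk$amplitude, -5)
  # two equal minima at 160 and 240 ms: earliest wins
  v <- mmn_component(4, 130, 160, 190, TAX, "linear") +
       mmn_component(4, 210, 240, 270, TAX, "linear")
  expect_equal(find_peak(mmn_wave(v, TAX))$peak_latency, 160)
  # noisy waves: equals brute-force scan
  set.seed(7)
  for (i in 1:50) {
    w <- mmn_wave(smooth_noise(3), TAX)
    pk <- find_peak(w)
    idx <- which(TAX >= 100 & TAX < 300)
    expect_equal(pk$amplitude, min(w$samples[idx]))
    expect_equal(pk$peak_latency, TAX[idx[which.min(w$samples[idx])]])
  }
  expect_error(find_peak(tri_wave(), c(900, 950)), "no samples")
})

test_that("ampavg matches the closed-form mean of the sampled triangle", {
  # plateau: ampavg equals the plateau value
  v <- numeric(length(TAX)); v[TAX >= 150 & TAX <= 210] <- -5
  expect_equal(compute_ampavg(mmn_wave(v, TAX), 180)$ampavg, -5)
  # symmetric triangle, slopes +-k: sampled mean over +-20 ms (21 samples)
  # is -A + k * 220/21 (sum of |offsets| 0,2,...,20 twice = 220)
  k <- 5 / 60
  sym <- component_wave(5, 120, 180, 240, shape = "linear")
  expect_equal(compute_ampavg(sym, 180)$ampavg, -5 + k * 220 / 21,
               tolerance = 1e-12)
  # magnitude never exceeds the peak magnitude for unimodal waves
  expect_lte(abs(compute_ampavg(tri_wave(), 180)$ampavg), 5)
  # window clipping is flagged at the epoch edge
  res <- compute_ampavg(tri_wave(), TAX[2])
  expect_true(res$clipped)
})

test_that("onset/offset are interpolated threshold crossings of the peak's excursion", {
  oo <- find_onset_offset(tri_wave(), -0.5, 180)
  expect_equal(oo$onset, 126)    # 120 + 0.5/5 * 60
  expect_equal(oo$offset, 252)   # 260 - 0.5/5 * 80
  expect_false(oo$onset_clipped || oo$offset_clipped)
  # wave below threshold from epoch start: clamp + flag
  v <- rep(-2, length(TAX)); v[TAX > 300] <- 0
  oo2 <- find_onset_offset(mmn_wave(v, TAX), -0.5, 180)
  expect_equal(oo2$onset, TAX[1])
  expect_true(oo2$onset_clipped)
  expect_false(oo2$offset_clipped)
  # multi-dip wave: an earlier sub-threshold excursion is ignored
  v3 <- mmn_component(3, 0, 40, 80, TAX, "linear") +
        mmn_component(5, 120, 180, 260, TAX, "linear")
  oo3 <- find_onset_offset(mmn_wave(v3, TAX), -0.5, 180)
  expect_equal(oo3$onset, 126)
  expect_equal(oo3$offset, 252)
  # exhaustive crossing enumeration agrees: the excursion's bounds are the
  # nearest crossings bracketing the peak
  crossings <- c()
  v <- v3
  for (i in 2:length(TAX)) {
    if ((v[i - 1] >= -0.5) != (v[i] >= -0.5)) {
      tt <- TAX[i - 1] + (-0.5 - v[i - 1]) / (v[i] - v[i - 1]) * 2
      crossings <- c(crossings, tt)
    }
  }
  expect_equal(max(crossings[crossings <= 180]), oo3$onset)
  expect_equal(min(crossings[crossings >= 180]), oo3$offset)
  expect_error(find_onset_offset(tri_wave(), -6, 180), "not below")
})

test_that("duration and area match trapezoidal integration with cut corners", {
  w <- tri_wave()
  oo <- find_onset_offset(w, -0.5, 180)
  da <- compute_duration_area(w, oo$onset, oo$offset)
  expect_equal(da$duration, 126)
  # full triangle 350 uV*ms minus the corner triangles 1.5 and 2.0
  expect_equal(da$area, 346.5, tolerance = 1e-9)
  expect_equal(compute_duration_area(w, 180, 180),
               list(duration = 0, area = 0))
  # threshold-referenced alternative subtracts Th from the integrand
  da_th <- compute_duration_area(w, oo$onset, oo$offset,
                                 reference = "threshold", threshold = -0.5)
  expect_equal(da_th$area, 346.5 - 0.5 * 126, tolerance = 1e-9)
  expect_error(compute_duration_area(w, 252, 126), "precede")
})

test_that("slopes are sign-restricted central-difference maxima", {
  w <- tri_wave()
  sl <- compute_slopes(w, 126, 180, 252)
  expect_equal(sl$upslope, 5 / 60, tolerance = 1e-9)
  expect_equal(sl$downslope, 5 / 80, tolerance = 1e-9)
  # symmetric component: equal slopes
  sym <- component_wave(4, 120, 180, 240)
  oo <- find_onset_offset(sym, -0.2, 180)
  sls <- compute_slopes(sym, oo$onset, 180, oo$offset)
  expect_equal(sls$upslope, sls$downslope, tolerance = 1e-6)
  # raised cosine: closed-form max derivative A*pi/(2*rise) within 1%
  cw <- component_wave(4, 110, 180, 300)
  oo <- find_onset_offset(cw, -0.04, 180)
  slc <- compute_slopes(cw, oo$onset, 180, oo$offset)
  expect_equal(slc$upslope, 4 * pi / (2 * 70), tolerance = 0.01)
  expect_error(compute_slopes(w, 180, 180, 252), "onset < peak")
})

test_that("extract_all recovers noiseless ground truth within tolerance", {
  set.seed(11)
  for (i in 1:30) {
    a <- random_component_args()
    a$shape <- "cosine"   # flat-top peak: magnitude recovery is grid-robust
    w <- do.call(component_wave, a)
    p <- extract_all(w)
    expect_true(p$valid)
    expect_lte(abs(p$peak_latency - a$t_pk), 2)          # one sample
    expect_lte(abs(abs(p$amplitude) - a$A) / a$A, 0.02)  # 2%
    expect_lte(abs(p$onset - a$t_on), 2)
    expect_lte(abs(p$offset - a$t_off), 2)
    expect_lte(abs(p$duration - (p$offset - p$onset)), 1e-9)
    k_up <- a$A * pi / (2 * (a$t_pk - a$t_on))
    expect_lte(abs(p$upslope - k_up) / k_up, 0.02)
  }
})

test_that("invalid waves yield missing parameters, and valid ones complete rows", {
  z <- extract_all(mmn_wave(numeric(length(TAX)), TAX))
  expect_false(z$valid)
  expect_true(all(is.na(unlist(z[MMN_PARAMETER_NAMES]))))
  # completeness on a small noisy cohort
  tr <- draw_ground_truth("rubberband", n_subjects = 4, seed = 3,
                          electrodes = c("FZ", "T7"), isis = 1.5)
  waves <- synthesize_average_waves(tr, noise = mmn_noise(sd = 8), seed = 5)
  tab <- extract_parameters(waves)
  expect_identical(nrow(tab), nrow(tr))
  ok <- tab[valid == TRUE]
  for (pn in MMN_PARAMETER_NAMES) expect_true(all(is.finite(ok[[pn]])))
})

test_that("parameter invariants hold on random synthetic waves", {
  set.seed(21)
  for (i in 1:100) {
    a <- random_component_args()
    w <- do.call(component_wave, c(a, list(noise = smooth_noise(1.5))))
    p <- extract_all(w)
    if (!p$valid) next
    expect_lte(p$onset, p$peak_latency)
    expect_lte(p$peak_latency, p$offset)
    expect_equal(p$duration, p$offset - p$onset)
    expect_lte(p$amplitude, p$threshold)
    expect_gte(p$upslope, 0)
    expect_gte(p$downslope, 0)
    expect_gte(p$area, 0)
  }
})

test_that("extraction is scale-consistent on threshold-free components", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_component_args()
    w <- do.call(component_wave, a)
    p1 <- extract_all(w)
    c_scale <- runif(1, 1.5, 4)
    p2 <- extract_all(mmn_wave(c_scale * w$samples, TAX))
    for (pn in c("amplitude", "ampavg", "area", "upslope", "downslope"))
      expect_equal(p2[[pn]], c_scale * p1[[pn]], tolerance = 1e-9)
    expect_equal(p2$peak_latency, p1$peak_latency)
  }
})
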