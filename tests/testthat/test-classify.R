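test_that("onset lands at the knee of a ramp-then-plateau trace", {
  tr <- ramp_trace(n_ramp = 100, n_total = 300)
  expect_lte(abs(detect_onset(tr) - 100L), 2L)
})

test_that("a trace inside the noise floor raises a no-slide error", {
  tr <- force_trace(time = (0:199) / 550, force = rep(0, 200),
                    surface_id = "flat", applied_mass = 0, velocity = 5)
  expect_error(detect_onset(tr), class = "frinstab_no_slide")
})

test_that("onset of a stiction-spike pull sits at the spike apex", {
  p <- phenotype_params("Sp", applied_mass = 100, velocity = 10,
                        noise_sd = 0)
  tr <- simulate_trace(p, 0.43)
  onset <- detect_onset(tr)
  apex <- which.max(tr$force)
  slip <- attr(tr, "events")$first_slip_index
  expect_lte(abs(onset - apex), 3L)
  expect_lte(abs(onset - slip), 3L)
})

test_that("features of a constant post-onset trace are flat", {
  tr <- plateau_trace(level = 1)
  ft <- extract_features(tr, detect_onset(tr))
  expect_equal(ft$steady_mean, 1, tolerance = 1e-6)
  expect_lt(ft$wave_amplitude, 0.01)
  expect_equal(ft$wave_count, 0L)
})

test_that("an 8 Hz sinusoid yields its amplitude and cycle count", {
  tr <- plateau_trace(level = 1, wave_amp = 0.3, wave_freq = 8,
                      duration = 2)
  onset <- detect_onset(tr)
  ft <- extract_features(tr, onset)
  seg_t <- (length(tr$force) - (onset + 15) + 1) / 550
  expect_equal(ft$wave_amplitude, 0.3, tolerance = 0.05)
  expect_lte(abs(ft$wave_count - 8 * seg_t), 1)
})

test_that("friction coefficient divides by the full normal load", {
  tr <- plateau_trace(level = 1.04, applied_mass = 100)
  ft <- extract_features(tr, detect_onset(tr))
  expect_equal(ft$mu, 1.04 / (0.106 * 9.81), tolerance = 1e-3)
})

test_that("feature extraction refuses degenerate post-onset segments", {
  tr <- ramp_trace(n_ramp = 100, n_total = 120)
  expect_error(extract_features(tr, 100L), class = "frinstab_feature_error")
})

test_that("label rules reproduce the threshold arithmetic", {
  # 10% spike rule over steady sliding
  expect_identical(classify_trace(make_features(1.20, 1.00))$label, "Sp")
  expect_identical(classify_trace(make_features(1.20, 1.00))$coexists_with,
                   "SS")
  expect_identical(classify_trace(make_features(1.05, 1.00))$label, "SS")
  # exact tie classifies as the spike
  expect_identical(classify_trace(make_features(1.10, 1.00))$label, "Sp")
  # 40% rule against the wave envelope: 1.60 < 1.4 * 1.30
  f <- make_features(1.60, 1.00, wave_amplitude = 0.30, wave_count = 5L)
  expect_identical(classify_trace(f)$label, "SFW")
  f2 <- make_features(1.90, 1.00, wave_amplitude = 0.30, wave_count = 5L)
  cl2 <- classify_trace(f2)
  expect_identical(cl2$label, "Sp")
  expect_identical(cl2$coexists_with, "SFW")
  # spikes below the noise floor carry no evidence
  tiny <- make_features(0.115, 0.100)
  expect_identical(classify_trace(tiny)$label, "SS")
})

test_that("classification is equivariant under joint force/noise rescaling", {
  set.seed(31)
  for (rep in seq_len(20)) {
    fp <- runif(1, 0.5, 3); sm <- runif(1, 0.4, 2)
    wa <- sample(c(0, runif(1, 0, 0.5)), 1); wc <- sample(0:6, 1)
    c1 <- classify_trace(make_features(fp, sm, wa, wc))
    scale <- runif(1, 0.1, 10)
    th <- classifier_thresholds(noise_floor = 0.04 * scale)
    c2 <- classify_trace(make_features(fp * scale, sm * scale, wa * scale,
                                       wc, noise_floor = 0.04 * scale), th)
    expect_identical(c1$label, c2$label)
  }
})

test_that("raising the first peak can only move the label toward Sp", {
  set.seed(32)
  rank_sp <- function(lab) as.integer(lab == "Sp")
  for (rep in seq_len(20)) {
    sm <- runif(1, 0.4, 2)
    wa <- sample(c(0, runif(1, 0, 0.5)), 1)
    wc <- sample(0:6, 1)
    peaks <- sort(runif(5, sm, 4 * sm))
    labs <- vapply(peaks, function(fp)
      classify_trace(make_features(fp, sm, wa, wc))$label, character(1))
    expect_true(all(diff(rank_sp(labs)) >= 0))
  }
})

test_that("mu of a noiseless steady-sliding pull matches mu_k0 within 1%", {
  p <- phenotype_params("SS", applied_mass = 100, velocity = 10,
                        noise_sd = 0, mu_k0 = 2)
  tr <- simulate_trace(p, 0.43)
  ft <- extract_features(tr, detect_onset(tr))
  expect_equal(ft$mu, 2, tolerance = 0.01)
})

test_that("first pulls are flagged, not classified", {
  p <- phenotype_params("SS", applied_mass = 100, velocity = 10)
  tr1 <- simulate_trace(p, 0.43, meta = list(pull_index = 1L))
  tr2 <- simulate_trace(p, 0.43, meta = list(pull_index = 2L))
  cls <- classify_traces(list(tr1, tr2))
  expect_true(cls$flagged[1])
  expect_true(is.na(cls$label[1]))
  expect_false(cls$flagged[2])
})

test_that("mu aggregation follows the mean-of-condition-means and IQR rules", {
  grid <- condition_grid(masses = c(0, 25), velocities = c(5, 10),
                         n_reps = 4L)
  # all traces mu = 2 -> mu_bar 2, iqr 0
  cls <- synthetic_classified(grid, function(i, j, r) "SS")
  cls$mu <- 2
  agg <- aggregate_mu(cls, grid)
  expect_equal(agg$mu_bar, 2)
  expect_equal(agg$iqr, 0)

  # {1,2,3,4} per condition: iqr via linear-interpolation quantiles
  cls$mu <- rep(1:4, times = 4)
  agg <- aggregate_mu(cls, grid)
  expect_equal(agg$mu_bar, 2.5)
  q <- stats::quantile(rep(1:4, 4), c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(agg$iqr, q[2] - q[1])

  # condition means {1..4}/2 (2x2 grid): mu_bar is their plain mean
  cls$mu <- rep(c(1, 2, 3, 4) / 2, each = 4)
  expect_equal(aggregate_mu(cls, grid)$mu_bar, mean(c(1, 2, 3, 4) / 2))

  # incomplete grid errors
  expect_error(aggregate_mu(cls[-1, ], grid),
               class = "frinstab_completeness_error")
})
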