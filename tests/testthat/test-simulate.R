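test_that("no drive means no force: v = 0, t0 = 0 stays at zero", {
  p <- sim_params(normal_force = 1, v = 0, mass = 0.1, mu_k0 = 2,
                  noise_sd = 0)
  tr <- simulate_trace(p, 0.5)
  expect_true(all(abs(tr$force) < 1e-12))
})

test_that("steady sliding settles at mu_k0 * N with no weakening or aging", {
  p <- phenotype_params("SS", applied_mass = 100, velocity = 10,
                        noise_sd = 0)
  tr <- simulate_trace(p, 0.45)
  target <- 2 * normal_force(100)
  late <- tail(tr$force, 30)
  expect_equal(mean(late), target, tolerance = 1e-3)
})

test_that("force ramps at exactly dF/dX = k while the block is stuck", {
  # large mu_k0 keeps the block stuck well past the stage acceleration ramp
  p <- sim_params(normal_force = normal_force(100), v = 0.01, mass = 0.106,
                  mu_k0 = 20, noise_sd = 0)
  tr <- simulate_trace(p, 1.4)
  fs <- tr$meta$sampling_rate
  i <- which(tr$time > p$accel_time + 0.05 & tr$force < 15)
  dF <- diff(tr$force[i])
  expect_equal(dF, rep(p$k * p$v / fs, length(dF)), tolerance = 1e-9)
})

test_that("simulation is deterministic given the seed and diverges without it", {
  p <- phenotype_params("SFW", applied_mass = 75, velocity = 10, seed = 11)
  tr1 <- simulate_trace(p, 0.3)
  tr2 <- simulate_trace(p, 0.3)
  expect_identical(tr1$force, tr2$force)
})

test_that("energy sanity: noiseless force never exceeds the aged static
           threshold plus loading and inertial slack", {
  for (ph in c("SS", "Sp", "SFW")) {
    p <- phenotype_params(ph, applied_mass = 75, velocity = 10,
                          noise_sd = 0)
    tr <- simulate_trace(p, 0.46)
    theta_max <- p$t0 + max(tr$time)
    mu_s_max <- p$mu_k0 + p$d_mu + p$aging_b * log1p(theta_max / p$theta0)
    slack <- p$k * p$v / (10 * p$sampling_rate) + p$v * sqrt(p$k * p$mass)
    expect_lt(max(tr$force), mu_s_max * p$normal_force + slack)
  }
})

test_that("guaranteed phenotype templates classify as intended 9/9 noiseless", {
  for (ph in c("SS", "Sp", "SFW")) {
    labels <- vapply(seq_len(9), function(r) {
      p <- phenotype_params(ph, applied_mass = 100, velocity = 10,
                            noise_sd = 0)
      classify_pull(simulate_trace(p, 0.43))$label
    }, character(1))
    expect_identical(labels, rep(ph, 9), label = ph)
  }
})

test_that("simulate_surface fills the default grid with 144 retained pulls", {
  grid <- condition_grid()
  spec <- demo_regime(grid, surface_id = "full")
  traces <- simulate_surface(spec, seed = 21)
  expect_length(traces, 144L)
  comp <- check_completeness(traces, grid)
  expect_true(comp$complete)
  # retained pulls only: sets 1-3, pulls 2-4
  pulls <- vapply(traces, function(tr) tr$meta$pull_index, integer(1))
  expect_true(all(pulls %in% 2:4))
})

test_that("pure steady-sliding weights classify as SS at every node", {
  grid <- condition_grid()
  w <- array(0, c(4, 4, 3))
  w[, , 1] <- 1
  spec <- regime_spec(grid, w, surface_id = "allss")
  traces <- simulate_surface(spec, seed = 3)
  cls <- classify_traces(traces)
  expect_true(all(cls$label == "SS"))
})

test_that("same seed reproduces an identical trace set", {
  grid <- condition_grid(masses = c(25, 100), velocities = c(10, 25),
                         n_reps = 3L)
  spec <- demo_regime(grid, surface_id = "det")
  t1 <- simulate_surface(spec, seed = 5)
  t2 <- simulate_surface(spec, seed = 5)
  expect_identical(lapply(t1, `[[`, "force"), lapply(t2, `[[`, "force"))
})

test_that("synthetic height maps hit the target rms exactly and repeat by seed", {
  hm <- synth_heightmap(0.4, rms = 3.7e-10, n_pixels = 64, seed = 8)
  h <- hm$heights
  expect_equal(sqrt(mean((h - mean(h))^2)), 3.7e-10, tolerance = 1e-9)
  hm2 <- synth_heightmap(0.4, rms = 3.7e-10, n_pixels = 64, seed = 8)
  expect_identical(hm$heights, hm2$heights)
  expect_error(synth_heightmap(1.2, 1e-9, 64),
               class = "frinstab_validation_error")
})

test_that("behavioural generator reproduces chance and ceiling accuracy", {
  pred <- stats::setNames(rep(0, 6), paste0("P", 1:6))
  chance <- synth_behavior(pred, beta0 = stats::qlogis(1 / 3), beta1 = 0,
                           sigma_subject = 0, n_subjects = 10,
                           n_trials_per_pair = 50, seed = 6)
  p_hat <- mean(chance$correct)
  se <- sqrt(1 / 3 * 2 / 3 / nrow(chance))
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
  # incorrect answers never land on the odd position
  wrong <- chance[!chance$correct, ]
  expect_true(all(wrong$chosen_position != wrong$odd_position))

  ceiling <- synth_behavior(pred, beta0 = 20, beta1 = 0, sigma_subject = 0,
                            n_subjects = 4, n_trials_per_pair = 10, seed = 6)
  expect_equal(mean(ceiling$correct), 1.0)
})
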