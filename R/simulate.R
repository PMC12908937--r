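#' Simulator parameters for the spring-block friction model
#'
#' The finger-on-surface rig is idealised as a single-degree-of-freedom
#' spring-block system: a block (the finger pad, effective mass `mass`) is
#' dragged through a spring of stiffness `k` (the force sensor / finger
#' compliance) by a stage moving at velocity `v`. Friction at the block
#' interface combines contact aging (static threshold growing
#' logarithmically with stationary contact time) and velocity weakening
#' (kinetic coefficient decaying with slip speed):
#'
#' \itemize{
#'   \item static: `mu_s = mu_k0 + d_mu + aging_b * log(1 + theta / theta0)`,
#'     where the state `theta` accrues while stuck and resets to 0 at
#'     re-stick after a slip (it starts at the pre-slide dwell `t0`);
#'   \item kinetic: `mu(xdot) = mu_k0 + d_mu * exp(-xdot / v_c)`.
#' }
#'
#' This is a deliberately minimal aging + velocity-weakening law (not a
#' full rate-and-state formulation): it is the simplest model that spans
#' the three observed trace phenotypes. `aging_b = d_mu = 0` gives steady
#' sliding (SS); large `aging_b` with a long initial dwell `t0` and
#' `d_mu ~ 0` gives a single stiction spike then steady sliding (Sp);
#' large `d_mu` with `v_c` comparable to `v` sustains limit-cycle
#' stick-slip, i.e. slow frictional waves (SFW).
#'
#' @param normal_force Normal load N (newtons).
#' @param v Drive velocity (m/s).
#' @param mass Effective block mass (kg).
#' @param mu_k0 Base kinetic friction coefficient.
#' @param k Spring stiffness (N/m), default 13900 (the force sensor).
#' @param d_mu Velocity-weakening depth (dimensionless), >= 0.
#' @param v_c Weakening velocity scale (m/s), > 0.
#' @param aging_b Aging gain (dimensionless), >= 0.
#' @param theta0 Aging time scale (s), > 0.
#' @param t0 Initial stationary dwell before the pull (s), >= 0.
#' @param damping Viscous damping ratio of block motion relative to the
#'   stage (dimensionless); models internal dissipation in the finger pad
#'   and sets how fast post-slip ringing decays. It acts on the relative
#'   velocity so the steady-sliding force is exactly `mu_k0 * N`. The
#'   default 5 reflects a heavily overdamped elastomer pad: slip onset
#'   then produces only a small inertial overshoot.
#' @param accel_time Stage acceleration time (s): the stage velocity ramps
#'   linearly from 0 to `v` over this interval, as a real motorised stage
#'   does (default 0.06 s). A finite ramp matters: it keeps the inertial
#'   force overshoot at slip onset small, because slip typically starts
#'   while the stage is still slow.
#' @param noise_sd Gaussian electronic noise SD added to the measured
#'   force (newtons). Default 0.013 N so that ~3 sigma peak-to-peak matches
#'   the ~0.04 N noise floor of the instrument.
#' @param sampling_rate Output sampling rate (Hz), default 550.
#' @param oversample Internal integration runs at
#'   `oversample * sampling_rate` (default 10) to avoid event aliasing.
#' @param seed Optional integer seed applied before noise generation.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(normal_force, v, mass, mu_k0, k = 13900,
                       d_mu = 0, v_c = 0.01, aging_b = 0, theta0 = 0.01,
                       t0 = 0, damping = 5, accel_time = 0.06,
                       noise_sd = 0.013, sampling_rate = 550,
                       oversample = 10L, seed = NULL) {
  p <- list(normal_force = normal_force, v = v, mass = mass, mu_k0 = mu_k0,
            k = k, d_mu = d_mu, v_c = v_c, aging_b = aging_b,
            theta0 = theta0, t0 = t0, damping = damping,
            accel_time = accel_time, noise_sd = noise_sd,
            sampling_rate = sampling_rate, oversample = as.integer(oversample),
            seed = seed)
  with(p, {
    if (k <= 0 || normal_force <= 0 || mass <= 0 || v_c <= 0 || theta0 <= 0)
      abort("k, normal_force, mass, v_c and theta0 must be positive",
            "frinstab_validation_error")
    if (v < 0 || d_mu < 0 || aging_b < 0 || noise_sd < 0 || t0 < 0)
      abort("v, d_mu, aging_b, t0 and noise_sd must be nonnegative",
            "frinstab_validation_error")
  })
  structure(p, class = "sim_params")
}

#' Simulate one pull of the spring-block friction model
#'
#' Integrates the stuck/sliding dynamics with a fixed-step semi-implicit
#' Euler scheme at `oversample * sampling_rate`, then decimates the
#' measured spring force `F = k (X - x)` to the output rate and adds
#' Gaussian sensor noise. The stage runs at `v` until it has covered
#' `duration * v`; pass `drive_duration` smaller than `duration` to model
#' recording past the end of travel.
#'
#' While stuck the block holds position, so the measured force ramps at
#' exactly `dF/dX = k`; slip starts when the spring force reaches the
#' aged static threshold, and the block re-sticks (resetting the age) when
#' its velocity returns to zero.
#'
#' @param p A `sim_params` object.
#' @param duration Recording duration (s).
#' @param meta Optional named list overriding trace metadata fields
#'   (`surface_id`, `applied_mass`, `deadweight`, `velocity`,
#'   `displacement`, `set_index`, `pull_index`).
#' @param drive_duration Stage motion duration (s); default `duration`.
#' @return A `force_trace` with attribute `events`, a list carrying
#'   `first_slip_time` (s) and `first_slip_index` (output sample index) of
#'   the first stick-to-slip transition, or `NA` if the block never slips.
#' @export
simulate_trace <- function(p, duration, meta = list(),
                           drive_duration = duration) {
  stopifnot(inherits(p, "sim_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  fs <- p$sampling_rate
  dt <- 1 / (fs * p$oversample)
  n_hi <- max(2L * p$oversample, floor(duration * fs) * p$oversample)
  c_damp <- 2 * p$damping * sqrt(p$k * p$mass)
  N <- p$normal_force

  x <- 0; vx <- 0; theta <- p$t0; stuck <- TRUE
  f_hi <- numeric(n_hi)
  first_slip <- NA_integer_
  tau <- p$accel_time
  for (i in seq_len(n_hi)) {
    t <- min((i - 1) * dt, drive_duration)
    # stage: linear velocity ramp 0 -> v over tau, then constant v
    if (t < tau) {
      X <- p$v * t^2 / (2 * tau)
      v_stage <- p$v * t / tau
    } else {
      X <- p$v * (t - tau / 2)
      v_stage <- p$v
    }
    if ((i - 1) * dt >= drive_duration) v_stage <- 0
    f_el <- p$k * (X - x)
    if (stuck) {
      mu_s <- p$mu_k0 + p$d_mu + p$aging_b * log1p(theta / p$theta0)
      if (f_el >= mu_s * N && f_el > 0) {
        stuck <- FALSE
        # place the block exactly at the threshold: the within-step force
        # excess is a discretisation artifact, not a physical overshoot
        x <- X - mu_s * N / p$k
        f_el <- mu_s * N
        vx <- 0
        if (is.na(first_slip)) first_slip <- i
      } else {
        theta <- theta + dt
      }
    }
    if (!stuck) {
      mu_k <- p$mu_k0 + p$d_mu * exp(-vx / p$v_c)
      # damping handled implicitly: unconditionally stable at large ratios
      vx <- (vx + dt * ((f_el - mu_k * N) / p$mass +
                          c_damp * v_stage / p$mass)) /
            (1 + c_damp * dt / p$mass)
      if (vx <= 0) {
        stuck <- TRUE; vx <- 0; theta <- 0
      } else {
        x <- x + vx * dt
      }
    }
    if (!is.finite(f_el) || abs(f_el) > 1e6)
      abort(sprintf(paste("integration diverged at t=%.4f s",
                          "(k=%g, N=%g, m=%g, d_mu=%g, v_c=%g, aging_b=%g)"),
                    t, p$k, N, p$mass, p$d_mu, p$v_c, p$aging_b),
            "frinstab_integration_error")
    f_hi[i] <- f_el
  }

  idx <- seq(1L, n_hi, by = p$oversample)
  f_out <- f_hi[idx]
  if (p$noise_sd > 0) f_out <- f_out + stats::rnorm(length(f_out), 0, p$noise_sd)
  time <- (idx - 1) * dt

  defaults <- list(surface_id = "sim",
                   applied_mass = max(0, p$mass * 1000 - 6), deadweight = 6,
                   velocity = p$v * 1000, displacement = p$v * drive_duration * 1000,
                   set_index = 1L, pull_index = 2L)
  meta <- utils::modifyList(defaults, meta)
  tr <- force_trace(time, f_out, surface_id = meta$surface_id,
                    applied_mass = meta$applied_mass,
                    deadweight = meta$deadweight, velocity = meta$velocity,
                    displacement = meta$displacement, sampling_rate = fs,
                    set_index = meta$set_index, pull_index = meta$pull_index)
  out_slip <- if (is.na(first_slip)) NA_integer_
              else as.integer(ceiling((first_slip - 1) / p$oversample)) + 1L
  attr(tr, "events") <- list(first_slip_time = if (is.na(first_slip)) NA_real_
                                               else (first_slip - 1) * dt,
                             first_slip_index = out_slip)
  tr
}

#' Parameter templates guaranteeing each instability phenotype
#'
#' Builds a `sim_params` realising a requested phenotype at a grid
#' condition. Templates:
#' \describe{
#'   \item{SS}{no weakening, no aging: the force ramps, slips at
#'     `mu_k0 * N` and settles onto steady sliding.}
#'   \item{Sp}{strong aging with a long pre-slide dwell: the first slip
#'     threshold exceeds steady friction by `spike_ratio`, producing one
#'     large stiction spike followed by steady sliding.}
#'   \item{SFW}{velocity weakening with `v_c` tied to the drive velocity;
#'     the weakening depth is set to `k * v / (2 * N * wave_freq)` so the
#'     relaxation (stick-reload) cycle runs near `wave_freq`, inside the
#'     sub-50 Hz band the classifier inspects.}
#' }
#'
#' @param phenotype One of "SS", "SFW", "Sp".
#' @param applied_mass Applied mass (g).
#' @param velocity Drive velocity (mm/s).
#' @param mu_k0 Base kinetic friction coefficient (default 2, typical of
#'   the elastomer-on-silane contacts measured here).
#' @param deadweight Finger deadweight (g).
#' @param wave_freq Target SFW cycle frequency (Hz), or `NULL` (default)
#'   to adapt it to the pull duration: `clamp(3.2 * v / 4, 8, 36)` Hz,
#'   which fits at least ~3 cycles into the 4 mm pull at any drive
#'   velocity while staying below the 50 Hz analysis band edge. The field
#'   offers no canonical band separating slow waves from microscopic
#'   stick-slip timescales, so the cycle frequency is a free parameter of
#'   the generator.
#' @param spike_ratio First-peak to steady-force ratio for the Sp
#'   template (default 1.6, comfortably beyond the 1.10 detection
#'   threshold).
#' @param noise_sd Sensor noise SD (N); 0 for noiseless templates.
#' @param t0 Pre-slide dwell for the Sp template (s).
#' @param ... Further overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
phenotype_params <- function(phenotype = c("SS", "SFW", "Sp"),
                             applied_mass, velocity, mu_k0 = 2,
                             deadweight = 6, wave_freq = NULL,
                             spike_ratio = 1.6, noise_sd = 0.013,
                             t0 = 2, ...) {
  phenotype <- match.arg(phenotype)
  N <- normal_force(applied_mass, deadweight)
  v <- velocity / 1000
  m <- (applied_mass + deadweight) / 1000
  if (is.null(wave_freq)) wave_freq <- min(36, max(8, 3.2 * velocity / 4))
  base <- list(normal_force = N, v = v, mass = m, mu_k0 = mu_k0,
               noise_sd = noise_sd)
  # SS and Sp are the dissipative phenotypes (heavily damped pad); SFW
  # requires under-damping so that velocity weakening can sustain the
  # limit cycle. The cycle's force span saturates near 2 * d_mu * N, so
  # the reload time k*v / (2 * d_mu * N) sets the wave frequency. At
  # 45 mm/s a 4 mm pull is too short to resolve two sub-50 Hz cycles, so
  # the SFW guarantee holds for drive velocities up to 25 mm/s; faster
  # pulls realise as spike-type traces.
  extra <- switch(phenotype,
    SS = list(),
    Sp = list(aging_b = spike_ratio_to_b(spike_ratio, mu_k0, t0),
              theta0 = 0.01, t0 = t0),
    SFW = list(d_mu = 13900 * v / (2 * N * wave_freq), v_c = v, damping = 1)
  )
  do.call(sim_params, utils::modifyList(c(base, extra), list(...)))
}

# Aging gain giving first-slip threshold spike_ratio * mu_k0 after dwell t0.
spike_ratio_to_b <- function(spike_ratio, mu_k0, t0, theta0 = 0.01) {
  (spike_ratio - 1) * mu_k0 / log1p(t0 / theta0)
}

#' Regime specification: phenotype mixture per grid node
#'
#' Assigns to every (mass, velocity) node of a condition grid a weight
#' vector over the three phenotypes; pulls simulated at that node draw
#' their phenotype from those weights. This is how a synthetic surface's
#' instability phase map is prescribed.
#'
#' @param grid A `condition_grid`.
#' @param weights Numeric array `n_mass x n_velocity x 3` (third dimension
#'   named SS, SFW, Sp), nonnegative, each node summing to 1.
#' @param surface_id Name of the synthetic surface.
#' @param mu_k0 Base kinetic friction coefficient used at all nodes.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(grid, weights, surface_id = "synthetic", mu_k0 = 2) {
  stopifnot(inherits(grid, "condition_grid"))
  dims <- c(length(grid$masses), length(grid$velocities), 3L)
  if (!is.array(weights) || !identical(dim(weights), dims))
    abort(sprintf("weights must be a %d x %d x 3 array", dims[1], dims[2]),
          "frinstab_validation_error")
  if (any(weights < 0))
    abort("phenotype weights must be nonnegative", "frinstab_validation_error")
  sums <- apply(weights, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-8))
    abort("phenotype weights must sum to 1 at every node",
          "frinstab_validation_error")
  dimnames(weights) <- list(grid$masses, grid$velocities,
                            c("SS", "SFW", "Sp"))
  structure(list(grid = grid, weights = weights, surface_id = surface_id,
                 mu_k0 = mu_k0),
            class = "regime_spec")
}

#' Smooth demo regime: instability boundaries shifted per surface
#'
#' Emulates the qualitative structure of measured phase maps: steady
#' sliding dominates at low mass and velocity, slow frictional waves grow
#' toward high mass and velocity, and stiction spikes occur at a roughly
#' condition-independent base rate. The two offsets shift the SFW boundary
#' and the spike propensity, so different offsets produce surfaces with
#' different instability totals.
#'
#' @param grid A `condition_grid`.
#' @param sfw_offset Logit offset of the SFW boundary (higher = more SFW).
#' @param sp_offset Logit offset of spike propensity (higher = more Sp).
#' @param surface_id,mu_k0 Passed to [regime_spec()].
#' @return A `regime_spec`.
#' @export
demo_regime <- function(grid, sfw_offset = 0, sp_offset = 0,
                        surface_id = "synthetic", mu_k0 = 2) {
  nm <- length(grid$masses); nv <- length(grid$velocities)
  w <- array(0, c(nm, nv, 3))
  for (i in seq_len(nm)) for (j in seq_len(nv)) {
    z <- (i - 1) / max(1, nm - 1)   # normalised mass
    u <- (j - 1) / max(1, nv - 1)   # normalised velocity
    p_sfw <- stats::plogis(3 * (z + u - 1.2) + sfw_offset)
    p_sp <- stats::plogis(-1 + sp_offset) * (1 - p_sfw)
    w[i, j, ] <- c(1 - p_sfw - p_sp, p_sfw, p_sp)
  }
  regime_spec(grid, w, surface_id = surface_id, mu_k0 = mu_k0)
}

#' Simulate a full surface: every grid node, `n_reps` pulls each
#'
#' For each (mass, velocity) node the per-pull phenotype is drawn from the
#' regime weights; each pull is then integrated with the matching
#' template. All randomness is tied to `seed`: the phenotype draws use the
#' master seed and each pull's noise uses a child seed derived by counter,
#' so the same seed reproduces the same trace set exactly.
#'
#' Pulls are labelled set 1-3, pull 2-4 within each set, mirroring the
#' acquisition protocol of four slides per set with the first discarded
#' for contact aging (only retained pulls are generated).
#'
#' @param spec A `regime_spec`.
#' @param seed Integer seed.
#' @param noise_sd Sensor noise SD (N); set 0 for noiseless sets.
#' @param wave_freq Passed to [phenotype_params()].
#' @return List of `force_trace` objects (length
#'   `n_mass * n_velocity * n_reps`), each with attribute `phenotype`
#'   recording the generating template.
#' @export
simulate_surface <- function(spec, seed = 1L, noise_sd = 0.013,
                             wave_freq = 30) {
  stopifnot(inherits(spec, "regime_spec"))
  grid <- spec$grid
  if (grid$n_reps %% 3L == 0L) {
    sets <- rep(seq_len(grid$n_reps / 3L), each = 3L)
    pulls <- rep(2:4, grid$n_reps / 3L)
  } else {
    sets <- rep(1L, grid$n_reps)
    pulls <- seq_len(grid$n_reps) + 1L
  }
  set.seed(seed)
  labels <- c("SS", "SFW", "Sp")
  draws <- list()
  for (i in seq_along(grid$masses)) for (j in seq_along(grid$velocities)) {
    draws[[paste(i, j)]] <- sample(labels, grid$n_reps, replace = TRUE,
                                   prob = spec$weights[i, j, ])
  }
  traces <- vector("list", length(grid$masses) * length(grid$velocities) *
                             grid$n_reps)
  counter <- 0L
  for (i in seq_along(grid$masses)) for (j in seq_along(grid$velocities)) {
    M <- grid$masses[i]; v <- grid$velocities[j]
    phen <- draws[[paste(i, j)]]
    for (r in seq_len(grid$n_reps)) {
      counter <- counter + 1L
      p <- phenotype_params(phen[r], applied_mass = M, velocity = v,
                            mu_k0 = spec$mu_k0, wave_freq = wave_freq,
                            noise_sd = noise_sd,
                            seed = child_seed(seed, counter))
      # 4 mm displacement at v mm/s plus the half-ramp lost to acceleration
      duration <- 4 / v + p$accel_time / 2
      tr <- simulate_trace(p, duration,
                           meta = list(surface_id = spec$surface_id,
                                       applied_mass = M, velocity = v,
                                       displacement = 4,
                                       set_index = sets[r],
                                       pull_index = pulls[r]))
      attr(tr, "phenotype") <- phen[r]
      traces[[counter]] <- tr
    }
  }
  traces
}

#' Generate a self-affine (fractal) height map of known Hurst exponent
#'
#' Spectral synthesis: a white Gaussian field is filtered in the Fourier
#' domain with amplitude proportional to `|q|^-(1+H)` (the 2-D
#' self-affine scaling), inverse-transformed, then recentred and rescaled
#' so the sample rms equals `rms` exactly.
#'
#' @param H Hurst exponent, strictly inside (0, 1).
#' @param rms Target rms height (m).
#' @param n_pixels Grid side length (pixels).
#' @param pixel_size Pixel size (m); default covers a 10 um scan.
#' @param seed Integer seed.
#' @return A `height_map`.
#' @export
synth_heightmap <- function(H, rms, n_pixels = 256,
                            pixel_size = 10e-6 / n_pixels, seed = 1L) {
  if (!is_scalar_number(H) || H <= 0 || H >= 1)
    abort("H must lie strictly inside (0, 1)", "frinstab_validation_error")
  set.seed(seed)
  n <- as.integer(n_pixels)
  w <- matrix(stats::rnorm(n * n), n, n)
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * pixel_size)
  if (length(freq) != n) freq <- freq[seq_len(n)]
  qmag <- sqrt(outer(freq^2, freq^2, "+"))
  amp <- qmag
  amp[qmag > 0] <- qmag[qmag > 0]^(-(1 + H))
  amp[qmag == 0] <- 0
  h <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (n * n)
  h <- h - mean(h)
  h <- h * rms / sqrt(mean(h^2))
  height_map(h, pixel_size = pixel_size, scan_size = n * pixel_size)
}

#' Generate a synthetic 3-AFC behavioural table from a known mixed model
#'
#' Per subject a random intercept `u ~ N(0, sigma_subject^2)` is drawn;
#' per trial the success probability is
#' `plogis(beta0 + beta1 * x_pair + u)`. The odd sample's position is
#' uniform on 1-3; on an incorrect trial the chosen position is uniform
#' over the two non-odd positions. Response times are log-normal with
#' log-mean linear in a second predictor plus a per-subject intercept.
#'
#' @param predictors Named numeric vector: accuracy predictor value per
#'   pair label.
#' @param beta0,beta1 Fixed intercept and slope on the logit scale.
#' @param sigma_subject SD of the subject random intercept.
#' @param n_subjects Number of subjects.
#' @param n_trials_per_pair Trials per subject per pair.
#' @param seed Integer seed.
#' @param rt_predictors Named numeric vector for the response-time
#'   predictor (defaults to `predictors`).
#' @param rt_beta0,rt_beta1 Log-scale intercept and slope for response
#'   time (seconds).
#' @param rt_sigma Residual SD of log response time.
#' @param rt_subject_sd SD of the subject random intercept on log RT.
#' @return A `behavioral_table`; attribute `truth` records all generating
#'   parameters.
#' @export
synth_behavior <- function(predictors, beta0, beta1, sigma_subject,
                           n_subjects = 10, n_trials_per_pair = 10,
                           seed = 1L, rt_predictors = predictors,
                           rt_beta0 = log(5), rt_beta1 = 0,
                           rt_sigma = 0.3, rt_subject_sd = 0.1) {
  if (n_subjects < 1 || n_trials_per_pair < 1)
    abort("n_subjects and n_trials_per_pair must be >= 1",
          "frinstab_validation_error")
  if (is.null(names(predictors)))
    abort("predictors must be a named vector (names = pair labels)",
          "frinstab_validation_error")
  set.seed(seed)
  pairs <- names(predictors)
  u_acc <- stats::rnorm(n_subjects, 0, sigma_subject)
  u_rt <- stats::rnorm(n_subjects, 0, rt_subject_sd)
  rows <- expand.grid(trial = seq_len(n_trials_per_pair),
                      pair_label = pairs,
                      subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  si <- match(rows$subject_id, sprintf("S%02d", seq_len(n_subjects)))
  x <- predictors[rows$pair_label]
  p_correct <- stats::plogis(beta0 + beta1 * x + u_acc[si])
  correct <- stats::runif(n) < p_correct
  odd <- sample.int(3L, n, replace = TRUE)
  chosen <- odd
  wrong <- which(!correct)
  if (length(wrong)) {
    pick <- stats::runif(length(wrong)) < 0.5
    alt <- mapply(function(o, first) setdiff(1:3, o)[if (first) 1L else 2L],
                  odd[wrong], pick)
    chosen[wrong] <- alt
  }
  xr <- rt_predictors[rows$pair_label]
  rt <- exp(rt_beta0 + rt_beta1 * xr + u_rt[si] +
              stats::rnorm(n, 0, rt_sigma))
  tab <- behavioral_table(data.frame(
    subject_id = rows$subject_id, pair_label = rows$pair_label,
    odd_position = odd, chosen_position = chosen, correct = correct,
    response_time = rt, stringsAsFactors = FALSE))
  attr(tab, "truth") <- list(beta0 = beta0, beta1 = beta1,
                             sigma_subject = sigma_subject,
                             rt_beta0 = rt_beta0, rt_beta1 = rt_beta1,
                             rt_sigma = rt_sigma,
                             rt_subject_sd = rt_subject_sd,
                             predictors = predictors,
                             rt_predictors = rt_predictors)
  tab
}
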