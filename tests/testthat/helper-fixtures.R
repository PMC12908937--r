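# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Analytic ramp-then-plateau trace: force rises linearly for `n_ramp`
# samples at slope k*v, then stays at the plateau.
ramp_trace <- function(n_ramp = 100, n_total = 300, fs = 550,
                       velocity = 10, k = 13900) {
  kv <- k * velocity / 1000
  f <- c(kv * (seq_len(n_ramp) - 1) / fs,
         rep(kv * (n_ramp - 1) / fs, n_total - n_ramp))
  force_trace(time = (seq_len(n_total) - 1) / fs, force = f,
              surface_id = "ramp", applied_mass = 100, velocity = velocity,
              displacement = 4, sampling_rate = fs)
}

# Trace with a constant post-onset level plus an optional sinusoid.
plateau_trace <- function(level = 1, wave_amp = 0, wave_freq = 8,
                          duration = 2, fs = 550, applied_mass = 100) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  ramp_n <- 30
  f <- rep(level, length(t))
  f[seq_len(ramp_n)] <- level * (seq_len(ramp_n) - 1) / (ramp_n - 1)
  f <- f + wave_amp * sin(2 * pi * wave_freq * t)
  f[seq_len(ramp_n)] <- pmin(f[seq_len(ramp_n)], level)
  force_trace(time = t, force = f, surface_id = "plateau",
              applied_mass = applied_mass, velocity = 10, displacement = 20,
              sampling_rate = fs)
}

# Hand-built features for direct classifier-rule tests.
make_features <- function(first_peak, steady_mean, wave_amplitude = 0,
                          wave_count = 0L, noise_floor = 0.04, mu = 1) {
  structure(list(onset_index = 10L, first_peak = first_peak,
                 steady_mean = steady_mean, wave_amplitude = wave_amplitude,
                 wave_count = as.integer(wave_count),
                 noise_floor = noise_floor, mu = mu),
            class = "trace_features")
}

# Small classified table covering a grid exactly, with chosen labels.
synthetic_classified <- function(grid, label_fun) {
  rows <- list()
  for (i in seq_along(grid$masses)) for (j in seq_along(grid$velocities)) {
    for (r in seq_len(grid$n_reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        surface_id = "syn", applied_mass = grid$masses[i],
        velocity = grid$velocities[j],
        set_index = (r - 1L) %/% 3L + 1L, pull_index = (r - 1L) %% 3L + 2L,
        label = label_fun(i, j, r), first_peak = 1, steady_mean = 1,
        wave_amplitude = 0, wave_count = 0L, mu = 1, coexists_with = "",
        flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Independent brute-force oracle for the two-sided rank-sum p-value:
# enumerate every assignment of the pooled mid-ranks to group A.
rank_sum_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n)])
  ws <- apply(utils::combn(n + m, n), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
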