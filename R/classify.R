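#' Classifier thresholds
#'
#' The classification scheme is heuristic, so its thresholds are plain
#' configuration with the standard defaults: a first peak 10% above the
#' steady-sliding mean marks a stiction spike; when slow waves are
#' present, the first peak must instead exceed the wave envelope level by
#' 40%. Waves count as present when at least `wave_min_count` sub-50 Hz
#' oscillation peaks with mean amplitude at least `wave_min_amplitude`
#' (default twice the noise floor) are detected.
#'
#' @param spike_over_steady Spike threshold relative to steady mean.
#' @param spike_over_wave Spike threshold relative to the wave envelope
#'   level (steady mean + wave amplitude).
#' @param wave_min_count Minimum number of detected wave peaks.
#' @param wave_min_amplitude Minimum mean wave amplitude (N); default
#'   `2 * noise_floor`.
#' @param noise_floor Electronic noise floor, peak-to-peak (N).
#' @return Named list of thresholds.
#' @export
classifier_thresholds <- function(spike_over_steady = 1.10,
                                  spike_over_wave = 1.40,
                                  wave_min_count = 2L,
                                  wave_min_amplitude = NULL,
                                  noise_floor = 0.04) {
  if (is.null(wave_min_amplitude)) wave_min_amplitude <- 2 * noise_floor
  list(spike_over_steady = spike_over_steady,
       spike_over_wave = spike_over_wave,
       wave_min_count = as.integer(wave_min_count),
       wave_min_amplitude = wave_min_amplitude,
       noise_floor = noise_floor)
}

# Zero-phase low-pass Butterworth with odd-reflection padding to suppress
# boundary transients; skips filtering when the cutoff is at or above
# Nyquist.
lowpass <- function(x, fs, f_cut, order = 2) {
  wn <- f_cut / (fs / 2)
  if (wn >= 1) return(x)
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 * fs / f_cut))
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  bf <- signal::butter(order, wn, type = "low")
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  y[(npad + 1):(npad + n)]
}

#' Detect the onset of sliding in a force trace
#'
#' The pull starts with a linear loading ramp of slope `k * v` (the block
#' is stuck, so force tracks stage motion through the sensor stiffness);
#' sliding onset ends the ramp. The detector low-pass filters the force
#' (cutoff the lower of 50 Hz and 10 cycles per drive duration) and
#' returns the first prominent local maximum; for monotone-to-plateau
#' traces with no such maximum it returns the first index where the
#' smoothed slope drops below 10% of `k * v`.
#'
#' @param trace A `force_trace` (length >= 10).
#' @param noise_floor Peak-to-peak electronic noise floor (N).
#' @param k Sensor/loading stiffness (N/m), for the slope criterion.
#' @return Integer sample index of the onset.
#' @export
detect_onset <- function(trace, noise_floor = 0.04, k = 13900) {
  f <- trace$force
  if (length(f) < 10L)
    abort("trace too short for onset detection (need >= 10 samples)",
          "frinstab_validation_error")
  fs <- trace$meta$sampling_rate
  v <- trace$meta$velocity / 1000               # m/s
  t_drive <- trace$meta$displacement / trace$meta$velocity  # s
  f_cut <- min(50, 10 / t_drive)
  ff <- lowpass(f, fs, f_cut)
  if (max(abs(ff)) <= noise_floor)
    abort("trace lies entirely within the noise floor: no sliding detected",
          "frinstab_no_slide")

  thresh <- max(2 * noise_floor, 0.05 * diff(range(ff)))
  n <- length(ff)
  peaks <- which(diff(sign(diff(ff))) < 0) + 1L
  for (p in peaks) {
    after <- ff[p:n]
    reexceed <- which(after > ff[p])
    seg_end <- if (length(reexceed)) p + reexceed[1] - 1L else n
    if (ff[p] - min(ff[p:seg_end]) >= thresh) return(p)
  }

  # monotone-to-plateau: knee where the smoothed slope leaves the ramp
  ma <- stats::filter(f, rep(1 / 5, 5), sides = 2)
  slope <- c(diff(ma), NA) * fs
  kv <- k * v
  loaded <- which(slope >= 0.5 * kv)[1]
  if (is.na(loaded)) {
    # loading ramp faster than the sampling can resolve: sliding starts
    # essentially at the first sample above half the plateau level
    return(max(1L, which(ff >= 0.5 * max(ff))[1]))
  }
  knee <- which(slope[seq(loaded, n)] < 0.1 * kv)[1]
  if (is.na(knee)) return(which.max(ff))
  loaded + knee - 1L
}

#' Extract classification features from a force trace
#'
#' Computes the quantities the instability rules operate on: the first
#' peak (maximum force within `w` samples of onset), the steady-sliding
#' mean (mean force from `onset + 3w` onward), the slow-wave amplitude
#' and count (baseline-to-peak amplitudes of oscillation peaks in the
#' post-peak segment after band-limiting to below 50 Hz and above two
#' cycles per segment), and the friction coefficient (steady mean divided
#' by normal force).
#'
#' @param trace A `force_trace`.
#' @param onset Onset sample index, from [detect_onset()].
#' @param noise_floor Peak-to-peak noise floor (N).
#' @param w Half-width of the first-peak window, samples.
#' @return An object of class `trace_features`.
#' @export
extract_features <- function(trace, onset, noise_floor = 0.04, w = 5L) {
  f <- trace$force
  n <- length(f)
  if (onset < 1L || onset > n)
    abort("onset index outside the trace", "frinstab_validation_error")
  post_start <- onset + 3L * w
  if (n - post_start + 1L < 3L * w)
    abort("post-onset segment shorter than 3w samples: cannot extract features",
          "frinstab_feature_error")
  fs <- trace$meta$sampling_rate
  first_peak <- max(f[max(1L, onset - w):min(n, onset + w)])
  post <- f[post_start:n]
  steady_mean <- mean(post)

  y <- post - steady_mean
  n1 <- length(y)
  t_seg <- n1 / fs
  f_lo <- 2 / t_seg
  freq <- (seq_len(n1) - 1) / n1 * fs
  fm <- pmin(freq, fs - freq)
  mask <- as.numeric(fm > f_lo & fm < 50)
  y_bl <- Re(stats::fft(stats::fft(y) * mask, inverse = TRUE)) / n1

  min_h <- noise_floor / 2
  pk <- which(diff(sign(diff(y_bl))) < 0) + 1L
  pk <- pk[y_bl[pk] >= min_h]
  wave_amplitude <- if (length(pk)) mean(y_bl[pk]) else 0
  wave_count <- length(pk)

  N <- normal_force(trace$meta$applied_mass, trace$meta$deadweight)
  structure(list(onset_index = as.integer(onset),
                 first_peak = first_peak,
                 steady_mean = steady_mean,
                 wave_amplitude = wave_amplitude,
                 wave_count = as.integer(wave_count),
                 noise_floor = noise_floor,
                 mu = steady_mean / N),
            class = "trace_features")
}

#' Classify features into an instability label
#'
#' Deterministic decision order, ties at exact threshold equality going to
#' the spike/wave (>=, not >):
#' \enumerate{
#'   \item waves present := `wave_count >= wave_min_count` and
#'     `wave_amplitude >= wave_min_amplitude`;
#'   \item if waves present and
#'     `first_peak >= spike_over_wave * (steady_mean + wave_amplitude)`:
#'     stiction spike coexisting with slow frictional waves;
#'   \item else if waves absent and
#'     `first_peak >= spike_over_steady * steady_mean`: stiction spike
#'     coexisting with steady sliding;
#'   \item else slow frictional wave if waves present;
#'   \item else steady sliding.
#' }
#'
#' In both spike branches the excess of the first peak over the reference
#' level must also reach the electronic noise floor: a relative spike
#' smaller than sensor noise carries no evidence. Because the guard is
#' expressed in units of `noise_floor`, classification remains equivariant
#' under a joint rescaling of force and noise floor.
#'
#' @param features A `trace_features` object.
#' @param thresholds See [classifier_thresholds()].
#' @return An object of class `classified_trace` with elements `label`
#'   ("SS", "SFW" or "Sp"), `coexists_with` (what follows the spike;
#'   empty unless `label == "Sp"`), and `features`.
#' @export
classify_trace <- function(features, thresholds = classifier_thresholds()) {
  th <- thresholds
  waves <- features$wave_count >= th$wave_min_count &&
    features$wave_amplitude >= th$wave_min_amplitude
  floor_ok <- function(ref) features$first_peak - ref >= th$noise_floor
  if (waves &&
      features$first_peak >= th$spike_over_wave *
        (features$steady_mean + features$wave_amplitude) &&
      floor_ok(features$steady_mean + features$wave_amplitude)) {
    label <- "Sp"; co <- "SFW"
  } else if (!waves &&
             features$first_peak >= th$spike_over_steady *
               features$steady_mean &&
             floor_ok(features$steady_mean)) {
    label <- "Sp"; co <- "SS"
  } else if (waves) {
    label <- "SFW"; co <- character(0)
  } else {
    label <- "SS"; co <- character(0)
  }
  structure(list(label = label, coexists_with = co, features = features),
            class = "classified_trace")
}

#' @export
print.classified_trace <- function(x, ...) {
  co <- if (length(x$coexists_with))
    paste0(" (over ", paste(x$coexists_with, collapse = "+"), ")") else ""
  cat(sprintf("<classified_trace> %s%s  peak %.3f N, steady %.3f N, waves %d x %.3f N, mu %.3f\n",
              x$label, co, x$features$first_peak, x$features$steady_mean,
              x$features$wave_count, x$features$wave_amplitude,
              x$features$mu))
  invisible(x)
}

#' Classify a single pull end to end
#'
#' Runs onset detection, feature extraction and the label rules on one
#' trace.
#'
#' @param trace A `force_trace`.
#' @param thresholds See [classifier_thresholds()].
#' @param k Loading stiffness for onset detection (N/m).
#' @return A `classified_trace`.
#' @export
classify_pull <- function(trace, thresholds = classifier_thresholds(),
                          k = 13900) {
  onset <- detect_onset(trace, noise_floor = thresholds$noise_floor, k = k)
  feats <- extract_features(trace, onset,
                            noise_floor = thresholds$noise_floor)
  classify_trace(feats, thresholds)
}

#' Classify a set of pulls into a tidy table
#'
#' First pulls of a set (`pull_index == 1`) are excluded from
#' classification and only flagged, since they carry contact aging from
#' setup preparation.
#'
#' @param traces List of `force_trace` objects.
#' @param thresholds See [classifier_thresholds()].
#' @param k Loading stiffness (N/m).
#' @return Data frame with one row per pull: metadata, the label, the
#'   extracted features, the friction coefficient, the coexistence flag
#'   and a `flagged` column marking excluded first pulls.
#' @export
classify_traces <- function(traces, thresholds = classifier_thresholds(),
                            k = 13900) {
  rows <- lapply(traces, function(tr) {
    m <- tr$meta
    base <- data.frame(surface_id = m$surface_id,
                       applied_mass = m$applied_mass,
                       velocity = m$velocity, set_index = m$set_index,
                       pull_index = m$pull_index,
                       stringsAsFactors = FALSE)
    if (m$pull_index == 1L) {
      cbind(base, data.frame(label = NA_character_, first_peak = NA_real_,
                             steady_mean = NA_real_, wave_amplitude = NA_real_,
                             wave_count = NA_integer_, mu = NA_real_,
                             coexists_with = NA_character_, flagged = TRUE,
                             stringsAsFactors = FALSE))
    } else {
      cl <- classify_pull(tr, thresholds, k)
      ft <- cl$features
      cbind(base, data.frame(label = cl$label, first_peak = ft$first_peak,
                             steady_mean = ft$steady_mean,
                             wave_amplitude = ft$wave_amplitude,
                             wave_count = ft$wave_count, mu = ft$mu,
                             coexists_with = paste(cl$coexists_with,
                                                   collapse = "+"),
                             flagged = FALSE, stringsAsFactors = FALSE))
    }
  })
  do.call(rbind, rows)
}

#' Friction coefficient summary over a complete condition grid
#'
#' The average friction coefficient is the mean of the 16 per-condition
#' means (each condition mean taken over its retained pulls); the
#' interquartile range is Q3 - Q1 over all per-pull coefficients (linear
#' interpolation quantiles), so it captures the spread of friction across
#' conditions on a single surface.
#'
#' @param classified Data frame from [classify_traces()] (one surface).
#' @param grid A `condition_grid`.
#' @return List with `mu_bar` and `iqr`.
#' @export
aggregate_mu <- function(classified, grid) {
  df <- classified[!classified$flagged & !is.na(classified$mu), , drop = FALSE]
  counts <- table(factor(df$applied_mass, levels = grid$masses),
                  factor(df$velocity, levels = grid$velocities))
  if (any(counts != grid$n_reps))
    abort("condition grid incomplete: cannot aggregate friction coefficients",
          "frinstab_completeness_error")
  cond_means <- tapply(df$mu, list(df$applied_mass, df$velocity), mean)
  mu_bar <- mean(cond_means)
  qs <- stats::quantile(df$mu, c(0.25, 0.75), type = 7, names = FALSE)
  list(mu_bar = mu_bar, iqr = qs[2] - qs[1])
}
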