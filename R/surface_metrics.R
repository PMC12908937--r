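#' Flatten an AFM height map
#'
#' Standard AFM post-processing before roughness or spectral analysis:
#' least-squares removal of a 2-D polynomial background of total degree 3
#' (all 10 monomials in the two scan coordinates), then subtraction of
#' each fast-scan line's median (rows are fast-scan lines), which also
#' serves as the scan-line (stroke) correction, and finally recentring to
#' zero mean. Aggregates are not masked.
#'
#' @param hm A `height_map` at least 8 x 8 pixels.
#' @return A flattened `height_map`.
#' @export
flatten_heightmap <- function(hm) {
  h <- hm$heights
  if (nrow(h) < 8L || ncol(h) < 8L)
    abort("height map must be at least 8 x 8", "frinstab_validation_error")
  if (stats::sd(as.vector(h)) == 0) {
    warning("degenerate (constant) height map; returning zero map")
    return(height_map(h * 0, hm$pixel_size, hm$scan_size))
  }
  # coordinates scaled to [-1, 1] for numerical conditioning
  u <- seq(-1, 1, length.out = nrow(h))
  v <- seq(-1, 1, length.out = ncol(h))
  U <- as.vector(matrix(u, nrow(h), ncol(h)))
  V <- as.vector(matrix(v, nrow(h), ncol(h), byrow = TRUE))
  X <- cbind(1, U, V, U^2, U * V, V^2, U^3, U^2 * V, U * V^2, V^3)
  fit <- stats::lm.fit(X, as.vector(h))
  res <- matrix(fit$residuals, nrow(h), ncol(h))
  res <- res - apply(res, 1, stats::median)
  res <- res - mean(res)
  height_map(res, hm$pixel_size, hm$scan_size)
}

#' Roughness descriptors of a (flattened) height map
#'
#' `Ra` is the mean absolute height and `Rrms` the root-mean-square
#' height, both about the map mean. `Ra <= Rrms` always.
#'
#' @param hm A `height_map`, normally flattened first.
#' @return List with `Ra` and `Rrms` in meters.
#' @export
roughness <- function(hm) {
  h <- hm$heights - mean(hm$heights)
  list(Ra = mean(abs(h)), Rrms = sqrt(mean(h^2)))
}

#' Hurst exponent from the line-averaged power spectral density
#'
#' Each fast-scan line is Hann-windowed and its periodogram computed; the
#' periodograms are averaged over all lines and the log-log slope of
#' power versus wavenumber is fit over the central band (excluding the
#' lowest 3 and the highest 25% of wavenumber bins, where flattening and
#' noise/pixelation dominate). For a self-affine profile the 1-D PSD
#' scales as `q^-(1 + 2H)`, so `H = (|slope| - 1) / 2`. Estimates outside
#' (0, 1) are clipped to the boundary and flagged.
#'
#' @param hm A `height_map`, normally flattened first.
#' @return List with `H`, `clipped` (logical) and `psd_fit`
#'   (`slope`, `intercept` on log10 scales, and the fitted `q_range` in
#'   cycles/m).
#' @export
hurst_exponent <- function(hm) {
  h <- hm$heights
  n <- ncol(h)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))  # Hann
  hw <- sweep(h, 2, win, `*`)
  spec <- t(apply(hw, 1, function(row) Mod(stats::fft(row))^2))
  nq <- n %/% 2
  psd <- colMeans(spec)[2:(nq + 1)]
  q <- (1:nq) / (n * hm$pixel_size)
  keep <- seq_len(nq) > 3 & seq_len(nq) <= floor(0.75 * nq)
  if (sum(keep) < 8L)
    abort("fewer than 8 usable wavenumber bins: grid too small for PSD fit",
          "frinstab_fit_error")
  lx <- log10(q[keep]); ly <- log10(psd[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  slope <- fit$coefficients[2]
  H <- (abs(slope) - 1) / 2
  clipped <- H <= 0 || H >= 1
  H <- min(max(H, 0), 1)
  list(H = as.numeric(H), clipped = clipped,
       psd_fit = list(slope = as.numeric(slope),
                      intercept = as.numeric(fit$coefficients[1]),
                      q_range = range(q[keep])))
}

#' Contact-angle hysteresis summary
#'
#' Per droplet the hysteresis is advancing minus receding angle; the
#' summary reports the mean advancing and receding angles, the mean
#' hysteresis and its sample SD. A droplet with receding above advancing
#' is physically suspect: it is kept but triggers a warning.
#'
#' @param advancing,receding Paired numeric vectors of angles in degrees,
#'   one entry per droplet (typically 5).
#' @return List with `advancing_mean`, `receding_mean`, `hysteresis_mean`,
#'   `hysteresis_sd` and `n_droplets`.
#' @export
contact_angle_hysteresis <- function(advancing, receding) {
  if (length(advancing) != length(receding))
    abort("advancing and receding must be paired (equal length)",
          "frinstab_validation_error")
  if (length(advancing) < 1L)
    abort("need at least one droplet", "frinstab_validation_error")
  hyst <- advancing - receding
  if (any(hyst < 0))
    warning(sprintf("%d droplet(s) with receding > advancing kept but flagged",
                    sum(hyst < 0)))
  list(advancing_mean = mean(advancing), receding_mean = mean(receding),
       hysteresis_mean = mean(hyst),
       hysteresis_sd = if (length(hyst) > 1) stats::sd(hyst) else NA_real_,
       n_droplets = length(advancing))
}

#' All surface descriptors in one call
#'
#' Flattens the height map, then computes roughness, the PSD Hurst
#' exponent and (if angles are given) the contact-angle hysteresis.
#'
#' @param hm A raw `height_map`.
#' @param advancing,receding Optional contact-angle vectors (degrees).
#' @return An object of class `surface_metrics`.
#' @export
surface_metrics <- function(hm, advancing = NULL, receding = NULL) {
  flat <- flatten_heightmap(hm)
  rg <- roughness(flat)
  hu <- hurst_exponent(flat)
  cah <- if (!is.null(advancing) && !is.null(receding))
    contact_angle_hysteresis(advancing, receding) else NULL
  structure(list(Ra = rg$Ra, Rrms = rg$Rrms, hurst = hu$H,
                 hurst_clipped = hu$clipped, psd_fit = hu$psd_fit,
                 cah = cah),
            class = "surface_metrics")
}

#' @export
print.surface_metrics <- function(x, ...) {
  cat(sprintf("<surface_metrics> Ra %.3g m, Rrms %.3g m, H %.2f%s\n",
              x$Ra, x$Rrms, x$hurst,
              if (x$hurst_clipped) " (clipped)" else ""))
  if (!is.null(x$cah))
    cat(sprintf("  contact angle %.2f - %.2f deg, hysteresis %.2f +/- %.2f (n=%d)\n",
                x$cah$advancing_mean, x$cah$receding_mean,
                x$cah$hysteresis_mean, x$cah$hysteresis_sd,
                x$cah$n_droplets))
  invisible(x)
}
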