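#' Finite-difference current source density
#'
#' `CSD(x) = (phi(x+h) - 2 phi(x) + phi(x-h)) / h^2` at interior contacts of
#' an equally spaced laminar probe; the two end contacts are undefined (not
#' extrapolated). The formula is implemented exactly as printed; set
#' `sink_negative = TRUE` to flip the sign so that current sinks are
#' negative, the usual physiological plotting convention.
#'
#' @param phi per-channel voltage values, superficial first.
#' @param spacing_um contact spacing h (150 um).
#' @param sink_negative flip the sign for the sink/source convention.
#' @return Numeric vector of length `length(phi) - 2` (interior contacts).
#' @export
csd_finite_difference <- function(phi, spacing_um = 150,
                                  sink_negative = FALSE) {
  n <- length(phi)
  if (n < 3) stop("CSD needs at least 3 channels")
  h <- spacing_um
  out <- (phi[3:n] - 2 * phi[2:(n - 1)] + phi[1:(n - 2)]) / h^2
  if (sink_negative) -out else out
}

#' Channel signal-to-noise ratio
#'
#' `SNR = (Signal - Noise) / sigma_noise`, evaluated in each of the eight
#' 50 ms response windows (30-80 ms to 100-150 ms after stimulus onset, in
#' 10 ms steps); the channel passes when the maximum SNR exceeds 3
#' (strictly).
#'
#' @param signal_window_means mean MUAe amplitude per response window
#'   (typically eight values).
#' @param noise_mean,noise_sd baseline mean and standard deviation.
#' @param threshold inclusion threshold (3).
#' @return List with `snr` (per window), `max_snr`, `pass`.
#' @export
snr <- function(signal_window_means, noise_mean, noise_sd, threshold = 3) {
  if (noise_sd <= 0) stop("noise SD must be positive")
  s <- (signal_window_means - noise_mean) / noise_sd
  list(snr = s, max_snr = max(s), pass = max(s) > threshold)
}

# rule shared by the fit and its oracle: latency is the earliest time where
# y(t) reaches 33% of the maximum of the earliest peak (first local maximum
# of the curve, or its overall maximum when the response is monotone).
latency_from_curve <- function(t, y, fraction = 0.33) {
  dy <- diff(y)
  peaks <- which(dy[-length(dy)] > 0 & dy[-1] <= 0) + 1L
  peak_val <- if (length(peaks)) y[peaks[1L]] else max(y)
  thr <- fraction * peak_val
  idx <- which(y >= thr)
  if (!length(idx)) return(NA_real_)
  t[idx[1L]]
}

#' Fit the parametric response-latency model
#'
#' Nonlinear least squares of [latency_model()] (sum of an exponentially
#' dissipating and a sustained cumulative-Gaussian component) to an average
#' MUAe trace, with `n_starts` multi-starts spanning the trace's rise region.
#' The response latency is the earliest time where the fitted curve reaches
#' 33% of the maximum of its earliest peak -- a relative threshold, so the
#' latency is invariant to amplitude rescaling.
#'
#' @param trace average MUAe time course.
#' @param t_grid time axis (ms), same length as `trace`.
#' @param n_starts number of random/spread starts (20).
#' @return An object of class `latency_fit`: `mu`, `sigma`, `alpha`, `c`,
#'   `d`, `latency_ms`, `residual` (RMS), `converged`. A flat trace (no
#'   response) yields `converged = FALSE` and `NA` latency.
#' @export
fit_latency <- function(trace, t_grid, n_starts = 20) {
  stopifnot(length(trace) == length(t_grid))
  scale <- max(abs(trace))
  dynamic <- diff(range(trace))
  if (scale == 0 || dynamic < 1e-6 * max(scale, 1)) {
    return(structure(list(mu = NA_real_, sigma = NA_real_, alpha = NA_real_,
                          c = NA_real_, d = NA_real_, latency_ms = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "latency_fit"))
  }
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); alpha <- exp(par[3])
    y <- latency_model(t_grid, mu, sigma, alpha, par[4], par[5])
    sum((y - trace)^2)
  }
  # starts span the rise region of the trace
  rise <- t_grid[which(trace >= min(trace) + 0.5 * dynamic)[1L]]
  mus <- seq(max(min(t_grid), rise - 40), rise + 20, length.out = 5)
  sigmas <- c(3, 8, 15)
  starts <- expand.grid(mu = mus, lsigma = log(sigmas), lalpha = log(0.02))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$mu[i], starts$lsigma[i], starts$lalpha[i], dynamic, 0)
    fit <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(mu = NA_real_, sigma = NA_real_, alpha = NA_real_,
                          c = NA_real_, d = NA_real_, latency_ms = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "latency_fit"))
  }
  mu <- best$par[1]; sigma <- exp(best$par[2]); alpha <- exp(best$par[3])
  cc <- best$par[4]; dd <- best$par[5]
  tt <- seq(min(t_grid), max(t_grid), by = 0.1)
  yfit <- latency_model(tt, mu, sigma, alpha, cc, dd)
  latency <- latency_from_curve(tt, yfit)
  structure(list(mu = mu, sigma = sigma, alpha = alpha, c = cc, d = dd,
                 latency_ms = latency,
                 residual = sqrt(best$value / length(trace)),
                 converged = is.finite(latency)),
            class = "latency_fit")
}

#' Assign probe contacts to laminar compartments
#'
#' Compartments relative to the granular (input-layer) reference channel,
#' identified externally from the earliest CSD sink or earliest latency.
#' V1 bands: supragranular 0.25-1 mm above the reference, granular within
#' +-0.25 mm, infragranular 0.25-0.75 mm below. V4 bands: supragranular
#' 0.1-1 mm above, granular within +-0.1 mm, infragranular 0.1-0.75 mm
#' below. Spiking overrides: a channel beyond the supragranular (resp.
#' infragranular) band that still shows clear spiking is pulled into that
#' compartment; a channel inside the supragranular band without spiking,
#' with no spiking on any contact above it, is `outside`.
#'
#' @param reference_channel 0-based index of the granular reference contact.
#' @param n_channels probe size.
#' @param area `"V1"` or `"V4"`.
#' @param spacing_um contact spacing (150 um).
#' @param spiking optional logical vector: clear spiking per contact.
#' @return An object of class `layer_assignment`: character vector of
#'   compartments (`supragranular`, `granular`, `infragranular`, `outside`),
#'   one per contact, with attributes `reference_channel` and `area`.
#' @export
assign_layers <- function(reference_channel, n_channels = 16L,
                          area = c("V1", "V4"), spacing_um = 150,
                          spiking = NULL) {
  area <- match.arg(area)
  if (reference_channel < 0 || reference_channel >= n_channels)
    stop("reference channel outside probe")
  ch <- seq_len(n_channels) - 1L
  # contact 0 is most superficial, so smaller index = above the reference
  rel_um <- (reference_channel - ch) * spacing_um     # positive = above
  gran_hw <- if (area == "V1") 250 else 100
  labels <- rep("outside", n_channels)
  labels[abs(rel_um) <= gran_hw] <- "granular"
  labels[rel_um > gran_hw & rel_um <= 1000] <- "supragranular"
  labels[rel_um < -gran_hw & rel_um >= -750] <- "infragranular"
  if (!is.null(spiking)) {
    stopifnot(length(spiking) == n_channels)
    labels[rel_um > 1000 & spiking] <- "supragranular"
    labels[rel_um < -750 & spiking] <- "infragranular"
    # non-spiking supragranular contacts with only non-spiking contacts
    # above them are outside the cortex
    for (i in seq_len(n_channels)) {
      if (labels[i] == "supragranular" && !spiking[i] &&
          (i == 1L || !any(spiking[seq_len(i - 1L)])))
        labels[i] <- "outside"
    }
  }
  structure(labels, reference_channel = reference_channel, area = area,
            class = "layer_assignment")
}

#' Receptive-field z-map and contour mask
#'
#' Converts a stimulus-position response map to z-scores against the
#' baseline, then returns the 4-connected region of `z >= threshold` cells
#' containing the peak.
#'
#' @param response_map matrix of per-position mean responses.
#' @param baseline_mean,baseline_sd baseline statistics (`baseline_sd > 0`).
#' @param threshold z threshold for the contour (3).
#' @return List with `z` (matrix), `mask` (logical matrix), `flagged`
#'   (`TRUE` when the peak is below threshold and the mask is empty).
#' @export
rf_zmap <- function(response_map, baseline_mean, baseline_sd, threshold = 3) {
  if (baseline_sd <= 0) stop("baseline SD must be positive")
  z <- (response_map - baseline_mean) / baseline_sd
  peak <- which(z == max(z), arr.ind = TRUE)[1, ]
  mask <- matrix(FALSE, nrow(z), ncol(z))
  if (z[peak[1], peak[2]] < threshold)
    return(list(z = z, mask = mask, flagged = TRUE))
  above <- z >= threshold
  # flood fill (4-connectivity) from the peak
  queue <- list(peak)
  mask[peak[1], peak[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(z) && q[2] >= 1 && q[2] <= ncol(z) &&
          above[q[1], q[2]] && !mask[q[1], q[2]]) {
        mask[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  list(z = z, mask = mask, flagged = FALSE)
}
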