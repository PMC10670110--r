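#' Configuration for the hemodynamic signal generator
#'
#' Collects the knobs of the synthetic OxyHb generator. The neural
#' component is a zero-mean multivariate normal whose covariance is
#' `identity + coupling_strength * adjacency` of a latent graph; the
#' nuisance components emulate what contaminates real fNIRS recordings:
#' physiological oscillations (cardiac ~1.2 Hz, respiration ~0.25 Hz,
#' Mayer waves ~0.1 Hz, each with a per-channel random phase), 1/f pink
#' noise, per-channel linear drift, and sparse spike artifacts.
#'
#' @param sampling_rate sampling frequency in Hz (default 25.6).
#' @param coupling_strength unitless covariance weight applied to the
#'   latent adjacency (default 0.6).
#' @param physio_components named list of `c(frequency_hz, amplitude)`
#'   pairs added as sinusoids (amplitudes in concentration units, >= 0).
#' @param noise_sd standard deviation of the additive pink noise
#'   (concentration units).
#' @param drift_slope per-channel linear drift slopes are drawn from
#'   `N(0, drift_slope)` (units/s).
#' @param artifact_rate expected spike artifacts per channel per minute.
#' @param seed optional integer seed.
#' @return an object of class `signal_gen_config`.
#' @export
signal_gen_config <- function(sampling_rate = 25.6,
                              coupling_strength = 0.6,
                              physio_components = list(cardiac = c(1.2, 0.25),
                                                       respiration = c(0.25, 0.15),
                                                       mayer = c(0.10, 0.15)),
                              noise_sd = 0.3,
                              drift_slope = 0.005,
                              artifact_rate = 0.5,
                              seed = NULL) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  for (pc in physio_components) {
    if (length(pc) != 2 || pc[2] < 0) stop("each physio component must be c(frequency_hz, amplitude >= 0)")
    if (sampling_rate <= 2 * pc[1]) stop("sampling_rate must exceed twice every physio frequency")
  }
  if (noise_sd < 0 || artifact_rate < 0) stop("noise_sd and artifact_rate must be >= 0")
  structure(
    list(sampling_rate = sampling_rate, coupling_strength = coupling_strength,
         physio_components = physio_components, noise_sd = noise_sd,
         drift_slope = drift_slope, artifact_rate = artifact_rate, seed = seed),
    class = "signal_gen_config"
  )
}

#' Multichannel hemodynamic recording container
#'
#' @param data numeric matrix, time points in rows, channels in columns.
#' @param sampling_rate sampling frequency in Hz.
#' @param channels optional channel labels.
#' @return an object of class `hemo_recording`.
#' @export
hemo_recording <- function(data, sampling_rate, channels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording must be finite")
  channels <- channels %||% sprintf("CH%02d", seq_len(ncol(data)))
  colnames(data) <- channels
  structure(list(data = data, sampling_rate = sampling_rate, channels = channels),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("hemo_recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate))
  invisible(x)
}

# covariance of the neural component: identity + coupling * adjacency,
# projected onto the positive-definite cone by eigenvalue clipping
latent_covariance <- function(adjacency, coupling_strength, floor = 1e-6) {
  n <- nrow(adjacency)
  sigma <- diag(n) + coupling_strength * adjacency
  project_pd(sigma, floor)
}

project_pd <- function(sigma, floor = 1e-6) {
  es <- eigen(sigma, symmetric = TRUE)
  if (any(es$values < floor)) {
    sigma <- es$vectors %*% (pmax(es$values, floor) * t(es$vectors))
    sigma <- (sigma + t(sigma)) / 2
  }
  if (any(!is.finite(sigma))) stop("latent covariance could not be projected to positive definite")
  sigma
}

# 1/f-shaped noise via spectral shaping of white noise
pink_noise <- function(n, sd = 1) {
  if (sd == 0) return(numeric(n))
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# nuisance components shared by all generator entry points
nuisance_components <- function(n_t, n_ch, config) {
  fs <- config$sampling_rate
  t <- (seq_len(n_t) - 1) / fs
  out <- matrix(0, n_t, n_ch)
  for (pc in config$physio_components) {
    phase <- runif(n_ch, 0, 2 * pi)
    out <- out + pc[2] * sin(outer(t, rep(2 * pi * pc[1], n_ch)) +
                               matrix(phase, n_t, n_ch, byrow = TRUE))
  }
  if (config$noise_sd > 0) {
    for (ch in seq_len(n_ch)) out[, ch] <- out[, ch] + pink_noise(n_t, config$noise_sd)
  }
  if (config$drift_slope > 0) {
    slopes <- rnorm(n_ch, 0, config$drift_slope)
    out <- out + outer(t, slopes)
  }
  if (config$artifact_rate > 0) {
    tau <- 0.3 * fs # spike decay constant, samples
    for (ch in seq_len(n_ch)) {
      n_ev <- rpois(1, config$artifact_rate * n_t / fs / 60)
      if (n_ev == 0) next
      at <- sample.int(n_t, n_ev)
      amp <- sample(c(-1, 1), n_ev, replace = TRUE) * (5 + rexp(n_ev, 1)) * max(config$noise_sd, 0.1)
      for (e in seq_len(n_ev)) {
        span <- at[e]:min(n_t, at[e] + ceiling(5 * tau))
        out[span, ch] <- out[span, ch] + amp[e] * exp(-(span - at[e]) / tau)
      }
    }
  }
  out
}

#' Generate a synthetic OxyHb recording from a latent graph
#'
#' Samples channels from a zero-mean multivariate normal whose covariance
#' is `identity + coupling_strength * adjacency` (eigenvalue-clipped to
#' positive definite), so channel pairs joined in the latent graph are more
#' correlated than unconnected pairs, then adds the configured
#' physiological sinusoids, pink noise, linear drift and spike artifacts.
#' Generation is fully reproducible under the config seed.
#'
#' @param network a [make_ws_graph()] object (or adjacency matrix).
#' @param config a [signal_gen_config()].
#' @param duration_s recording length in seconds (>= 5, one online window).
#' @return a [hemo_recording()] with the latent network attached as
#'   attribute `"network"`.
#' @export
gen_oxyhb <- function(network, config = signal_gen_config(), duration_s) {
  adj <- as_adjacency(network)
  if (duration_s < 5) stop("duration_s must cover at least one 5 s analysis window")
  if (!is.null(config$seed)) set.seed(config$seed)
  n_ch <- nrow(adj)
  n_t <- round(duration_s * config$sampling_rate)
  sigma <- latent_covariance(adj, config$coupling_strength)
  cf <- chol(sigma)
  neural <- matrix(rnorm(n_t * n_ch), n_t, n_ch) %*% cf
  rec <- hemo_recording(neural + nuisance_components(n_t, n_ch, config),
                        config$sampling_rate)
  attr(rec, "network") <- network
  rec
}

#' Optical configuration for the raw-intensity generator and the modified
#' Beer-Lambert inversion
#'
#' The extinction table holds representative molar extinction coefficients
#' of oxy- and deoxyhemoglobin at the three laser wavelengths (columns
#' HbO, HbR; units are arbitrary but used consistently by the forward and
#' inverse model, so recovered concentrations are in matched arbitrary
#' molar-mm units). The table is replaceable.
#'
#' @param wavelengths laser wavelengths in nm.
#' @param extinction numeric matrix `length(wavelengths) x 2` (HbO, HbR).
#' @param dpf differential pathlength factor per wavelength.
#' @param distance_cm source-detector separation in cm.
#' @param baseline_intensity strictly positive baseline detector intensity
#'   (scalar or per-channel).
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(wavelengths = c(780, 805, 830),
                          extinction = default_extinction(),
                          dpf = c(6.0, 6.0, 6.0),
                          distance_cm = 3,
                          baseline_intensity = 1) {
  extinction <- as.matrix(extinction)
  if (nrow(extinction) != length(wavelengths) || ncol(extinction) != 2) {
    stop("extinction must be a length(wavelengths) x 2 matrix (HbO, HbR)")
  }
  if (length(dpf) != length(wavelengths) || any(dpf <= 0)) stop("dpf must be positive, one per wavelength")
  if (any(baseline_intensity <= 0)) stop("baseline_intensity must be strictly positive")
  structure(list(wavelengths = wavelengths, extinction = extinction, dpf = dpf,
                 distance_cm = distance_cm, baseline_intensity = baseline_intensity),
            class = "optics_config")
}

#' Representative hemoglobin extinction coefficients
#'
#' Molar extinction coefficients (1/(mM cm)) of oxyhemoglobin and
#' deoxyhemoglobin at 780, 805 and 830 nm, a version-pinned constant so
#' that forward generation and inversion are deterministic; replace via
#' [optics_config()] if a different tabulation is preferred.
#' @return 3 x 2 matrix with columns `HbO`, `HbR`.
#' @export
default_extinction <- function() {
  m <- matrix(c(0.710, 1.075,
                0.905, 0.880,
                0.974, 0.693), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("780", "805", "830"), c("HbO", "HbR"))
  m
}

#' Generate three-wavelength raw intensities from concentration series
#'
#' Applies the inverse modified Beer-Lambert law with the same extinction
#' table, DPF and source-detector distance used by [od_to_conc()], so
#' `od_to_conc(intensity_to_od(...))` recovers the input concentrations
#' exactly (up to floating point) when no filtering intervenes.
#'
#' @param hbo,hbr time x channel matrices of concentration changes.
#' @param optics an [optics_config()].
#' @param sampling_rate sampling frequency in Hz.
#' @return object of class `raw_intensity`: list with `values` (time x
#'   channel x wavelength array), `sampling_rate`, and the `optics` used.
#' @export
gen_raw_intensity <- function(hbo, hbr, optics = optics_config(), sampling_rate = 25.6) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr))) stop("hbo and hbr must have identical dimensions")
  if (!all(is.finite(hbo)) || !all(is.finite(hbr))) stop("concentrations must be finite")
  n_wl <- length(optics$wavelengths)
  n_t <- nrow(hbo); n_ch <- ncol(hbo)
  i0 <- rep_len(optics$baseline_intensity, n_ch)
  vals <- array(NA_real_, c(n_t, n_ch, n_wl))
  path <- optics$distance_cm * optics$dpf
  for (w in seq_len(n_wl)) {
    od <- (hbo * optics$extinction[w, 1] + hbr * optics$extinction[w, 2]) * path[w]
    vals[, , w] <- matrix(i0, n_t, n_ch, byrow = TRUE) * exp(-od)
  }
  structure(list(values = vals, sampling_rate = sampling_rate, optics = optics),
            class = "raw_intensity")
}
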