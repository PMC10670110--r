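#' Preprocessing configuration
#'
#' Parameters of the intensity-to-concentration chain: optical-density
#' conversion, motion-artifact detection and spline correction, the
#' 5th-order Butterworth band-pass (0.01-0.2 Hz), and the modified
#' Beer-Lambert inversion with DPF `[6, 6, 6]` and a 3 cm source-detector
#' separation. Motion thresholds follow common fNIRS practice (amplitude
#' 0.5 OD over a 0.5 s window, an SD multiplier of 50 on the sample-to-
#' sample variability, 1 s mask padding) and are all configurable.
#'
#' @param filter_order Butterworth order (5).
#' @param passband band edges in Hz, `0 < low < high < Nyquist`.
#' @param optics an [optics_config()] carrying extinction table, DPF and
#'   distance.
#' @param motion_window_s window over which signal change is measured.
#' @param motion_amp_threshold optical-density change flagged as motion.
#' @param motion_sd_mult multiplier on the channel's sample-to-sample SD.
#' @param motion_padding_s margin added around flagged intervals.
#' @param mode `"offline"` (zero-phase forward-backward filtering) or
#'   `"online"` (causal, as physically required at the feedback refresh).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 5,
                              passband = c(0.01, 0.2),
                              optics = optics_config(),
                              motion_window_s = 0.5,
                              motion_amp_threshold = 0.5,
                              motion_sd_mult = 50,
                              motion_padding_s = 1,
                              mode = c("offline", "online")) {
  if (passband[1] <= 0 || passband[1] >= passband[2]) stop("passband must satisfy 0 < low < high")
  structure(list(filter_order = filter_order, passband = passband, optics = optics,
                 motion_window_s = motion_window_s,
                 motion_amp_threshold = motion_amp_threshold,
                 motion_sd_mult = motion_sd_mult,
                 motion_padding_s = motion_padding_s,
                 mode = match.arg(mode)),
            class = "preprocess_config")
}

#' Convert raw intensities to optical density
#'
#' `OD(t) = -ln(I(t) / reference)` per channel and wavelength. The
#' reference defaults to the temporal mean intensity of each channel-
#' wavelength trace; pass the known baseline intensity for an exact
#' inverse of [gen_raw_intensity()].
#'
#' @param intensity a `raw_intensity` object or a time x channel matrix
#'   (single wavelength).
#' @param reference `"mean"` (default) or a numeric baseline intensity
#'   (scalar, or channel x wavelength matrix).
#' @return object of class `od_series`: list with `values` (time x channel
#'   x wavelength array) and `sampling_rate`.
#' @export
intensity_to_od <- function(intensity, reference = "mean") {
  if (inherits(intensity, "raw_intensity")) {
    vals <- intensity$values
    fs <- intensity$sampling_rate
  } else {
    vals <- as.matrix(intensity)
    dim(vals) <- c(dim(vals), 1L)
    fs <- NA_real_
  }
  bad <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive intensity at sample %d, channel %d, wavelength %d",
                 bad[1, 1], bad[1, 2], bad[1, 3]))
  }
  n_ch <- dim(vals)[2]; n_wl <- dim(vals)[3]
  od <- vals
  for (w in seq_len(n_wl)) {
    m <- matrix(vals[, , w], nrow = dim(vals)[1], ncol = n_ch)
    ref <- if (identical(reference, "mean")) {
      colMeans(m)
    } else if (is.matrix(reference)) {
      reference[, w]
    } else {
      rep_len(reference, n_ch)
    }
    od[, , w] <- -log(sweep(m, 2, ref, "/"))
  }
  structure(list(values = od, sampling_rate = fs), class = "od_series")
}

# accept od_series or plain matrix; returns list(values = 3d array, fs)
coerce_od <- function(od, sampling_rate = NULL) {
  if (inherits(od, "od_series")) return(list(values = od$values, fs = od$sampling_rate))
  vals <- as.matrix(od)
  dim(vals) <- c(dim(vals), 1L)
  list(values = vals, fs = sampling_rate)
}

#' Detect motion artifacts by amplitude and variability thresholds
#'
#' For each channel-wavelength trace, flags every sample interval over
#' which the signal change within `motion_window_s` exceeds the amplitude
#' threshold or `motion_sd_mult` times the channel's sample-to-sample
#' standard deviation. Flags closer than the padding margin are merged.
#'
#' @param od an `od_series` or time x channel matrix.
#' @param config a [preprocess_config()].
#' @param sampling_rate required when `od` is a plain matrix.
#' @return object of class `artifact_mask`: per-trace list of interval
#'   matrices (columns `start`, `end`, sample indices) plus `n_samples`.
#' @export
detect_motion <- function(od, config = preprocess_config(), sampling_rate = NULL) {
  x <- coerce_od(od, sampling_rate)
  fs <- x$fs
  if (is.null(fs) || is.na(fs)) stop("sampling_rate is required")
  w <- max(1L, round(config$motion_window_s * fs))
  if (w >= dim(x$values)[1]) stop("motion window must be shorter than the recording")
  pad <- round(config$motion_padding_s * fs)
  n_t <- dim(x$values)[1]
  out <- list()
  for (ch in seq_len(dim(x$values)[2])) {
    for (wl in seq_len(dim(x$values)[3])) {
      sig <- x$values[, ch, wl]
      change <- abs(sig[(w + 1):n_t] - sig[seq_len(n_t - w)])
      thr <- min(config$motion_amp_threshold,
                 config$motion_sd_mult * stats::sd(diff(sig)))
      hit <- which(change > thr)
      intervals <- if (length(hit) == 0) {
        matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
      } else {
        merge_intervals(cbind(start = pmax(1L, hit - pad),
                              end = pmin(n_t, hit + w + pad)))
      }
      out[[sprintf("ch%d_wl%d", ch, wl)]] <- intervals
    }
  }
  structure(list(intervals = out, n_samples = n_t,
                 dim = dim(x$values)[2:3]), class = "artifact_mask")
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  keep <- list(iv[1, ])
  for (r in seq_len(nrow(iv))[-1]) {
    last <- keep[[length(keep)]]
    if (iv[r, 1] <= last[2] + 1L) {
      keep[[length(keep)]] <- c(last[1], max(last[2], iv[r, 2]))
    } else {
      keep[[length(keep) + 1L]] <- iv[r, ]
    }
  }
  m <- do.call(rbind, keep)
  colnames(m) <- c("start", "end")
  m
}

#' Spline correction of flagged motion intervals
#'
#' Within each flagged interval the artifact trend is modelled by a cubic
#' smoothing spline and subtracted; the corrected segment is re-anchored
#' to the sample preceding the interval and the remainder of the trace is
#' shifted to restore continuity at the trailing edge. Unflagged samples
#' are untouched except for that level shift, and the series length is
#' preserved. Intervals touching a recording boundary are anchored on
#' their interior side only (with a warning).
#'
#' @param od an `od_series` or time x channel matrix.
#' @param mask an [detect_motion()] mask.
#' @return corrected object of the same type as `od`.
#' @export
spline_correct <- function(od, mask) {
  plain <- !inherits(od, "od_series")
  x <- coerce_od(od)
  vals <- x$values
  n_t <- dim(vals)[1]
  if (mask$n_samples != n_t) stop("mask does not match the recording length")
  for (ch in seq_len(dim(vals)[2])) {
    for (wl in seq_len(dim(vals)[3])) {
      iv <- mask$intervals[[sprintf("ch%d_wl%d", ch, wl)]]
      if (is.null(iv) || nrow(iv) == 0) next
      sig <- vals[, ch, wl]
      for (r in seq_len(nrow(iv))) {
        s <- iv[r, 1]; e <- iv[r, 2]
        seg <- sig[s:e]
        fit <- spline_trend(seg)
        corr <- seg - fit
        if (s > 1) {
          corr <- corr - corr[1] + sig[s - 1]
        } else {
          warning("artifact interval touches the recording start; one-sided anchoring")
          corr <- corr - corr[length(corr)] + seg[length(seg)]
        }
        if (e < n_t) {
          sig[(e + 1):n_t] <- sig[(e + 1):n_t] + (corr[length(corr)] - seg[length(seg)])
        } else if (s > 1) {
          warning("artifact interval touches the recording end; one-sided anchoring")
        }
        sig[s:e] <- corr
      }
      vals[, ch, wl] <- sig
    }
  }
  if (plain) return(matrix(vals[, , 1], nrow = n_t, ncol = dim(vals)[2]))
  structure(list(values = vals, sampling_rate = x$fs), class = "od_series")
}

# slow component of an artifact segment: cubic smoothing spline where the
# segment is long enough, otherwise a straight-line trend
spline_trend <- function(seg) {
  n <- length(seg)
  if (n >= 8 && stats::sd(seg) > 0) {
    idx <- seq_len(n)
    fit <- try(stats::smooth.spline(idx, seg)$y, silent = TRUE)
    if (!inherits(fit, "try-error") && length(fit) == n) return(fit)
  }
  stats::fitted(stats::lm.fit(cbind(1, seq_len(n)), seg))
}

# stable realization of the 5th-order Butterworth band-pass: a single
# transfer-function band-pass is numerically unstable at passbands this
# narrow relative to the sampling rate, so the band is realized as a
# cascade of a high-pass and a low-pass section of the configured order
butter_cascade <- function(order, passband, fs) {
  ny <- fs / 2
  if (passband[2] >= ny) stop("passband upper edge must be below the Nyquist frequency")
  list(hp = signal::butter(order, passband[1] / ny, type = "high"),
       lp = signal::butter(order, passband[2] / ny, type = "low"))
}

#' Butterworth band-pass filter
#'
#' 5th-order Butterworth band-pass with cut-offs 0.01-0.2 Hz by default.
#' Offline mode filters forward and backward (zero phase); online mode is
#' strictly causal (each output sample depends on past inputs only), as
#' required for real-time feedback, at the cost of the filter's group
#' delay. The band is realized as a cascade of high-pass and low-pass
#' sections of the stated order for numerical stability.
#'
#' @param x numeric vector, time x channel matrix, [hemo_recording()] or
#'   `od_series`.
#' @param config a [preprocess_config()] (passband, order, mode).
#' @param sampling_rate required when `x` carries no sampling rate.
#' @return filtered object of the same type and dimensions as `x`.
#' @export
bandpass <- function(x, config = preprocess_config(), sampling_rate = NULL) {
  if (inherits(x, "hemo_recording")) {
    out <- x
    out$data <- bandpass_matrix(x$data, config, x$sampling_rate)
    return(out)
  }
  if (inherits(x, "od_series")) {
    for (wl in seq_len(dim(x$values)[3])) {
      m <- matrix(x$values[, , wl], nrow = dim(x$values)[1], ncol = dim(x$values)[2])
      x$values[, , wl] <- bandpass_matrix(m, config, x$sampling_rate)
    }
    return(x)
  }
  if (is.null(sampling_rate)) stop("sampling_rate is required for plain input")
  if (is.matrix(x)) return(bandpass_matrix(x, config, sampling_rate))
  as.vector(bandpass_matrix(matrix(x, ncol = 1), config, sampling_rate))
}

bandpass_matrix <- function(m, config, fs) {
  filt <- butter_cascade(config$filter_order, config$passband, fs)
  apply_one <- if (config$mode == "offline") {
    function(v) signal::filtfilt(filt$lp, signal::filtfilt(filt$hp, v))
  } else {
    function(v) as.numeric(signal::filter(filt$lp, signal::filter(filt$hp, v)))
  }
  out <- apply(m, 2, apply_one)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Modified Beer-Lambert inversion: for each channel and time point the
#' wavelength-wise OD changes are regressed on the extinction
#' coefficients scaled by source-detector distance and DPF, yielding
#' least-squares OxyHb and DeoxyHb concentration changes (arbitrary
#' molar-mm units consistent with the extinction table).
#'
#' @param od an `od_series` (time x channel x wavelength).
#' @param config a [preprocess_config()] carrying the optics.
#' @return list of class `hemo_conc` with `hbo` and `hbr`
#'   [hemo_recording()] objects.
#' @export
od_to_conc <- function(od, config = preprocess_config()) {
  x <- coerce_od(od)
  optics <- config$optics
  n_wl <- dim(x$values)[3]
  if (n_wl != length(optics$wavelengths)) {
    stop("extinction table does not cover the recorded wavelengths")
  }
  path <- optics$distance_cm * optics$dpf
  design <- optics$extinction * path # n_wl x 2
  if (abs(det(crossprod(design))) < 1e-12) stop("extinction system is singular")
  n_t <- dim(x$values)[1]; n_ch <- dim(x$values)[2]
  hbo <- matrix(NA_real_, n_t, n_ch)
  hbr <- matrix(NA_real_, n_t, n_ch)
  for (ch in seq_len(n_ch)) {
    odw <- t(x$values[, ch, ]) # n_wl x n_t
    sol <- qr.solve(design, odw)
    hbo[, ch] <- sol[1, ]
    hbr[, ch] <- sol[2, ]
  }
  structure(list(hbo = hemo_recording(hbo, x$fs),
                 hbr = hemo_recording(hbr, x$fs)),
            class = "hemo_conc")
}

#' Full offline preprocessing chain
#'
#' Intensity -> OD -> motion detection -> spline correction -> band-pass
#' -> concentrations, mirroring standard offline fNIRS processing. The
#' online variant (causal filter, correction optional) is obtained by
#' setting `mode = "online"` in the config; by default the online chain is
#' filter-only.
#'
#' @param intensity a `raw_intensity` object.
#' @param config a [preprocess_config()].
#' @param correct_motion apply motion detection/spline correction
#'   (default TRUE offline, FALSE online).
#' @return a `hemo_conc` list (`hbo`, `hbr` recordings).
#' @export
preprocess_intensity <- function(intensity, config = preprocess_config(),
                                 correct_motion = config$mode == "offline") {
  od <- intensity_to_od(intensity)
  if (correct_motion) {
    mask <- detect_motion(od, config)
    od <- spline_correct(od, mask)
  }
  od <- bandpass(od, config)
  od_to_conc(od, config)
}
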