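#' Multichannel extracellular recordings
#'
#' A `recording` wraps a channels x samples matrix of potentials (volts)
#' with its sampling rate, stimulus event times and an optional map from
#' rows to electrode-array sites. Long-format access for plotting and
#' dplyr work is provided by `tidy()`.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz (25 kHz in the reference
#'   acquisition setup).
#' @param event_times stimulus onset times in seconds, all within the
#'   recording span.
#' @param channel_map optional integer vector mapping rows to
#'   [electrode_array()] site numbers.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, sampling_rate, event_times = numeric(0),
                      channel_map = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive", call. = FALSE)
  }
  span <- ncol(samples) / sampling_rate
  if (length(event_times) && (any(event_times < 0) || any(event_times > span))) {
    stop("`event_times` must lie within the recording span", call. = FALSE)
  }
  structure(list(
    samples = samples, sampling_rate = sampling_rate,
    event_times = as.numeric(event_times),
    channel_map = channel_map, band = "wideband"
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate, x$band,
              length(x$event_times)))
  invisible(x)
}

#' @export
tidy.recording <- function(x, ...) {
  nt <- ncol(x$samples)
  tibble::tibble(
    channel = rep(seq_len(nrow(x$samples)), times = nt),
    time_s = rep((seq_len(nt) - 1L) / x$sampling_rate,
                 each = nrow(x$samples)),
    value = as.vector(x$samples)
  )
}

#' Band-pass separation of LFP and unit activity
#'
#' Splits the extracellular signal at the standard corners: the LFP band
#' (1-500 Hz, synaptic population activity) or the unit band (500 Hz-8 kHz,
#' spikes). A Butterworth band-pass at the named corners is applied with
#' zero phase (forward-backward filtering), implemented as a cascade of
#' high-pass and low-pass sections of the given order — numerically robust
#' at the extreme corner ratios involved (1 Hz at a 25 kHz rate) while
#' preserving the Butterworth corners and rolloff.
#'
#' @param rec a [recording()].
#' @param band `"lfp"` or `"unit"`, or use `corners` directly.
#' @param order filter order of each section (default 4).
#' @param corners optional explicit corner pair in Hz (overrides `band`).
#' @return A filtered [recording()] with its `band` field updated.
#' @export
bandpass <- function(rec, band = c("lfp", "unit"), order = 4L, corners = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(corners)) {
    band <- match.arg(band)
    corners <- switch(band, lfp = c(1, 500), unit = c(500, 8000))
  } else {
    band <- "custom"
  }
  fs <- rec$sampling_rate
  if (fs <= 2 * corners[2]) {
    stop("upper cutoff at or above Nyquist frequency", call. = FALSE)
  }
  hp <- butter_sos(order, corners[1] / (fs / 2), "high")
  lp <- butter_sos(order, corners[2] / (fs / 2), "low")
  out <- rec
  out$samples <- t(apply(rec$samples, 1, function(x) {
    sos_filtfilt(lp, sos_filtfilt(hp, x - mean(x)))
  }))
  out$band <- band
  out
}

# Butterworth design factored into second-order sections. A corner five
# decades below the sampling rate puts poles within ~1e-4 of the unit
# circle; the expanded order-2*order polynomial is then numerically
# inaccurate (it fails to null DC), while biquads are exact: the high-pass
# numerator is literally (1, -2, 1).
butter_sos <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(w > 0, w < 1)
  W <- tan(pi * w / 2)                   # pre-warped analog cutoff
  k <- seq_len(order)
  u <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # prototype poles
  p <- if (type == "low") W * u else W / u
  zp <- (1 + p) / (1 - p)                # bilinear transform
  # pair conjugate poles into real biquads (order assumed even or 1)
  zp <- zp[Im(zp) >= 0 | abs(Im(zp)) < 1e-12]
  sections <- lapply(zp, function(z1) {
    if (abs(Im(z1)) < 1e-12) {
      a <- c(1, -Re(z1))
      b <- if (type == "low") c(1, 1) else c(1, -1)
    } else {
      a <- c(1, -2 * Re(z1), Mod(z1)^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    }
    ref <- if (type == "low") 1 else -1   # unit gain at DC / Nyquist
    g <- sum(a * ref^(seq_along(a) - 1)) / sum(b * ref^(seq_along(b) - 1))
    list(b = b * g, a = a)
  })
  sections
}

# zero-phase application of a second-order-section cascade
sos_filtfilt <- function(sections, x) {
  for (s in sections) x <- signal::filtfilt(signal::Arma(s$b, s$a), x)
  x
}

#' Event-related potential by trial averaging
#'
#' Cuts a fixed window around every stimulus event and averages the
#' time-locked epochs (the ERP). The default window is -50 ms to +100 ms
#' around the event.
#'
#' @param rec a [recording()] (typically LFP-band) with event times set.
#' @param window `c(pre, post)` in seconds relative to each event.
#' @return A channels x window matrix with attribute `time_s` (epoch time
#'   axis) and `n_trials`.
#' @export
epoch_average <- function(rec, window = c(-0.05, 0.1)) {
  stopifnot(inherits(rec, "recording"))
  if (!length(rec$event_times)) stop("recording has no events", call. = FALSE)
  fs <- rec$sampling_rate
  i0 <- round(rec$event_times * fs) + 1L
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs)
  lo <- i0 + pre
  hi <- i0 + post
  bad <- which(lo < 1L | hi > ncol(rec$samples))
  if (length(bad)) {
    stop(sprintf("epoch window exceeds recording bounds for event(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  L <- post - pre + 1L
  acc <- matrix(0, nrow(rec$samples), L)
  for (e in seq_along(i0)) {
    acc <- acc + rec$samples[, lo[e]:hi[e], drop = FALSE]
  }
  erp <- acc / length(i0)
  attr(erp, "time_s") <- (pre:post) / fs
  attr(erp, "n_trials") <- length(i0)
  erp
}

#' Threshold spike detection on the unit band
#'
#' Negative-edge detection: the threshold is `-4` standard deviations of
#' each channel (or a MAD-based robust equivalent); a spike is registered
#' at each downward crossing, subsequent crossings within the 1.5 ms dead
#' time are suppressed, and the spike time is the trough (minimum) within
#' the dead-time window. A 20-sample snippet — eight samples prior to the
#' trough and twelve posterior, the trough counted among the posterior
#' twelve — is extracted per spike; spikes too close to the record edges
#' for a full snippet are dropped. The threshold scales with the data, so
#' detection is invariant to positive rescaling of the channel.
#'
#' @param rec a unit-band [recording()].
#' @param threshold_sd threshold in standard deviations (default 4).
#' @param dead_time dead time in seconds (default 1.5 ms).
#' @param estimator `"sd"` or `"mad"` (`mad / 0.6745`, robust to spikes).
#' @param snippet `c(pre, post)` samples around (and excluding) the trough
#'   sample; the default `c(8, 11)` yields the 20-sample window.
#' @return A tibble of class `spike_train` with columns `channel`,
#'   `time_s`, `trough_index` and a matrix column `waveform`
#'   (spikes x 20 samples).
#' @export
detect_spikes <- function(rec, threshold_sd = 4, dead_time = 0.0015,
                          estimator = c("sd", "mad"), snippet = c(8L, 11L)) {
  stopifnot(inherits(rec, "recording"))
  estimator <- match.arg(estimator)
  fs <- rec$sampling_rate
  dead <- max(1L, round(dead_time * fs))
  nsnip <- sum(snippet) + 1L
  rows <- list()
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    if (length(x) < nsnip) {
      warning(sprintf("channel %d shorter than a snippet; skipped", ch),
              call. = FALSE)
      next
    }
    s <- if (estimator == "sd") stats::sd(x) else stats::mad(x)
    thr <- -threshold_sd * s
    cross <- which(x[-1] < thr & x[-length(x)] >= thr) + 1L
    troughs <- integer(0)
    last_end <- -Inf
    for (t in cross) {
      if (t <= last_end) next
      w_end <- min(t + dead, length(x))
      tr <- t + which.min(x[t:w_end]) - 1L
      troughs <- c(troughs, tr)
      last_end <- t + dead
    }
    keep <- troughs - snippet[1] >= 1L & troughs + snippet[2] <= length(x)
    troughs <- troughs[keep]
    if (!length(troughs)) next
    wf <- t(vapply(troughs, function(tr) {
      x[(tr - snippet[1]):(tr + snippet[2])]
    }, numeric(nsnip)))
    tb <- tibble::tibble(channel = ch, time_s = (troughs - 1L) / fs,
                         trough_index = troughs)
    tb$waveform <- wf
    rows[[length(rows) + 1L]] <- tb
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(channel = integer(0), time_s = numeric(0),
                   trough_index = integer(0))
  }
  structure(out, sampling_rate = fs, threshold_sd = threshold_sd,
            class = c("spike_train", class(out)))
}

#' Spike-triggered average of the electric potentials
#'
#' Averages potential epochs across all spike times (the STAP), on
#' whichever recording is supplied — wide-band or LFP-band, as configured
#' by the caller. Spikes without full window coverage are dropped; per-class
#' STAPs are obtained by filtering the spike train (e.g. on an external
#' cluster label column) before the call.
#'
#' @param rec the [recording()] to average (all channels).
#' @param spikes a [detect_spikes()] spike train (any subset/class of it).
#' @param window `c(pre, post)` in seconds around each spike time.
#' @return A channels x window matrix with attributes `time_s` and
#'   `n_spikes`.
#' @export
spike_triggered_average <- function(rec, spikes, window = c(-0.004, 0.006)) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  i0 <- round(spikes$time_s * fs) + 1L
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs)
  lo <- i0 + pre
  hi <- i0 + post
  ok <- lo >= 1L & hi <= ncol(rec$samples)
  if (!any(ok)) {
    rlang::abort("no spike has full window coverage",
                 class = "vcsd_empty_result")
  }
  L <- post - pre + 1L
  acc <- matrix(0, nrow(rec$samples), L)
  for (e in which(ok)) {
    acc <- acc + rec$samples[, lo[e]:hi[e], drop = FALSE]
  }
  stap <- acc / sum(ok)
  attr(stap, "time_s") <- (pre:post) / fs
  attr(stap, "n_spikes") <- sum(ok)
  stap
}

#' Read / write recordings as CSV
#'
#' Plain-text interchange schema: a channels x samples numeric matrix in
#' CSV (no header, one row per channel) plus a JSON sidecar with
#' `sampling_rate`, `event_times` and `channel_map`.
#'
#' @param rec a [recording()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   the reconstructed [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(rec$samples, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate, event_times = rec$event_times,
         channel_map = rec$channel_map, band = rec$band),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(samples) <- NULL
  rec <- recording(samples, meta$sampling_rate,
                   event_times = meta$event_times %||% numeric(0),
                   channel_map = meta$channel_map)
  rec$band <- meta$band %||% "wideband"
  rec
}
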