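#' SPARC configuration
#'
#' Parameters of the spectral arc length smoothness metric applied to the
#' pressure signal of a tracing. The metric is the negative arc length of
#' the (DC-normalized) Fourier magnitude spectrum of the signal up to an
#' adaptive cutoff: spectra of rough signals wiggle more and are longer, so
#' rougher tracings score more negative (larger SPARC = smoother).
#'
#' The spectrum is zero-padded to length `2^(ceiling(log2(N)) + pad_level)`.
#' The cutoff frequency is the last frequency not exceeding `fc_max` at
#' which the normalized magnitude still reaches `amp_threshold`. With
#' `freq_normalized = TRUE` the arc length is computed over dimensionless
#' frequency (freq / cutoff), the canonical form of the metric with typical
#' values around -1.5 to -5; with `FALSE` (default) frequency stays in Hz.
#' `signal_mode` selects the analyzed signal: the pressure series itself or
#' its first time-derivative (default). The derivative reading of "pressure
#' change" is what produces smoothness values on the study's reported scale
#' (tens to low hundreds negative): the derivative's spectral DC is the net
#' pressure change of the tracing, a much smaller normalizer than the mean
#' pressure level, so high-frequency structure is amplified in proportion
#' to how unsteady the pressure is.
#'
#' @param pad_level Zero-padding exponent (>= 0), default 4.
#' @param fc_max Maximum cutoff frequency, Hz, default 10.
#' @param amp_threshold Normalized-magnitude threshold in (0, 1),
#'   default 0.05.
#' @param freq_normalized Use dimensionless frequency? Default `FALSE`.
#' @param signal_mode `"pressure_derivative"` (default) or `"pressure"`.
#' @return An object of class `sparc_config`.
#' @export
sparc_config <- function(pad_level = 4, fc_max = 10, amp_threshold = 0.05,
                         freq_normalized = FALSE,
                         signal_mode = c("pressure_derivative", "pressure")) {
  if (pad_level < 0 || fc_max <= 0 || amp_threshold <= 0 ||
      amp_threshold >= 1)
    stop_validation("invalid sparc_config parameters")
  structure(list(pad_level = as.integer(pad_level), fc_max = fc_max,
                 amp_threshold = amp_threshold,
                 freq_normalized = isTRUE(freq_normalized),
                 signal_mode = match.arg(signal_mode)),
            class = "sparc_config")
}

#' Resample a recording's pressure signal onto a uniform grid
#'
#' Linear interpolation onto `m + 1` evenly spaced points from the first to
#' the last timestamp, where `m = round(duration * rate)` — endpoints are
#' preserved exactly and the effective rate `m / duration` equals `rate`
#' whenever the duration is a whole number of sample periods (as with
#' device frames). Device frames may jitter; spectral analysis needs a
#' uniform grid.
#'
#' @param rec A [pen_recording()] (single-stroke).
#' @param rate Target rate, Hz.
#' @return List with `t` (grid), `pressure` (interpolated values) and
#'   `rate` (effective rate, Hz).
#' @export
resample_uniform <- function(rec, rate = DEVICE_RATE) {
  s <- rec$samples
  if (nrow(s) < 2) stop_validation("fewer than 2 samples")
  if (rate <= 0) stop_validation("rate must be positive")
  dur <- s$t[nrow(s)] - s$t[1]
  m <- max(1, round(dur * rate))
  grid <- seq(s$t[1], s$t[nrow(s)], length.out = m + 1)
  p <- stats::approx(s$t, s$pressure, xout = grid)$y
  p[1] <- s$pressure[1]
  p[m + 1] <- s$pressure[nrow(s)]
  list(t = grid, pressure = p, rate = m / dur)
}

#' Drawing time of a recording
#'
#' Elapsed time from first to last pen-contact sample, in seconds.
#'
#' @param rec A [pen_recording()].
#' @return Seconds.
#' @export
drawing_time <- function(rec) {
  s <- rec$samples
  if (nrow(s) < 2) stop_validation("fewer than 2 samples")
  s$t[nrow(s)] - s$t[1]
}

#' Average pressure of a recording
#'
#' Time-weighted mean stylus pressure: the arithmetic mean of the uniformly
#' resampled pressure series (robust to frame jitter).
#'
#' @param rec A [pen_recording()].
#' @param rate Resampling rate, Hz.
#' @return Device pressure units.
#' @export
average_pressure <- function(rec, rate = DEVICE_RATE) {
  mean(resample_uniform(rec, rate)$pressure)
}

#' Spectral arc length (SPARC) of a uniformly sampled signal
#'
#' Computes the negative arc length of the normalized Fourier magnitude
#' spectrum of `signal` (or of its time-derivative, per
#' `cfg$signal_mode`) up to the adaptive cutoff; see [sparc_config()] for
#' the metric and its parameters. The value is finite, non-positive, and
#' invariant to positive rescaling of the signal. A perfectly constant
#' signal in derivative mode has an identically zero derivative and is
#' assigned the supremum value 0 (maximal smoothness).
#'
#' @param signal Numeric vector, uniformly sampled (>= 4 samples).
#' @param rate Sampling rate, Hz.
#' @param cfg A [sparc_config()].
#' @return A single non-positive number.
#' @export
#' @examples
#' p <- 1.5 + 0.2 * sin(seq(0, 2 * pi, length.out = 240))
#' sparc(p, 120, sparc_config(signal_mode = "pressure"))
sparc <- function(signal, rate, cfg = sparc_config()) {
  stopifnot(inherits(cfg, "sparc_config"))
  if (length(signal) < 4) stop_validation("signal too short for SPARC")
  if (any(!is.finite(signal))) stop_validation("non-finite signal")
  if (cfg$signal_mode == "pressure_derivative") {
    signal <- diff(signal) * rate
    if (all(signal == 0)) return(0)
  }
  N <- length(signal)
  nfft <- 2^(ceiling(log2(N)) + cfg$pad_level)
  M <- Mod(stats::fft(c(signal, numeric(nfft - N))))[seq_len(nfft / 2 + 1)]
  if (M[1] == 0)
    stop_validation("spectrum has zero DC component (V(0) = 0)")
  V <- M / M[1]
  f <- (seq_len(nfft / 2 + 1) - 1) * rate / nfft
  keep <- f <= cfg$fc_max
  V <- V[keep]; f <- f[keep]
  k <- max(which(V >= cfg$amp_threshold))  # k >= 1 since V[1] == 1
  if (k < 2) return(0)
  V <- V[seq_len(k)]; f <- f[seq_len(k)]
  if (cfg$freq_normalized) f <- f / f[k]
  -sum(sqrt(diff(f)^2 + diff(V)^2))
}

#' Extract the three screening features from recordings
#'
#' Computes drawing time (DT, s), average pressure (AP, device units) and
#' SPARC smoothness of the pressure change (SP) on the 120 Hz-resampled
#' pressure series. For a cohort, returns one row per recording.
#'
#' @param x A [pen_recording()] or `cm_cohort`.
#' @param cfg A [sparc_config()].
#' @param rate Resampling rate, Hz.
#' @param ... Passed between methods.
#' @return A data.frame with columns `participant_id`, `group`, `shape`,
#'   `DT`, `AP`, `SP`.
#' @export
extract_features <- function(x, ...) UseMethod("extract_features")

#' @rdname extract_features
#' @export
extract_features.pen_recording <- function(x, cfg = sparc_config(),
                                           rate = DEVICE_RATE, ...) {
  u <- tryCatch(resample_uniform(x, rate), error = function(e)
    stop_validation("%s/%s: %s", x$participant_id, x$shape,
                    conditionMessage(e)))
  sp <- tryCatch(sparc(u$pressure, u$rate, cfg), error = function(e)
    stop_validation("%s/%s: %s", x$participant_id, x$shape,
                    conditionMessage(e)))
  data.frame(participant_id = x$participant_id,
             group = x$group %||% NA_character_, shape = x$shape,
             DT = drawing_time(x), AP = mean(u$pressure), SP = sp,
             stringsAsFactors = FALSE)
}

#' @rdname extract_features
#' @export
extract_features.cm_cohort <- function(x, cfg = sparc_config(),
                                       rate = DEVICE_RATE, ...) {
  rows <- lapply(x$recordings, extract_features, cfg = cfg, rate = rate)
  do.call(rbind, rows)
}

#' Write / read a feature table CSV
#'
#' Columns `participant_id,group,shape,DT,AP,SP`, one row per recording.
#'
#' @param features Feature data.frame from [extract_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
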