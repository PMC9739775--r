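# Recording-level preprocessing: linear-phase FIR low-pass at 40 Hz,
# then segmentation into fixed-length epochs with 50% overlap.

#' Design a linear-phase low-pass FIR filter
#'
#' Hamming-windowed sinc design (via [signal::fir1()]) with the
#' coefficients renormalized to exact unit DC gain. Taps are symmetric,
#' so the filter has linear phase and a group delay of
#' `(n_taps - 1) / 2` samples.
#'
#' @param fs sampling rate in Hz.
#' @param cutoff_hz cutoff frequency in Hz (default 40).
#' @param n_taps odd number of taps, at least 11 (default 101).
#' @return a `fir_spec` with fields `cutoff_hz`, `n_taps`,
#'   `coefficients` and `fs`.
#' @export
design_lowpass_fir <- function(fs, cutoff_hz = 40, n_taps = 101L) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(cutoff_hz, "cutoff_hz")
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fs / 2))
  }
  n_taps <- as.integer(n_taps)
  if (n_taps < 11L || n_taps %% 2L == 0L) stop("n_taps must be odd and >= 11")
  h <- signal::fir1(n_taps - 1L, cutoff_hz / (fs / 2), type = "low",
                    window = signal::hamming(n_taps))
  h <- as.numeric(h) / sum(h)
  structure(list(cutoff_hz = cutoff_hz, n_taps = n_taps,
                 coefficients = h, fs = fs),
            class = "fir_spec")
}

#' Evaluate the magnitude response of an FIR filter
#'
#' @param spec a `fir_spec`.
#' @param freq_hz frequencies (Hz) at which to evaluate.
#' @return magnitude gain at each frequency.
#' @export
fir_gain <- function(spec, freq_hz) {
  n <- spec$n_taps
  vapply(freq_hz, function(f) {
    Mod(sum(spec$coefficients * exp(-1i * 2 * pi * f / spec$fs * (0:(n - 1L)))))
  }, numeric(1))
}

#' Zero-phase low-pass filter a recording
#'
#' Applies the FIR filter with reflection padding at both edges and
#' compensates the `(n_taps - 1) / 2`-sample group delay, so the output
#' has the same length as the input and is time-aligned with it.
#'
#' @param rec an `eeg_recording`, longer than the filter.
#' @param spec a `fir_spec` from [design_lowpass_fir()]; designed on the
#'   fly from `rec$fs` when omitted.
#' @return the filtered `eeg_recording`.
#' @export
lowpass_filter <- function(rec, spec = design_lowpass_fir(rec$fs)) {
  x <- rec$samples
  L <- length(x)
  n <- spec$n_taps
  if (L <= n) stop("recording (", L, " samples) must be longer than the filter (", n, " taps)")
  p <- (n - 1L) %/% 2L
  xpad <- c(x[(p + 1L):2L], x, x[(L - 1L):(L - p)])
  conv <- stats::filter(xpad, spec$coefficients, method = "convolution", sides = 1L)
  y <- as.numeric(conv[(2L * p + 1L):(2L * p + L)])
  out <- rec
  out$samples <- y
  out
}

#' Cut a recording into fixed-length overlapping epochs
#'
#' Windows are half-open `[start, start + w)` with 0-based start
#' indices. The window length in samples is `w = round(window_s * fs)`;
#' the hop is `floor(w * (1 - overlap))`; only complete windows are
#' kept. A requested window up to 2 s longer than the recording is
#' clamped to the full recording duration (so a nominal 24 s window on a
#' 23.6 s recording yields one whole-recording epoch); anything longer
#' yields an empty list with a warning.
#'
#' @param rec an `eeg_recording`.
#' @param window_s window length in seconds.
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @return list of `eeg_epoch` objects (possibly empty).
#' @export
segment_epochs <- function(rec, window_s, overlap = 0.5) {
  stopifnot_scalar_pos(window_s, "window_s")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  L <- length(rec$samples)
  duration <- L / rec$fs
  window_eff <- window_s
  if (window_s > duration) {
    if (window_s - duration <= 2 + 1e-9) {
      message(sprintf("window %.3g s clamped to recording duration %.3g s (%s)",
                      window_s, duration, rec$source_id))
      window_eff <- duration
    } else {
      warning(sprintf("window %.3g s exceeds recording duration %.3g s (%s); no epochs",
                      window_s, duration, rec$source_id))
      return(list())
    }
  }
  w <- as.integer(min(round(window_eff * rec$fs), L))
  step <- max(1L, as.integer(floor(w * (1 - overlap))))
  starts <- seq.int(0L, L - w, by = step)
  lapply(starts, function(s) {
    structure(list(samples = rec$samples[(s + 1L):(s + w)],
                   fs = rec$fs, label = rec$label,
                   source_id = rec$source_id,
                   window_s = window_eff, start_index = s),
              class = "eeg_epoch")
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch %s> class %s, %d samples @ %.2f Hz, start %d\n",
              x$source_id, x$label, length(x$samples), x$fs, x$start_index))
  invisible(x)
}
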