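# The 7-dimensional per-epoch feature vector: mean, median, population
# variance, and a spectrum-amplitude summary for each of the four EEG
# bands (delta, theta, alpha, beta).

#' Default EEG band definitions
#'
#' Half-open intervals `[lo, hi)` so shared edges are never counted
#' twice: delta `[1, 4)`, theta `[4, 8)`, alpha `[8, 12)`,
#' beta `[12, 25)` Hz.
#'
#' @return data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo_hz = c(1, 4, 8, 12), hi_hz = c(4, 8, 12, 25),
             stringsAsFactors = FALSE)
}

FEATURE_NAMES <- c("mean", "median", "variance",
                   "delta", "theta", "alpha", "beta")

#' Time-domain features of an epoch
#'
#' Variance is the population variance (divide by `n`), a descriptive
#' statistic rather than an estimator.
#'
#' @param x numeric samples of an epoch (or an `eeg_epoch`).
#' @return named vector `(mean, median, variance)`.
#' @export
time_domain_features <- function(x) {
  if (inherits(x, "eeg_epoch")) x <- x$samples
  if (length(x) == 0L) stop("epoch must be non-empty")
  m <- mean(x)
  c(mean = m, median = stats::median(x), variance = mean((x - m)^2))
}

#' Spectrum amplitude of the four EEG bands
#'
#' One-sided discrete Fourier magnitudes `|X_k|` are computed on the raw
#' (unwindowed, non-detrended) epoch; a band's amplitude summarizes the
#' magnitudes of the bins whose frequency `k * fs / n` lies in
#' `[lo_hz, hi_hz)`. The default summary is the mean over band bins,
#' which keeps features commensurate across window lengths (a sum would
#' grow with the bin count); `"sum"` and `"peak"` are also available.
#' A band containing no bins (very short windows at low fs) returns 0
#' with a warning.
#'
#' @param x numeric samples (or an `eeg_epoch`).
#' @param fs sampling rate in Hz (taken from the epoch if given one).
#' @param bands band table as from [eeg_bands()].
#' @param summary `"mean"`, `"sum"` or `"peak"`.
#' @return named vector `(delta, theta, alpha, beta)`.
#' @export
band_amplitudes <- function(x, fs = NULL, bands = eeg_bands(),
                            summary = c("mean", "sum", "peak")) {
  summary <- match.arg(summary)
  if (inherits(x, "eeg_epoch")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs is required when x is a bare numeric vector")
  n <- length(x)
  if (n < 2L) stop("epoch must contain at least 2 samples")
  mag <- Mod(stats::fft(x))
  k <- 0:(n %/% 2L)
  freq <- k * fs / n
  mag1 <- mag[k + 1L]
  out <- numeric(nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    sel <- freq >= bands$lo_hz[b] & freq < bands$hi_hz[b]
    if (!any(sel)) {
      warning(sprintf("band %s [%g, %g) Hz contains no FFT bins (n = %d, fs = %g); amplitude set to 0",
                      bands$name[b], bands$lo_hz[b], bands$hi_hz[b], n, fs))
      out[b] <- 0
    } else {
      out[b] <- switch(summary,
                       mean = mean(mag1[sel]),
                       sum = sum(mag1[sel]),
                       peak = max(mag1[sel]))
    }
  }
  out
}

#' Full 7-dimensional feature vector of an epoch
#'
#' Fixed, documented ordering:
#' `(mean, median, variance, delta, theta, alpha, beta)`.
#'
#' @param epoch an `eeg_epoch`.
#' @param bands band table as from [eeg_bands()].
#' @param summary band-amplitude summary, see [band_amplitudes()].
#' @return named length-7 numeric vector.
#' @export
extract_feature_vector <- function(epoch, bands = eeg_bands(),
                                   summary = "mean") {
  stopifnot(inherits(epoch, "eeg_epoch"))
  c(time_domain_features(epoch$samples),
    band_amplitudes(epoch$samples, fs = epoch$fs, bands = bands,
                    summary = summary))
}

#' Build the per-epoch feature table for one window length
#'
#' Each recording is low-pass filtered, cut into `overlap`-fraction
#' overlapping epochs of `window_s` seconds, and each epoch contributes
#' one row of 7 features plus `label`, `source_id` and `window_s`
#' provenance columns. No standardization is applied here; z-scoring
#' happens inside cross-validation using training-fold statistics only.
#'
#' @param set an `eeg_recording_set` (or list of recordings).
#' @param window_s window length in seconds.
#' @param overlap overlap fraction (default 0.5).
#' @param filter_spec a `fir_spec`, or `NULL` to design the default
#'   40 Hz / 101-tap filter from the data's sampling rate; `FALSE`
#'   skips filtering.
#' @param bands,summary passed to [band_amplitudes()].
#' @return data frame with columns
#'   `mean, median, variance, delta, theta, alpha, beta, label,
#'   source_id, window_s`.
#' @export
build_feature_table <- function(set, window_s, overlap = 0.5,
                                filter_spec = NULL, bands = eeg_bands(),
                                summary = "mean") {
  recs <- if (inherits(set, "eeg_recording_set")) set$recordings else set
  if (!length(recs)) stop("no recordings supplied")
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    filtered <- if (isFALSE(filter_spec)) {
      rec
    } else if (is.null(filter_spec)) {
      lowpass_filter(rec, design_lowpass_fir(rec$fs))
    } else {
      lowpass_filter(rec, filter_spec)
    }
    epochs <- segment_epochs(filtered, window_s, overlap = overlap)
    if (!length(epochs)) next
    feats <- t(vapply(epochs, extract_feature_vector, numeric(7L),
                      bands = bands, summary = summary))
    rows[[i]] <- data.frame(feats,
                            label = rec$label, source_id = rec$source_id,
                            window_s = window_s,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop(sprintf("window of %g s yields no epochs for any recording", window_s))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[1:7] <- FEATURE_NAMES
  out$label <- as_class_factor(out$label)
  out
}
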