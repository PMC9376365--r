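#' Zero-phase band-pass filtering of an EEG recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel; the default 2-35 Hz band is the conventional resting-EEG
#' analysis band.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < rate/2.
#' @param order Butterworth order (applied twice by filtering both ways).
#' @return The filtered `eeg_recording` (length preserved).
#' @export
bandlimit <- function(rec, low = 2, high = 35, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low ||
      high >= rec$rate / 2)
    stop("band edges must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / (rec$rate / 2), type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- signal::filtfilt(bf, rec$samples[ch, ])
  out
}

#' Cut a recording into consecutive non-overlapping epochs
#'
#' @param rec An `eeg_recording`.
#' @param epoch_s Epoch length in seconds (default 4 s).
#' @return List of channels x samples matrices; a trailing remainder
#'   shorter than one epoch is dropped.
#' @export
segment_epochs <- function(rec, epoch_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_s * rec$rate)
  n <- ncol(rec$samples)
  if (n < len) stop("recording shorter than one epoch")
  k <- n %/% len
  lapply(seq_len(k), function(i)
    rec$samples[, ((i - 1) * len + 1):(i * len), drop = FALSE])
}

# Hann-tapered periodogram of one epoch (single channel). Returns freq and
# power on the native grid rate/n; absolute scale is arbitrary -- every
# consumer uses power ratios.
periodogram_hann <- function(x, rate) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  sp <- stats::fft((x - mean(x)) * w)
  m <- floor(n / 2)
  data.frame(freq = seq_len(m) * rate / n,
             power = (Mod(sp[1 + seq_len(m)])^2) / sum(w^2))
}

#' Relative power of a frequency band within one epoch
#'
#' The fraction x = (power in `band`) / (power in `total_band`), computed
#' from a Hann-tapered periodogram with right-open bin assignment
#' (f1 <= f < f2), so the thirty-three 1-Hz bins of 2-35 Hz partition the
#' total exactly.
#'
#' @param epoch Numeric vector, one channel of one epoch.
#' @param rate Sampling rate (Hz).
#' @param band Length-2 numeric, the target band (Hz).
#' @param total_band Length-2 numeric, the analysis band (Hz).
#' @return A fraction in \[0, 1\].
#' @export
epoch_relative_power <- function(epoch, rate, band,
                                 total_band = c(2, 35)) {
  if (band[1] < total_band[1] || band[2] > total_band[2])
    stop("band must lie within total_band")
  pg <- periodogram_hann(epoch, rate)
  in_total <- pg$freq >= total_band[1] & pg$freq < total_band[2]
  tot <- sum(pg$power[in_total])
  if (tot <= 0) stop("zero total power in analysis band")
  sum(pg$power[in_total & pg$freq >= band[1] & pg$freq < band[2]]) / tot
}

#' Logit transform of a relative power fraction
#'
#' Computes log(x / (1 - x)) with natural logarithm, the standard
#' skewness-compensating transform for relative EEG band power. Values at
#' or beyond 0/1 are clamped to `eps`/`1 - eps` with a warning.
#'
#' @param x Numeric vector of fractions.
#' @param eps Clamp margin.
#' @return Logit values (dimensionless).
#' @export
logit_transform <- function(x, eps = 1e-6) {
  bad <- x <= 0 | x >= 1
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d value(s) clamped to [%g, %g] before logit",
                    sum(bad, na.rm = TRUE), eps, 1 - eps))
    x <- pmin(pmax(x, eps), 1 - eps)
  }
  log(x / (1 - x))
}

#' Alpha subband names used throughout the package
#' @return Character vector "8-9" ... "12-13".
#' @export
alpha_subbands <- function() {
  lo <- 8:12
  sprintf("%d-%d", lo, lo + 1)
}

#' Per-channel mean logit relative power of the five 1-Hz alpha subbands
#'
#' For every channel and subband (8-9 ... 12-13 Hz) the epoch-wise relative
#' power x (fraction of 2-35 Hz power, per 4-s epoch) is logit-transformed
#' and averaged over epochs. Epochs whose absolute amplitude exceeds
#' `reject_uv` on any channel are rejected first (amplitude stand-in for
#' visual artifact screening).
#'
#' @param rec An `eeg_recording` (band-limit it first; see [bandlimit()]).
#' @param epoch_s Epoch length in seconds.
#' @param total_band Analysis band (Hz) used as the denominator.
#' @param reject_uv Artifact rejection threshold in microvolts; `NULL`
#'   disables rejection.
#' @return A data.frame (channel, band, value) with attributes `n_epochs`
#'   and `n_rejected`.
#' @export
subject_subband_table <- function(rec, epoch_s = 4, total_band = c(2, 35),
                                  reject_uv = 100) {
  epochs <- segment_epochs(rec, epoch_s)
  if (!is.null(reject_uv)) {
    keep <- vapply(epochs, function(e) max(abs(e)) <= reject_uv, logical(1))
    n_rejected <- sum(!keep)
    epochs <- epochs[keep]
  } else n_rejected <- 0L
  if (length(epochs) == 0L) stop("no epochs left after artifact rejection")
  bands <- alpha_subbands()
  lo <- 8:12
  out <- expand.grid(channel = rec$labels, band = bands,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vals <- matrix(0, nrow = length(rec$labels), ncol = length(bands),
                 dimnames = list(rec$labels, bands))
  for (ch in seq_along(rec$labels)) {
    # one periodogram per epoch; the five fractions share its denominator
    logits <- vapply(epochs, function(e) {
      pg <- periodogram_hann(e[ch, ], rec$rate)
      in_total <- pg$freq >= total_band[1] & pg$freq < total_band[2]
      tot <- sum(pg$power[in_total])
      if (tot <= 0) stop("zero total power in analysis band")
      vapply(seq_along(lo), function(b) {
        x <- sum(pg$power[in_total & pg$freq >= lo[b] &
                            pg$freq < lo[b] + 1]) / tot
        logit_transform(x)
      }, numeric(1))
    }, numeric(length(lo)))
    vals[ch, ] <- rowMeans(matrix(logits, nrow = length(lo)))
  }
  out$value <- vals[cbind(out$channel, out$band)]
  attr(out, "n_epochs") <- length(epochs)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Individual alpha peak frequency per channel
#'
#' IAPF is the frequency of the maximum of the epoch-averaged power
#' spectrum restricted to 8-13 Hz, at the native resolution of the epochs
#' (0.25 Hz for 4-s epochs). Ties break toward the lower frequency; a
#' maximum sitting on the 8 or 13 Hz boundary is flagged, since it usually
#' means no distinct alpha peak exists.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_s Epoch length in seconds.
#' @param range Alpha search range in Hz (inclusive).
#' @return data.frame (channel, iapf, boundary).
#' @export
estimate_iapf <- function(rec, epoch_s = 4, range = c(8, 13)) {
  epochs <- segment_epochs(rec, epoch_s)
  iapf <- numeric(length(rec$labels))
  boundary <- logical(length(rec$labels))
  for (ch in seq_along(rec$labels)) {
    pgs <- lapply(epochs, function(e) periodogram_hann(e[ch, ], rec$rate))
    freq <- pgs[[1]]$freq
    mean_pow <- Reduce(`+`, lapply(pgs, `[[`, "power")) / length(pgs)
    sel <- freq >= range[1] & freq <= range[2]
    f_sel <- freq[sel]; p_sel <- mean_pow[sel]
    i <- which.max(p_sel)  # first maximum = lower-frequency tie-break
    iapf[ch] <- f_sel[i]
    boundary[ch] <- i == 1L || i == length(f_sel)
  }
  data.frame(channel = rec$labels, iapf = iapf, boundary = boundary,
             stringsAsFactors = FALSE)
}
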