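#' Synthesize a resting EEG recording
#'
#' Builds a multi-channel recording as an amplitude-modulated narrow-band
#' alpha process plus 1/f^a background noise. Each channel's spectrum is
#' assembled in the frequency domain: background amplitude proportional to
#' f^(-a/2) and a Gaussian alpha profile centred at the subject's true peak
#' frequency, both with complex-Gaussian random coefficients (so the alpha
#' component waxes and wanes like real bursts rather than a pure sinusoid).
#' Occipital channels carry the largest alpha amplitude.
#'
#' @param subject One cohort row (list or single-row data.frame) with at
#'   least `id`, `true_iapf`, `true_alpha_power`.
#' @param params An [eeg_gen_params()] bundle; `params$seed` combined with
#'   the subject id gives a private, reproducible RNG stream.
#' @return An `eeg_recording`: list with `samples` (channels x time matrix,
#'   a.u. treated as microvolts), `rate` (Hz) and `labels`.
#' @export
synth_eeg <- function(subject, params = eeg_gen_params()) {
  stop_if_not_scalar_num(params$duration, "duration", positive = TRUE)
  stop_if_not_scalar_num(params$sample_rate, "sample_rate", positive = TRUE)
  iapf <- subject$true_iapf
  amp <- subject$true_alpha_power
  if (is.null(iapf) || is.null(amp))
    stop("subject must carry true_iapf and true_alpha_power")
  n <- round(params$duration * params$sample_rate)
  labels <- params$channels
  gains <- alpha_channel_gain(labels)
  freqs <- seq_len(floor(n / 2)) * params$sample_rate / n
  # Power spectral densities; background floored below 0.5 Hz to avoid the
  # 1/f singularity (the analysis band starts at 2 Hz anyway).
  bg_amp <- params$noise_sd / pmax(freqs, 0.5)^(params$one_over_f_exponent / 2)
  alpha_prof <- exp(-(freqs - iapf)^2 / (2 * params$alpha_bandwidth^2))
  samples <- matrix(0, nrow = length(labels), ncol = n,
                    dimnames = list(labels, NULL))
  for (ch in seq_along(labels)) {
    s <- subject_seed(params$seed, subject$id, paste0("eeg/", labels[ch]))
    x <- with_local_seed(s, {
      m <- length(freqs)
      z_bg <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) /
        sqrt(2)
      z_al <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) /
        sqrt(2)
      half <- bg_amp * z_bg + gains[ch] * amp * sqrt(alpha_prof) * z_al
      spec <- complex(length.out = n)
      spec[1 + seq_len(m)] <- half
      if (n %% 2 == 0) spec[m + 1] <- complex(real = Re(half[m]) * sqrt(2))
      kconj <- seq_len(if (n %% 2 == 0) m - 1 else m)
      spec[n + 1 - kconj] <- Conj(half[kconj])
      Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
    })
    samples[ch, ] <- x
  }
  structure(list(samples = samples, rate = params$sample_rate,
                 labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  invisible(x)
}
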