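#' EEG generator parameters
#'
#' Parameter bundle for the synthetic cohort and EEG generators. Defaults
#' describe a 16-channel 10-20 montage resting recording sampled at 256 Hz
#' for 150 s, an alpha oscillation whose peak frequency declines with age
#' (three times faster in APOE e4 carriers), and a 1/f background.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param channels Channel labels (10-20 names). Alpha amplitude is graded
#'   by scalp region with an occipital maximum.
#' @param iapf_intercept Population alpha peak frequency (Hz) at age 40.
#' @param iapf_age_slope_e4minus,iapf_age_slope_e4plus Age slope of the
#'   individual alpha peak frequency (IAPF), Hz/year, per genotype.
#' @param iapf_sd Residual SD of true IAPF around the age line (Hz).
#' @param alpha_bandwidth SD of the Gaussian spectral profile of the alpha
#'   oscillation (Hz); 0.25 Hz gives a sharp ~0.6 Hz full-width peak that
#'   the 0.25 Hz-resolution estimator can resolve.
#' @param alpha_amplitude Alpha amplitude scale (a.u., occipital channels).
#' @param one_over_f_exponent Exponent of the 1/f^a background power.
#' @param noise_sd Background noise scale (a.u.).
#' @param prop_women Probability a subject is assigned sex "W".
#' @param seed Master seed; every subject derives a private RNG stream from
#'   it and their id, so cohort-size changes do not shift other subjects.
#' @return A list of class `eeg_gen_params`.
#' @export
eeg_gen_params <- function(sample_rate = 256, duration = 150,
                           channels = eeg_channels_1020(),
                           iapf_intercept = 10.2,
                           iapf_age_slope_e4minus = -0.010,
                           iapf_age_slope_e4plus = -0.030,
                           iapf_sd = 0.8,
                           alpha_bandwidth = 0.25,
                           alpha_amplitude = 1.2,
                           one_over_f_exponent = 1.0,
                           noise_sd = 1.0,
                           prop_women = 2 / 3,
                           seed = 1L) {
  stop_if_not_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  stop_if_not_scalar_num(duration, "duration", positive = TRUE)
  if (sample_rate <= 2 * 35)
    stop("sample_rate must exceed twice the highest synthesized frequency")
  if (iapf_age_slope_e4minus > 0 || iapf_age_slope_e4plus > 0)
    warning("positive IAPF age slope: alpha speeds up with age")
  structure(list(
    sample_rate = sample_rate, duration = duration, channels = channels,
    iapf_intercept = iapf_intercept,
    iapf_age_slope_e4minus = iapf_age_slope_e4minus,
    iapf_age_slope_e4plus = iapf_age_slope_e4plus,
    iapf_sd = iapf_sd, alpha_bandwidth = alpha_bandwidth,
    alpha_amplitude = alpha_amplitude,
    one_over_f_exponent = one_over_f_exponent, noise_sd = noise_sd,
    prop_women = prop_women, seed = seed
  ), class = "eeg_gen_params")
}

#' Standard 16-channel 10-20 montage labels
#' @return Character vector of channel names.
#' @export
eeg_channels_1020 <- function() {
  c("O2", "O1", "P4", "P3", "C4", "C3", "F4", "F3",
    "Fp2", "Fp1", "T6", "T5", "T4", "T3", "F8", "F7")
}

# Regional alpha gain: posterior dominance of the resting alpha rhythm.
alpha_channel_gain <- function(channels) {
  gain <- c(O2 = 1, O1 = 1, P4 = 0.9, P3 = 0.9, C4 = 0.75, C3 = 0.75,
            F4 = 0.6, F3 = 0.6, Fp2 = 0.5, Fp1 = 0.5, T6 = 0.7, T5 = 0.7,
            T4 = 0.6, T3 = 0.6, F8 = 0.5, F7 = 0.5)
  out <- gain[channels]
  out[is.na(out)] <- 0.6
  names(out) <- channels
  out
}

#' Generate a synthetic cohort
#'
#' One row per subject: demographics, APOE genotype, age group (threshold
#' 50 years), and the ground-truth generative parameters (`true_iapf`,
#' `true_alpha_power`) later consumed by [synth_eeg()]. Ages are uniform on
#' 26-79; `true_iapf` follows a genotype-specific age line centred at age 40
#' plus Gaussian noise, clamped to 7-14 Hz.
#'
#' @param n_e4minus,n_e4plus Subject counts per genotype.
#' @param params An [eeg_gen_params()] bundle.
#' @param seed Master seed (overrides `params$seed` when given).
#' @return A `data.frame` (cohort table).
#' @export
generate_cohort <- function(n_e4minus, n_e4plus, params = eeg_gen_params(),
                            seed = params$seed) {
  if (!is.numeric(n_e4minus) || !is.numeric(n_e4plus) ||
      n_e4minus < 0 || n_e4plus < 0)
    stop("subject counts must be non-negative")
  n_e4minus <- as.integer(n_e4minus); n_e4plus <- as.integer(n_e4plus)
  ids <- c(if (n_e4minus > 0) sprintf("E4m_%03d", seq_len(n_e4minus)),
           if (n_e4plus > 0) sprintf("E4p_%03d", seq_len(n_e4plus)))
  genotype <- rep(c("E4minus", "E4plus"), c(n_e4minus, n_e4plus))
  n <- length(ids)
  if (n == 0L) {
    return(data.frame(id = character(), age = numeric(), sex = character(),
                      genotype = character(), age_group = character(),
                      true_iapf = numeric(), true_alpha_power = numeric(),
                      stringsAsFactors = FALSE))
  }
  age <- numeric(n); sex <- character(n)
  true_iapf <- numeric(n); true_alpha_power <- numeric(n)
  for (i in seq_len(n)) {
    s <- subject_seed(seed, ids[i], "cohort")
    draws <- with_local_seed(s, {
      list(age = stats::runif(1, 26, 79),
           sex = if (stats::runif(1) < params$prop_women) "W" else "M",
           iapf_noise = stats::rnorm(1, 0, params$iapf_sd),
           amp_noise = stats::rnorm(1, 0, 0.1))
    })
    slope <- if (genotype[i] == "E4plus") params$iapf_age_slope_e4plus
             else params$iapf_age_slope_e4minus
    age[i] <- draws$age
    sex[i] <- draws$sex
    true_iapf[i] <- min(14, max(7, params$iapf_intercept +
                                  slope * (draws$age - 40) + draws$iapf_noise))
    true_alpha_power[i] <- params$alpha_amplitude * exp(draws$amp_noise)
  }
  data.frame(id = ids, age = age, sex = sex, genotype = genotype,
             age_group = ifelse(age < 50, "younger", "older"),
             true_iapf = true_iapf, true_alpha_power = true_alpha_power,
             stringsAsFactors = FALSE)
}
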