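test_that("band-pass passes in-band tones and rejects out-of-band tones", {
  t <- seq(1 / 256, 30, by = 1 / 256)
  tone <- function(f) sin(2 * pi * f * t)
  rms <- function(x) sqrt(mean(x^2))
  out1 <- bandlimit(mk_rec(tone(1)))
  expect_lt(rms(out1$samples), 0.1 * rms(tone(1)))
  out10 <- bandlimit(mk_rec(tone(10)))
  expect_lt(abs(rms(out10$samples) / rms(tone(10)) - 1), 0.05)
  expect_error(bandlimit(mk_rec(tone(10)), low = 2, high = 128), "rate/2")
  expect_error(bandlimit(mk_rec(tone(10)), low = 10, high = 5), "rate/2")
})

test_that("epoch segmentation drops the trailing remainder", {
  rec <- mk_rec(rnorm(150 * 256))
  eps <- segment_epochs(rec, 4)
  expect_length(eps, 37)
  expect_true(all(vapply(eps, ncol, integer(1)) == 1024))
  expect_length(segment_epochs(mk_rec(rnorm(8 * 256)), 4), 2)
  expect_error(segment_epochs(mk_rec(rnorm(3 * 256)), 4), "shorter")
})

test_that("relative powers behave like spectral fractions", {
  set.seed(1)
  x <- rnorm(1024)
  # partition: the 33 1-Hz bins of 2-35 Hz sum to 1
  fracs <- vapply(2:34, function(f)
    epoch_relative_power(x, 256, c(f, f + 1)), numeric(1))
  expect_equal(sum(fracs), 1, tolerance = 1e-12)
  # white noise: each bin near 1/33
  many <- replicate(200, epoch_relative_power(rnorm(1024), 256, c(10, 11)))
  expect_equal(mean(many), 1 / 33, tolerance = 0.05)
  # a pure in-bin tone concentrates its band
  tone <- sin(2 * pi * 10.5 * seq(1 / 256, 4, by = 1 / 256))
  expect_gt(epoch_relative_power(tone, 256, c(10, 11)), 0.9)
  expect_error(epoch_relative_power(x, 256, c(1, 3)), "within total_band")
})

test_that("logit transform is the natural-log logit with clamping", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.9), log(9))
  expect_equal(logit_transform(0.1), -log(9))
  expect_equal(logit_transform(0.9), -logit_transform(0.1))
  expect_warning(v <- logit_transform(c(0, 1)), "clamped")
  expect_equal(v, c(log(1e-6 / (1 - 1e-6)), -log(1e-6 / (1 - 1e-6))))
  # monotone: preserves ordering of fractions
  x <- sort(runif(20, 0.01, 0.99))
  expect_true(all(diff(logit_transform(x)) > 0))
})

test_that("subband table is flat for white noise and peaked for a tone", {
  set.seed(2)
  rec <- mk_rec(rnorm(300 * 256))
  st <- subject_subband_table(rec, reject_uv = NULL)
  bm <- tapply(st$value, st$band, mean)
  expect_lt(max(bm) - min(bm), 0.2)
  # strong 11.5 Hz alpha: the 11-12 subband dominates
  t <- seq(1 / 256, 60, by = 1 / 256)
  rec2 <- mk_rec(3 * sin(2 * pi * 11.5 * t) + rnorm(length(t)))
  st2 <- subject_subband_table(rec2, reject_uv = NULL)
  bm2 <- tapply(st2$value, st2$band, mean)
  expect_equal(names(which.max(bm2)), "11-12")
})

test_that("single-epoch table equals that epoch's logit fractions", {
  set.seed(3)
  rec <- mk_rec(rnorm(4 * 256))
  st <- subject_subband_table(rec, reject_uv = NULL)
  direct <- vapply(8:12, function(f)
    logit_transform(epoch_relative_power(rec$samples[1, ], 256,
                                         c(f, f + 1))), numeric(1))
  expect_equal(st$value, direct)
  expect_equal(attr(st, "n_epochs"), 1L)
})

test_that("amplitude-threshold artifact rejection drops loud epochs", {
  set.seed(4)
  x <- rnorm(12 * 256)
  x[3000] <- 500  # a spike in epoch 3
  st <- subject_subband_table(mk_rec(x), reject_uv = 100)
  expect_equal(attr(st, "n_rejected"), 1L)
  expect_equal(attr(st, "n_epochs"), 2L)
})

test_that("IAPF is the argmax of the mean spectrum with lower tie-break", {
  # two equal tones at 9 and 11 Hz: tie resolves to 9
  t <- seq(1 / 256, 20, by = 1 / 256)
  rec <- mk_rec(sin(2 * pi * 9 * t) + sin(2 * pi * 11 * t))
  ia <- estimate_iapf(rec)
  expect_equal(ia$iapf, 9)
  # monotone 1/f-ish spectrum with no alpha: boundary at 8 flagged
  p <- eeg_gen_params(seed = 12, duration = 60)
  subj <- list(id = "s", true_iapf = 10, true_alpha_power = 0)
  reco <- synth_eeg(subj, p)
  ia2 <- estimate_iapf(reco)
  expect_true(ia2$boundary[ia2$iapf == 8][1])
})

test_that("relative powers and IAPF are scale invariant", {
  p <- eeg_gen_params(seed = 13, duration = 20)
  subj <- list(id = "s", true_iapf = 10.5, true_alpha_power = 1.2)
  rec <- synth_eeg(subj, p)
  scaled <- rec
  scaled$samples <- rec$samples * 37.5
  expect_equal(subject_subband_table(rec, reject_uv = NULL)$value,
               subject_subband_table(scaled, reject_uv = NULL)$value)
  expect_equal(estimate_iapf(rec)$iapf, estimate_iapf(scaled)$iapf)
})
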