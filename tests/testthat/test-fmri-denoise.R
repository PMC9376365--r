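test_that("motion expansion yields the canonical 24 columns", {
  set.seed(41)
  m <- matrix(rnorm(50 * 6), 50, 6)
  x <- motion_expand(m)
  expect_equal(ncol(x), 24)
  expect_true(all(motion_expand(matrix(0, 20, 6)) == 0))
  # a linear ramp has a constant derivative after row 1
  ramp <- matrix(0, 30, 6); ramp[, 1] <- seq(0, 2.9, by = 0.1)
  d <- motion_expand(ramp)[, 7]
  expect_equal(d[1], 0)
  expect_true(all(abs(d[-1] - 0.1) < 1e-12))
  expect_error(motion_expand(m[, 1:5]), "6 columns")
})

test_that("framewise displacement follows the Power formula", {
  m <- matrix(0, 20, 6)
  expect_equal(framewise_displacement(m), rep(0, 20))
  m2 <- m; m2[10, 1] <- 1    # 1 mm x-jump at volume 10
  fd <- framewise_displacement(m2)
  expect_equal(fd[10], 1)
  expect_equal(fd[11], 1)    # and back
  m3 <- m; m3[5:20, 4] <- 0.01  # rotation step of 0.01 rad
  expect_equal(framewise_displacement(m3)[5], 0.5)  # 50 mm x 0.01
})

test_that("scrubbing censors strictly above the empirical percentile", {
  fd <- seq_len(100)  # 100 distinct values
  sc <- scrub_mask(fd, 97)
  expect_equal(sum(sc$mask), 3)
  expect_equal(ncol(sc$spikes), 3)
  expect_true(all(colSums(sc$spikes) == 1))
  expect_equal(sum(scrub_mask(rep(1, 50))$mask), 0)
  expect_equal(sum(scrub_mask(fd, 0)$mask), 99)  # all above the minimum
})

test_that("aCompCor returns ordered unit-variance components per tissue", {
  set.seed(42)
  n <- 120
  lat <- matrix(rnorm(n * 2), n, 2)
  noise <- cbind(lat %*% matrix(rnorm(2 * 6), 2, 6),
                 matrix(rnorm(n * 6), n, 6))
  tissues <- rep(c("wm", "csf"), each = 6)
  cc <- acompcor(noise, tissues, k_per_tissue = 5)
  expect_equal(ncol(cc), 10)
  expect_equal(apply(cc, 2, sd), rep(1, 10), ignore_attr = TRUE)
  # rank-2 wm block: first two components explain all wm variance
  expl <- attr(cc, "explained")$wm
  expect_equal(sum(expl[1:2]), 1, tolerance = 1e-10)
  expect_true(all(diff(attr(cc, "explained")$csf) <= 1e-12))
  expect_error(acompcor(matrix(1, 50, 4), rep(c("wm", "csf"), 2)),
               "zero-variance")
})

test_that("residualization is invariant to component sign flips", {
  set.seed(43)
  y <- matrix(rnorm(100), 100, 1)
  cc <- matrix(rnorm(300), 100, 3)
  r1 <- qr.resid(qr(cbind(1, cc)), y)
  r2 <- qr.resid(qr(cbind(1, cc %*% diag(c(-1, 1, -1)))), y)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("denoise projects out the design and band-passes residuals", {
  set.seed(44)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  # an exact linear combination is annihilated
  y <- X %*% runif(5) + 3
  den <- denoise(matrix(y, ncol = 1), X, tr = 1.5)
  expect_lt(max(abs(attr(den, "residuals_prefilter"))), 1e-8)
  # residual orthogonality on noisy data
  y2 <- matrix(rnorm(n * 3), n, 3)
  den2 <- denoise(y2, X, tr = 1.5)
  rp <- attr(den2, "residuals_prefilter")
  expect_lt(max(abs(cor(rp, X))), 1e-10)
  # out-of-band tone is attenuated by >= 20 dB
  tone <- sin(2 * pi * 0.2 * seq_len(n) * 1.5)
  den3 <- denoise(matrix(tone, ncol = 1), matrix(rnorm(n), ncol = 1),
                  tr = 1.5)
  expect_lt(sqrt(mean(den3^2)) / sqrt(mean(tone^2)), 0.1)
  expect_warning(denoise(y2, cbind(X, X[, 1]), tr = 1.5),
                 "rank-deficient")
})

test_that("denoising brings planted couplings closer than raw", {
  p <- bold_gen_params(seed = 45, n_volumes = 300)
  err <- function(r, truth) sqrt(mean((r - truth)[upper.tri(r)]^2))
  e_raw <- c(); e_den <- c()
  for (i in 1:4) {
    ses <- synth_bold(list(id = paste0("s", i),
                           genotype = c("E4minus", "E4plus")[1 + i %% 2]), p)
    des <- nuisance_design(ses)
    den <- denoise(ses$roi, des, tr = ses$tr)
    r_den <- tanh(unclass(connectivity(den)))
    r_den[is.na(r_den)] <- 1
    truth <- ses$truth; diag(truth) <- 1
    e_raw <- c(e_raw, err(cor(ses$roi), truth))
    e_den <- c(e_den, err(r_den, truth))
  }
  expect_lt(mean(e_den), mean(e_raw))
})

test_that("censored volumes have zero leverage on connectivity", {
  p <- bold_gen_params(seed = 46, n_volumes = 200)
  ses <- synth_bold(list(id = "cz", genotype = "E4plus"), p)
  des <- nuisance_design(ses)
  idx <- which(des$censored)
  expect_gt(length(idx), 0)
  z1 <- connectivity(denoise(ses$roi, des, tr = ses$tr))
  ses$roi[idx[1], ] <- ses$roi[idx[1], ] + 1000
  z2 <- connectivity(denoise(ses$roi, des, tr = ses$tr))
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-8)
})
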