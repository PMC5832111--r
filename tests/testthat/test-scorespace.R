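test_that("reference signals have the documented shape and content", {
  Y <- reference_signals(10, n_harmonics = 2, fs = 250, n_samples = 2500)
  expect_equal(dim(Y), c(2500L, 4L))
  t <- (0:2499) / 250
  expect_equal(Y[, 1], sin(2 * pi * 10 * t))
  expect_equal(Y[, 2], cos(2 * pi * 10 * t))
  expect_equal(Y[, 3], sin(2 * pi * 20 * t))
  # pairwise orthogonality over an integer number of cycles
  G <- crossprod(Y)
  expect_equal(G - diag(diag(G)), matrix(0, 4, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(reference_signals(70, 2, fs = 250, n_samples = 100),
               "Nyquist")
})

test_that("cca_score is perfect on a noiseless matched segment, bounded always", {
  seg <- tone_segment(10)
  expect_gte(cca_score(seg, 10), 0.99)
  set.seed(6)
  for (i in 1:10) {
    noise <- eeg_segment(matrix(rnorm(500 * 3), 500, 3), 250)
    s <- cca_score(noise, 7 + 10 * runif(1))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("cca_score matches an explicit covariance eigen-decomposition", {
  # independent oracle: largest eigenvalue of Sxx^-1 Sxy Syy^-1 Syx
  set.seed(13)
  n <- 400
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 1] <- X[, 1] + sin(2 * pi * 9 * (0:(n - 1)) / 250)
  seg <- eeg_segment(X, 250)
  Y <- reference_signals(9, 2, 250, n)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc) / n; Syy <- crossprod(Yc) / n
  Sxy <- crossprod(Xc, Yc) / n
  Mmat <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  rho_oracle <- sqrt(max(Re(eigen(Mmat)$values)))
  expect_equal(cca_score(seg, 9), rho_oracle, tolerance = 1e-8)
  # and against the stock implementation on well-conditioned data
  expect_equal(cca_score(seg, 9), stats::cancor(Xc, Yc)$cor[1],
               tolerance = 1e-8)
})

test_that("a constant channel degrades gracefully instead of failing", {
  seg <- tone_segment(12, duration = 4)
  seg$samples[, 3] <- 7            # rank-deficient
  s <- cca_score(seg, 12)
  expect_gte(s, 0.99)
  expect_lte(s, 1)
})

test_that("the score curve peaks at the stimulated frequency", {
  seg <- tone_segment(12)
  cur <- cca_score_curve(seg)
  expect_equal(nrow(cur), 101L)
  expect_equal(cur$frequency[which.max(cur$score)], 12)
})

test_that("jitter displaces and attenuates the CCA peak (paired simulation)", {
  clean <- tone_segment(10, seed = 30)
  jit <- tone_segment(10, seed = 30, jitter_mean = jitter_measured(10),
                      jitter_sd = 0.004)
  cur_c <- cca_score_curve(clean)
  cur_j <- cca_score_curve(jit)
  peak_j <- cur_j$frequency[which.max(cur_j$score)]
  expect_lt(abs(peak_j - 10), 0.3 + 1e-9)
  expect_lt(max(cur_j$score), max(cur_c$score))
})

test_that("cca is scale invariant and psd scales quadratically", {
  seg <- tone_segment(10, duration = 4)
  seg3 <- eeg_segment(3 * seg$samples, seg$fs)
  expect_equal(cca_score(seg, 10), cca_score(seg3, 10), tolerance = 1e-9)
  p1 <- psd_curve(seg)
  p3 <- psd_curve(seg3)
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-9)
})

test_that("psd_curve localises power and respects Parseval's bound", {
  seg <- tone_segment(15)
  pc <- psd_curve(seg)
  per_ch <- split(pc, pc$channel)
  for (ch in per_ch) {
    expect_equal(ch$frequency[which.max(ch$power)], 15)
    expect_true(all(ch$power >= 0))
  }
  # integrated grid power cannot exceed the total signal variance
  ch1 <- per_ch[[1]]
  grid_power <- sum(ch1$power) * 0.1
  expect_lte(grid_power, var(seg$samples[, 1]) * 1.05)
  expect_error(psd_curve(tone_segment(10, duration = 1), window_sec = 2.5),
               "longer than the segment")
})

test_that("white-noise PSD is flat under long averaging", {
  set.seed(99)
  x <- matrix(rnorm(250 * 120), ncol = 1)   # 2 minutes, many Welch windows
  pc <- psd_curve(eeg_segment(x, 250))
  expect_lt(max(pc$power) / min(pc$power), 3)
  expect_equal(mean(pc$power), 1 / 125, tolerance = 0.1)  # sd^2/(fs/2)
})

test_that("select_best_channel maximises the peak-to-second-peak margin", {
  grid <- frequency_grid()
  nf <- length(grid$freqs)
  base <- rep(0.5, nf)
  ch1 <- base; ch1[21] <- 10; ch1[61] <- 8    # margin 2
  ch2 <- base; ch2[31] <- 9; ch2[81] <- 3     # margin 6
  toy <- tibble::tibble(frequency = rep(grid$freqs, 2),
                        channel = rep(1:2, each = nf),
                        power = c(ch1, ch2))
  class(toy) <- c("psd_curve", class(toy))
  expect_equal(select_best_channel(toy), 2L)

  single <- toy[toy$channel == 1, ]
  class(single) <- c("psd_curve", class(single))
  expect_equal(select_best_channel(single), 1L)

  # a clean SSVEP channel beats pure-noise channels at high SNR
  set.seed(2)
  seg <- tone_segment(12, duration = 5)
  noisy <- seg$samples * 0
  noisy[, 4] <- seg$samples[, 4]              # only channel 4 has signal
  noisy[, -4] <- rnorm(length(noisy[, -4])) * 0.3
  pc <- psd_curve(eeg_segment(noisy, 250))
  expect_equal(select_best_channel(pc), 4L)
})
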