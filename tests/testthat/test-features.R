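test_that("the default partition scheme has nine bands containing the targets", {
  scheme <- default_partitions()
  b <- scheme$boundaries
  expect_length(b, 10L)
  expect_equal(scheme$n_partitions, 9L)
  expect_true(all(diff(b) > 0))
  expect_equal(b[1], 7)
  expect_equal(b[10], 17)
  # each target strictly inside a band: positive distance to both edges
  for (f in c(8.5, 10, 12, 15)) {
    k <- findInterval(f, b)
    expect_gt(f - b[k], 0)
    expect_gt(b[k + 1] - f, 0)
  }
  expect_error(partition_scheme(c(7, 8.5, 9, 10.5, 11.5, 12.5, 13.5, 14.5,
                                  15.5, 17)), "strictly inside")
  expect_error(partition_scheme(1:5), "10 strictly increasing")
})

test_that("CCA partition statistics on a constant curve are in closed form", {
  grid <- frequency_grid()
  cur <- tibble::tibble(frequency = grid$freqs, score = 0.4)
  st <- partition_stats_cca(cur)
  expect_length(st, 36L)
  scheme <- default_partitions()
  k <- findInterval(grid$freqs, scheme$boundaries, rightmost.closed = TRUE)
  for (p in 1:9) {
    n_p <- sum(k == p)
    expect_equal(st[[sprintf("cca_p%d_power", p)]], 0.16)
    expect_equal(st[[sprintf("cca_p%d_mean", p)]], 0.4)
    expect_equal(st[[sprintf("cca_p%d_sd", p)]], 0)
    expect_equal(st[[sprintf("cca_p%d_entropy", p)]], log(n_p))
  }
})

test_that("partition statistics match hand arithmetic on toy curves", {
  # three points in one band: scores 0.2, 0.4, 0.4
  s <- c(0.2, 0.4, 0.4)
  cur <- tibble::tibble(frequency = c(7.2, 7.5, 7.8),
                        score = s)
  # restrict the scheme check to the band containing the points by
  # computing the stats directly
  st <- partition_stats_cca(
    tibble::tibble(
      frequency = c(cur$frequency,
                    seq(8.5, 16.9, length.out = 30)),  # fill other bands
      score = c(s, rep(0.1, 30))))
  expect_equal(st[["cca_p1_mean"]], 1 / 3)
  expect_equal(st[["cca_p1_power"]], mean(s^2))
  expect_equal(st[["cca_p1_sd"]], sqrt(mean((s - mean(s))^2)))
  p <- s / sum(s)
  expect_equal(st[["cca_p1_entropy"]], -sum(p * log(p)))

  # four PSD points in one band: 1, 2, 3, 4
  pow <- c(1, 2, 3, 4)
  psd <- tibble::tibble(
    frequency = c(7.1, 7.4, 7.7, 8.0, seq(8.5, 16.9, length.out = 30)),
    channel = 1L,
    power = c(pow, rep(0.5, 30)))
  class(psd) <- c("psd_curve", class(psd))
  st2 <- partition_stats_psd(psd, channel = 1L)
  expect_length(st2, 18L)
  expect_equal(st2[["psd_p1_mean"]], 2.5)
  expect_equal(st2[["psd_p1_sd"]], sqrt(1.25))
})

test_that("an all-zero partition gets maximal entropy and zero sd", {
  grid <- frequency_grid()
  cur <- tibble::tibble(frequency = grid$freqs, score = 0)
  st <- partition_stats_cca(cur)
  scheme <- default_partitions()
  k <- findInterval(grid$freqs, scheme$boundaries, rightmost.closed = TRUE)
  expect_equal(st[["cca_p3_entropy"]], log(sum(k == 3)))
  expect_equal(st[["cca_p3_sd"]], 0)
})

test_that("fuse concatenates 36 + 18 into 54 and is sliceable", {
  cca <- setNames(runif(36), fusion_feature_names()[1:36])
  psd <- setNames(runif(18), fusion_feature_names()[37:54])
  v <- fuse(cca, psd)
  expect_length(v, 54L)
  expect_equal(v[1:36], cca)
  expect_equal(v[37:54], psd)
  expect_error(fuse(cca[1:35], psd), "36")
  expect_error(fuse(cca, psd[1:17]), "18")
  expect_error(fuse(replace(cca, 1, NaN), psd), "finite")
})

test_that("entropy features respect their bounds on real curves", {
  ft <- small_features()
  scheme <- default_partitions()
  grid <- frequency_grid()
  k <- findInterval(grid$freqs, scheme$boundaries, rightmost.closed = TRUE)
  for (p in 1:9) {
    h <- ft[[sprintf("cca_p%d_entropy", p)]]
    expect_true(all(h >= 0 - 1e-12))
    expect_true(all(h <= log(sum(k == p)) + 1e-12))
  }
})

test_that("fusion vectors have 54 dimensions regardless of grid step", {
  seg <- tone_segment(10, duration = 4)
  for (step in c(0.1, 0.05, 0.25)) {
    grid <- frequency_grid(step = step)
    cur <- cca_score_curve(seg, grid)
    pc <- psd_curve(seg, grid)
    v <- fuse(partition_stats_cca(cur), partition_stats_psd(pc, channel = 1))
    expect_length(v, 54L)
  }
})

test_that("the stimulated band carries the largest CCA power at high SNR", {
  ft <- small_features()
  scheme <- default_partitions()
  power_cols <- sprintf("cca_p%d_power", 1:9)
  band_of <- function(f) findInterval(f, scheme$boundaries)
  hits <- mapply(function(i) {
    p <- as.numeric(ft[i, power_cols])
    which.max(p) == band_of(ft$frequency[i])
  }, seq_len(nrow(ft)))
  expect_gt(mean(hits), 0.9)
})

test_that("extract_features emits one labeled row per frame", {
  ft <- small_features()
  # 3 subjects x 4 freqs x 3 trials x 2 frames (5 s / 2.5 s)
  expect_equal(nrow(ft), 72L)
  expect_equal(ncol(ft), 5L + 54L)
  expect_true(all(fusion_feature_names() %in% names(ft)))
  expect_true(all(table(ft$subject) == 24L))
  # channel selection is per subject: constant within subject
  per_subj <- tapply(ft$channel, ft$subject, function(ch) length(unique(ch)))
  expect_true(all(per_subj == 1L))
})
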