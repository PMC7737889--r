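test_that("Welch CSD segmentation, normalisation and auto-spectra are correct", {
  fs <- 200
  x <- withr::with_seed(1, rnorm(3 * fs))
  cs <- welch_csd(x, x, fs)
  expect_equal(cs$n_segments, 5)               # 3 s, 1 s segments, 50% overlap
  expect_equal(diff(cs$freqs)[1], 1)           # 1 Hz grid
  expect_true(all(abs(Im(cs$Pxy)) < 1e-12))    # auto-spectrum is real
  expect_equal(Re(cs$Pxy), cs$Pxx)
  # Parseval: grid average of Pxx ~ total power (white noise)
  expect_lt(abs(mean(cs$Pxx) - var(x)) / var(x), 0.10)
  expect_error(welch_csd(x[1:100], x[1:100], fs), "longer than")
})

test_that("welch_csd equals a direct DFT evaluation to machine precision", {
  fs <- 32
  withr::with_seed(7, {
    x <- rnorm(64)
    y <- rnorm(64)
  })
  cs <- welch_csd(x, y, fs, seg_len = 1, overlap = 0.5)
  ref <- h_direct_csd(x, y, fs, seg_len = 1, overlap = 0.5)
  expect_equal(cs$Pxy, ref$Pxy, tolerance = 1e-10)
  expect_equal(cs$Pxx, ref$Pxx, tolerance = 1e-10)
  expect_equal(cs$Pyy, ref$Pyy, tolerance = 1e-10)
  # and so does the ImCoh spectrum built from it
  expect_equal(imcoh_spectrum(cs),
               Im(ref$Pxy)^2 / (ref$Pxx * ref$Pyy), tolerance = 1e-10)
})

test_that("imaginary coherence is zero for identical signals, one in quadrature", {
  fs <- 200
  x <- withr::with_seed(2, rnorm(3 * fs))
  expect_true(all(imcoh_spectrum(welch_csd(x, x, fs)) < 1e-20))

  # quarter-cycle-shifted 20 Hz tone: ImCoh ~ 1 at the carrier
  t <- seq(0, 3, by = 1 / fs)[-1]
  withr::with_seed(3, {
    s <- sin(2 * pi * 20 * t)
    x2 <- s + 0.01 * rnorm(length(t))
    y2 <- sin(2 * pi * 20 * t - pi / 2) + 0.01 * rnorm(length(t))
  })
  v <- imcoh_spectrum(welch_csd(x2, y2, fs))
  expect_gt(v[which(welch_csd(x2, y2, fs)$freqs == 20)], 0.95)

  # signed convention: quadrature gives |Im coherency| ~ 1 with a sign
  vs <- imcoh_spectrum(welch_csd(x2, y2, fs), squared = FALSE)
  expect_gt(abs(vs[21]), 0.95)
})

test_that("band ImCoh recovers the analytic mixing value (epoch-pooled)", {
  fs <- 200
  n_ep <- 60
  eps <- withr::with_seed(11, {
    lapply(seq_len(n_ep), function(i) {
      h_mixing_pair(600, fs, 13, 29.99, a = 1, phi = pi / 4, ps = 1, n1 = 1, n2 = 1)
    })
  })
  ep <- withr::with_seed(12, h_pair_epochs(eps, fs))
  # pooled estimator over blocks: mean within 3 MC SE of 0.125
  blocks <- split(seq_len(n_ep), rep(1:6, each = 10))
  vals <- vapply(blocks, function(ii) {
    sub <- ep
    sub$kept <- seq_len(n_ep) %in% ii
    band_filter_then_imcoh(sub, "Fz-Cz", "beta", average = "csd")
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.125), 3 * se + 0.01)

  # the per-epoch mode returns one value per kept epoch
  pe <- band_filter_then_imcoh(ep, "Fz-Cz", "beta", average = "epoch")
  expect_length(pe, n_ep)
  expect_true(all(pe >= 0 & pe <= 1))
})

test_that("band coupling is band-specific: gamma-coupled pair shows no delta ImCoh", {
  fs <- 200
  eps <- withr::with_seed(21, {
    lapply(1:30, function(i) {
      g <- h_mixing_pair(600, fs, 30, 40.5, a = 1, phi = pi / 2, ps = 4, n1 = 0.1, n2 = 0.1)
      d1 <- h_band_noise(600, fs, 0.5, 3.99, 4)
      d2 <- h_band_noise(600, fs, 0.5, 3.99, 4)
      list(x = g$x + d1, y = g$y + d2)
    })
  })
  ep <- withr::with_seed(22, h_pair_epochs(eps, fs))
  v_gamma <- band_filter_then_imcoh(ep, "Fz-Cz", "gamma", average = "csd")
  v_delta <- band_filter_then_imcoh(ep, "Fz-Cz", "delta", average = "csd")
  expect_gt(v_gamma, 0.8)
  expect_lt(v_delta, 0.15)
})

test_that("ImCoh is symmetric, scale-invariant, bounded, order-invariant", {
  fs <- 200
  eps <- withr::with_seed(31, {
    lapply(1:10, function(i) h_mixing_pair(600, fs, 13, 29.99, phi = pi / 3))
  })
  ep <- withr::with_seed(32, h_pair_epochs(eps, fs))
  v_xy <- band_filter_then_imcoh(ep, "Fz-Cz", "beta", average = "epoch")
  v_yx <- band_filter_then_imcoh(ep, "Cz-Fz", "beta", average = "epoch")
  expect_equal(v_xy, v_yx, tolerance = 1e-12)

  # rescaling one channel changes nothing
  ep_scaled <- ep
  ep_scaled$data[, 1, ] <- 7.3 * ep_scaled$data[, 1, ]
  ep_scaled$data[, 2, ] <- 0.2 * ep_scaled$data[, 2, ]
  expect_equal(band_filter_then_imcoh(ep_scaled, "Fz-Cz", "beta", average = "epoch"),
               v_xy, tolerance = 1e-8)

  # epoch order invariance of the subject-level mean
  perm <- c(7, 2, 9, 4, 1, 10, 3, 8, 5, 6)
  ep_perm <- ep
  ep_perm$data <- ep$data[perm, , , drop = FALSE]
  expect_equal(mean(band_filter_then_imcoh(ep_perm, "Fz-Cz", "beta", average = "epoch")),
               mean(v_xy), tolerance = 1e-12)

  expect_true(all(v_xy >= 0 & v_xy <= 1))
})

test_that("the subject feature set has exactly 30 bounded values in fixed order", {
  fs <- 200
  data <- withr::with_seed(41, array(rnorm(6 * 4 * 600), c(6, 4, 600)))
  ep <- structure(list(data = data, fs = fs, t_pre = 1, t_post = 2,
                       channel_names = c("Fz", "Cz", "Pz", "Fp1"),
                       labels = rep("frequent", 6), kept = rep(TRUE, 6)),
                  class = "olf_epochs")
  f <- subject_features(ep)
  expect_length(f, 30)
  expect_identical(names(f), olfcoh:::olf_feature_names())
  expect_true(all(f >= 0 & f <= 1))

  # degenerate identical channels: all values 0
  ep0 <- ep
  for (ch in 2:4) ep0$data[, ch, ] <- ep0$data[, 1, ]
  expect_true(all(subject_features(ep0) < 1e-20))

  # amplitude scale invariance of the whole feature set
  ep2 <- ep
  ep2$data <- 2 * ep2$data
  expect_equal(subject_features(ep2), f, tolerance = 1e-10)

  ep_none <- ep
  ep_none$kept[] <- FALSE
  expect_error(subject_features(ep_none), "no kept epochs")
})
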