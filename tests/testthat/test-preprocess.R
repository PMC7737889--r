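make_rec <- function(x_list, fs, events = NULL) {
  m <- do.call(cbind, x_list)
  colnames(m) <- c("Fz", "Cz", "Pz", "Fp1")[seq_len(ncol(m))]
  recording(m, fs, events)
}

test_that("band limiting passes in-band tones, rejects out-of-band, removes DC", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)[-1]
  tone <- function(f) sin(2 * pi * f * t)
  rec <- make_rec(list(tone(10), tone(90), tone(10) + 100, rnorm(length(t))), fs)
  out <- bandlimit(rec, 0.5, 40.5)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))  # skip edges
  amp <- function(x) sqrt(2 * mean(x[mid]^2))
  expect_lt(abs(amp(out$samples[, "Fz"]) - 1), 0.05)        # 10 Hz preserved
  # 90 Hz is > 1 octave above 40.5 -> at least 20 dB down
  expect_lt(amp(out$samples[, "Cz"]), 0.1)
  expect_lt(abs(mean(out$samples[mid, "Pz"])), 1)           # DC removed
  expect_error(bandlimit(rec, 40, 0.5), "band edges")
  expect_error(bandlimit(rec, 0.5, 2000), "band edges")
})

test_that("decimation preserves duration, waveform shape and event times", {
  fs <- 2000
  t <- seq(0, 6, by = 1 / fs)[-1]
  tone <- sin(2 * pi * 10 * t)
  ev <- data.frame(onset_s = c(2, 4), label = c("frequent", "rare"))
  rec <- make_rec(list(tone, tone, tone, tone), fs, ev)
  out <- resample_recording(rec, 200)
  expect_equal(out$fs, 200)
  expect_lt(abs(nrow(out$samples) / 200 - nrow(rec$samples) / 2000), 1 / 200)
  expect_identical(out$events, rec$events)
  t2 <- (seq_len(nrow(out$samples)) - 1) / 200
  mid <- seq(200, nrow(out$samples) - 200)
  expect_gt(cor(out$samples[mid, "Fz"], sin(2 * pi * 10 * t2[mid])), 0.999)

  # identity and arithmetic
  expect_identical(resample_recording(rec, 2000), rec)
  long <- recording(matrix(rnorm(240000 * 2), ncol = 2,
                           dimnames = list(NULL, c("Fz", "Cz"))), 200)
  expect_equal(nrow(long$samples), 1200 * 200)
  expect_error(resample_recording(rec, 4000), "upsampling")
  expect_error(resample_recording(rec, 300), "integer")
})

test_that("ICA isolates and removes the injected blink component", {
  fs <- 200
  n <- fs * 120
  withr::with_seed(77, {
    base <- replicate(4, h_band_noise(n, fs, 0.5, 40.5, 150), simplify = FALSE)
    tpl <- olfcoh:::blink_template(fs)
    blink <- numeric(n)
    starts <- round(seq(fs, n - fs, length.out = 30))
    for (s in starts) blink[s + seq_along(tpl) - 1] <- blink[s + seq_along(tpl) - 1] + tpl
    gains <- c(0.2, 0.2, 0.2, 1)
    chans <- lapply(1:4, function(i) base[[i]] + 150 * gains[i] * blink)
  })
  rec <- make_rec(chans, fs)
  expect_gt(abs(cor(rec$samples[, "Fp1"], blink)), 0.8)
  clean <- remove_blinks(rec)
  expect_gt(attr(clean, "blink_cor"), 0.5)
  for (ch in colnames(clean$samples)) {
    expect_lt(abs(cor(clean$samples[, ch], blink)), 0.2)
  }
  # non-blink channels barely touched
  expect_gt(cor(clean$samples[, "Fz"], rec$samples[, "Fz"]), 0.9)

  # blink-free input returns nearly unchanged (below the correlation floor)
  rec2 <- make_rec(withr::with_seed(78, replicate(4, rnorm(n), simplify = FALSE)), fs)
  clean2 <- remove_blinks(rec2)
  expect_true(is.na(attr(clean2, "blink_cor")) ||
                all(vapply(colnames(clean2$samples), function(ch) {
                  cor(clean2$samples[, ch], rec2$samples[, ch]) >= 0.95
                }, logical(1))))

  # determinism
  expect_identical(remove_blinks(rec)$samples, clean$samples)
})

test_that("epoch extraction windows are exact, half-open, edge-safe", {
  fs <- 200
  n <- fs * 40
  ev <- data.frame(onset_s = c(0.5, seq(4, 36, by = 4)),
                   label = rep(c("rare", "frequent"), c(5, 5)))
  rec <- make_rec(withr::with_seed(1, replicate(4, rnorm(n), simplify = FALSE)),
                  fs, ev)
  expect_warning(ep <- extract_epochs(rec), "skipped")  # 0.5 s event lost
  expect_equal(length(ep$labels), 9)
  expect_equal(dim(ep$data), c(9, 4, 600))
  # stimulus onset maps to 0-based sample index fs * t_pre = 200
  on_idx <- round(fs * ep$t_pre)
  i_sample <- round((ev$onset_s[2] - 1) * fs) + 1 + on_idx
  expect_equal(ep$data[1, 1, on_idx + 1], unname(rec$samples[i_sample, 1]))

  # translation equivariance: shift samples and events by 2 s (the
  # previously edge-clipped 0.5 s event becomes valid and leads the array)
  shift <- 2 * fs
  rec2 <- recording(rbind(matrix(0, shift, 4,
                                 dimnames = list(NULL, colnames(rec$samples))),
                          rec$samples),
                    fs, transform(ev, onset_s = onset_s + 2))
  ep2 <- extract_epochs(rec2)
  expect_equal(dim(ep2$data)[1], 10)
  expect_equal(ep2$data[-1, , , drop = FALSE], ep$data)

  expect_error(extract_epochs(make_rec(list(rnorm(n)), fs)), "no events")
})

test_that("peak-to-average rejection flags spikes and spares noise", {
  fs <- 200
  ev <- data.frame(onset_s = seq(2, 58, by = 4), label = "frequent")
  n <- fs * 60
  rec <- make_rec(withr::with_seed(3, replicate(4, rnorm(n), simplify = FALSE)),
                  fs, ev)
  ep <- extract_epochs(rec)
  # inject a 20x-RMS spike into epoch 3
  ep$data[3, 2, 300] <- 20 * sqrt(mean(ep$data[3, 2, ]^2))
  out <- reject_artifacts(ep, par_threshold = 8)
  expect_false(out$kept[3])
  expect_gte(mean(out$kept[-3]), 0.99)
  expect_true(all(reject_artifacts(ep, par_threshold = 1e9)$kept))
  ep_bad <- ep
  ep_bad$data[] <- 0
  ep_bad$data[, , 1] <- 100
  expect_error(reject_artifacts(ep_bad, 8), "all epochs rejected")
})

test_that("condition selection restricts kept flags and validates labels", {
  sch <- generate_schedule(120, 0.25, 10, seed = 2)
  prof <- subject_profile("healthy", blink_rate = 0)
  # cheap epochs: reuse schedule labels on noise epochs
  data <- withr::with_seed(4, array(rnorm(120 * 4 * 600), c(120, 4, 600)))
  ep <- structure(list(data = data, fs = 200, t_pre = 1, t_post = 2,
                       channel_names = c("Fz", "Cz", "Pz", "Fp1"),
                       labels = sch$labels, kept = rep(TRUE, 120)),
                  class = "olf_epochs")
  expect_equal(sum(select_condition(ep, "frequent")$kept), 90)
  expect_equal(sum(select_condition(ep, "rare")$kept), 30)
  expect_error(select_condition(ep, "novel"), "not present")
  ep$kept[sch$labels == "rare"] <- FALSE
  expect_error(select_condition(ep, "rare"), "remain")
})

test_that("preprocessing does not mutate its inputs", {
  fs <- 200
  ev <- data.frame(onset_s = c(4, 8), label = "frequent")
  rec <- make_rec(withr::with_seed(9, replicate(4, rnorm(fs * 12), simplify = FALSE)),
                  fs, ev)
  snap <- rec$samples + 0
  invisible(bandlimit(rec))
  invisible(extract_epochs(rec))
  expect_identical(rec$samples, snap)
})
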