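#' Construct a multichannel EEG recording object
#'
#' @param samples Numeric matrix, time x channels (microvolts), with column
#'   names giving the channel labels.
#' @param fs Sampling rate in Hz.
#' @param events A data.frame with columns `onset_s` (seconds from recording
#'   start) and `label`.
#' @return An object of class `olf_recording`.
#' @export
recording <- function(samples, fs, events = NULL) {
  stopifnot(is.matrix(samples), fs > 0, !is.null(colnames(samples)))
  if (is.null(events)) {
    events <- data.frame(onset_s = numeric(0), label = character(0))
  }
  stopifnot(all(c("onset_s", "label") %in% names(events)))
  dur <- nrow(samples) / fs
  if (nrow(events) && any(events$onset_s < 0 | events$onset_s > dur)) {
    stop("event onsets must lie within the recording duration")
  }
  structure(list(samples = samples, fs = fs, events = events),
            class = "olf_recording")
}

#' @export
print.olf_recording <- function(x, ...) {
  cat(sprintf("<olf_recording> %d ch x %.1f s @ %g Hz, %d events [%s]\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs, nrow(x$events),
              paste(colnames(x$samples), collapse = " ")))
  invisible(x)
}

# duration in seconds
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

# constant phase shift of all frequency components by phi radians
# (frequency-domain rotation; unlike a time delay, the phase offset is the
# same at every frequency, which keeps the mixing-model ImCoh flat in band)
phase_shift <- function(x, phi) {
  n <- length(x)
  k <- 0:(n - 1)
  sgn <- ifelse(k == 0, 0, ifelse(k < n / 2, 1, ifelse(k == n / 2 & n %% 2 == 0, 0, -1)))
  Re(fft(fft(x) * exp(-1i * phi * sgn), inverse = TRUE)) / n
}

# band-limited Gaussian noise of a target variance; pad-and-trim avoids
# filter edge transients. All signals of one band share this filter, so
# their spectral shapes cancel in coherence ratios.
band_noise <- function(n, fs, low, high, power) {
  if (power <= 0) return(numeric(n))
  pad <- round(2 * fs)
  z <- bp_filtfilt(rnorm(n + 2 * pad), fs, low, high)[(pad + 1):(pad + n)]
  z * sqrt(power / var(z))
}

# stereotyped biphasic eye-blink transient (300 ms, unit peak)
blink_template <- function(fs, duration = 0.3) {
  t <- seq(0, duration, by = 1 / fs)
  sin(2 * pi * t / duration) * sin(pi * t / duration)^2
}

#' Generate a synthetic EEG recording for one subject
#'
#' Simulates the four-channel (Fz, Cz, Pz, Fp1) olfactory-task recording for
#' a subject profile and stimulus schedule. Each channel is a sum of five
#' band-limited components; for every (pair, band) entry in the profile's
#' coupling table the two paired channels share a band-limited source `s`
#' (the second channel receiving `a * s` phase-shifted by `phi` plus
#' independent noise), so the population imaginary coherence of that pair
#' and band equals [expected_imcoh()] with the profile's parameters. Eye
#' blinks are injected as stereotyped 300 ms biphasic transients on all
#' channels with a five-fold gain on Fp1.
#'
#' The task is embedded after `lead_in` seconds of baseline so that the
#' first trial's pre-stimulus window is available to epoching; event onsets
#' in the returned recording equal `lead_in + schedule onset`.
#'
#' @param profile An [subject_profile()].
#' @param schedule An [generate_schedule()] schedule.
#' @param fs Sampling rate in Hz; must be at least twice the highest band
#'   edge (81 Hz).
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param lead_in Baseline seconds prepended before the first trial.
#' @param blink_amp Blink peak amplitude on Fp1 in microvolts.
#' @return An [recording()] with channels Fz, Cz, Pz, Fp1 and one event per
#'   trial.
#' @export
generate_recording <- function(profile, schedule, fs = 200, seed = 1,
                               lead_in = 2, blink_amp = 150) {
  stopifnot(inherits(profile, "olf_profile"), inherits(schedule, "olf_schedule"))
  bands <- olf_bands()
  if (fs < 2 * max(bands$high)) {
    stop("fs = ", fs, " Hz is below the Nyquist rate for the requested bands")
  }
  dur <- lead_in + schedule$n_trials * schedule$trial_period
  n <- round(dur * fs)
  pw <- olf_band_power()

  withr::with_seed(seed, {
    x <- matrix(0, n, length(OLF_CHANNELS), dimnames = list(NULL, OLF_CHANNELS))
    for (bi in seq_len(nrow(bands))) {
      b <- bands$band[bi]
      lo <- bands$low[bi]
      hi <- bands$high[bi]
      cpl <- profile$coupling
      cpl <- if (is.null(cpl)) NULL else cpl[cpl$band == b, , drop = FALSE]
      coupled_ch <- character(0)
      if (!is.null(cpl) && nrow(cpl)) {
        for (ri in seq_len(nrow(cpl))) {
          ch <- strsplit(cpl$pair[ri], "-", fixed = TRUE)[[1]]
          s <- band_noise(n, fs, lo, hi, cpl$ps[ri])
          x[, ch[1]] <- x[, ch[1]] + s + band_noise(n, fs, lo, hi, cpl$n1[ri])
          x[, ch[2]] <- x[, ch[2]] + cpl$a[ri] * phase_shift(s, cpl$phi[ri]) +
            band_noise(n, fs, lo, hi, cpl$n2[ri])
          coupled_ch <- c(coupled_ch, ch)
        }
      }
      for (ch in setdiff(OLF_CHANNELS, coupled_ch)) {
        x[, ch] <- x[, ch] + band_noise(n, fs, lo, hi, pw[[b]])
      }
    }

    if (profile$blink_rate > 0) {
      n_blinks <- rpois(1, profile$blink_rate * dur / 60)
      if (n_blinks > 0) {
        tpl <- blink_template(fs)
        gain <- setNames(rep(0.2, 4), OLF_CHANNELS)
        gain["Fp1"] <- 1
        starts <- sort(round(runif(n_blinks, 0, n - length(tpl))))
        for (s0 in starts) {
          idx <- s0 + seq_along(tpl)
          x[idx, ] <- x[idx, ] + blink_amp * tpl %o% gain
        }
      }
    }
    x
  }) -> samples

  events <- data.frame(onset_s = lead_in + schedule$onsets,
                       label = schedule$labels,
                       stringsAsFactors = FALSE)
  recording(samples, fs, events)
}

#' Generate smell-test item responses for one subject
#'
#' Independent Bernoulli draws with the profile's per-item correct-answer
#' probabilities. The total score is the number of correct identifications.
#'
#' @param profile An [subject_profile()].
#' @param n_items Number of items (24 for the smell-identification kit).
#' @param seed Integer seed.
#' @return Integer vector of 0/1 responses of length `n_items`.
#' @export
generate_item_responses <- function(profile, n_items = 24, seed = 1) {
  stopifnot(length(profile$item_probs) == n_items)
  withr::with_seed(seed, rbinom(n_items, 1, profile$item_probs))
}
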