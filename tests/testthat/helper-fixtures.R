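# shared fixtures and independent oracles, built in code at test time

# band-limited noise with an exact target variance (same filter family as
# the generator, used to synthesize mixing-model channels)
h_band_noise <- function(n, fs, low, high, power, pad = 2 * fs) {
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  z <- signal::filtfilt(lp, signal::filtfilt(hp, rnorm(n + 2 * pad)))
  z <- z[(pad + 1):(pad + n)]
  z * sqrt(power / var(z))
}

# constant phase rotation of all frequency components
h_phase_shift <- function(x, phi) {
  n <- length(x)
  k <- 0:(n - 1)
  sgn <- ifelse(k == 0, 0, ifelse(k < n / 2, 1, ifelse(k == n / 2 & n %% 2 == 0, 0, -1)))
  Re(fft(fft(x) * exp(-1i * phi * sgn), inverse = TRUE)) / n
}

# one mixing-model channel pair: x = s + n1, y = a * s_phi + n2
h_mixing_pair <- function(n, fs, low, high, a = 1, phi = pi / 4,
                          ps = 1, n1 = 1, n2 = 1) {
  s <- h_band_noise(n, fs, low, high, ps)
  list(x = s + h_band_noise(n, fs, low, high, n1),
       y = a * h_phase_shift(s, phi) + h_band_noise(n, fs, low, high, n2))
}

# wrap a list of 2-channel epochs (x, y) into an olf_epochs object using
# the Fz / Cz channel slots
h_pair_epochs <- function(pairs_list, fs) {
  n_ep <- length(pairs_list)
  n_samp <- length(pairs_list[[1]]$x)
  data <- array(0, c(n_ep, 4, n_samp))
  for (i in seq_len(n_ep)) {
    data[i, 1, ] <- pairs_list[[i]]$x
    data[i, 2, ] <- pairs_list[[i]]$y
    data[i, 3, ] <- rnorm(n_samp)
    data[i, 4, ] <- rnorm(n_samp)
  }
  structure(list(data = data, fs = fs, t_pre = 1, t_post = n_samp / fs - 1,
                 channel_names = c("Fz", "Cz", "Pz", "Fp1"),
                 labels = rep("frequent", n_ep), kept = rep(TRUE, n_ep)),
            class = "olf_epochs")
}

# --- independent oracles ------------------------------------------------

# brute-force Welch CSD by explicit DFT sums (no fft), one-sided grid
h_direct_csd <- function(x, y, fs, seg_len = 1, overlap = 0.5) {
  nseg <- round(seg_len * fs)
  hop <- round(nseg * (1 - overlap))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))  # Hamming
  U <- sum(w^2)
  nf <- floor(nseg / 2) + 1
  Pxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  Pxx <- Pyy <- numeric(nf)
  for (s in starts) {
    xs <- x[s:(s + nseg - 1)]; xs <- (xs - mean(xs)) * w
    ys <- y[s:(s + nseg - 1)]; ys <- (ys - mean(ys)) * w
    for (k in seq_len(nf)) {
      e <- exp(-2i * pi * (k - 1) * (0:(nseg - 1)) / nseg)
      Fx <- sum(xs * e)
      Fy <- sum(ys * e)
      Pxy[k] <- Pxy[k] + Fx * Conj(Fy)
      Pxx[k] <- Pxx[k] + Mod(Fx)^2
      Pyy[k] <- Pyy[k] + Mod(Fy)^2
    }
  }
  L <- length(starts)
  list(freqs = (seq_len(nf) - 1) / seg_len,
       Pxy = Pxy / (L * U), Pxx = Pxx / (L * U), Pyy = Pyy / (L * U))
}

# brute-force Benjamini-Hochberg by its definition
h_bh_oracle <- function(p, q = 0.05, m = length(p)) {
  o <- order(p)
  ks <- which(p[o] <= seq_along(p) * q / m)
  sig <- logical(length(p))
  if (length(ks)) sig[o[seq_len(max(ks))]] <- TRUE
  sig
}

# exact permutation p-value for a two-sample mean difference (t statistic)
h_perm_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  tstat <- function(u, v) {
    (mean(u) - mean(v)) / sqrt(var(u) / length(u) + var(v) / length(v))
  }
  t_obs <- abs(tstat(a, b))
  t_all <- apply(idx, 2, function(ii) abs(tstat(pool[ii], pool[-ii])))
  mean(t_all >= t_obs - 1e-12)
}

# small ready-made cohort sim (no recordings) for behavioral/stats tests
h_small_cohort <- function(seed = 11, effects = "study") {
  generate_cohort(cohort_config(seed = seed, effects = effects),
                  recordings = FALSE)
}

# reduced-size recording config: 40-trial, 4 s-period task at 200 Hz
h_small_rec_config <- function(seed, effects = "recovery") {
  cohort_config(seed = seed, effects = effects,
                n_trials = 40, trial_period = 4)
}
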