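# windowed segment FFTs of one signal: matrix n_freq x n_segments
# (mean removed per segment; Hamming taper; one-sided frequency grid)
segment_ffts <- function(x, fs, seg_len = 1.0, overlap = 0.5) {
  nseg <- round(seg_len * fs)
  if (nseg > length(x)) stop("segment (", nseg, " samples) longer than the signal")
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  w <- signal::hamming(nseg)
  nf <- floor(nseg / 2) + 1
  segs <- vapply(starts, function(s) {
    v <- x[s:(s + nseg - 1)]
    (v - mean(v)) * w
  }, numeric(nseg))
  F <- stats::mvfft(segs)[seq_len(nf), , drop = FALSE]
  list(F = F, freqs = (seq_len(nf) - 1) / seg_len, U = sum(w^2))
}

#' Welch cross-spectral density of two signals
#'
#' Segment-averaged cross- and auto-power spectral densities: the signals
#' are split into `seg_len`-second segments with fractional `overlap`,
#' mean-removed, Hamming-tapered, Fourier-transformed, and the per-segment
#' periodograms averaged. The frequency grid spacing is `1/seg_len` Hz (1 Hz
#' for the study's one-second segments). Normalisation is such that the
#' average of `Pxx` over the grid approximates the signal's total power.
#'
#' @param x,y Equal-length numeric signals (use `y = x` for an
#'   auto-spectrum; `Pxy` is then real and equals `Pxx`).
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in seconds.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return An object of class `olf_csd`: a list with `freqs` (Hz), complex
#'   `Pxy`, real `Pxx`, `Pyy`, and `n_segments`.
#' @export
#' @examples
#' x <- rnorm(600)
#' cs <- welch_csd(x, x, fs = 200)   # 5 segments of a 3 s epoch
#' all(abs(Im(cs$Pxy)) < 1e-12)
welch_csd <- function(x, y, fs, seg_len = 1.0, overlap = 0.5) {
  stopifnot(length(x) == length(y), fs > 0, overlap >= 0, overlap < 1)
  fx <- segment_ffts(x, fs, seg_len, overlap)
  fy <- if (identical(x, y)) fx else segment_ffts(y, fs, seg_len, overlap)
  L <- ncol(fx$F)
  structure(
    list(freqs = fx$freqs,
         Pxy = rowMeans(fx$F * Conj(fy$F)) / fx$U,
         Pxx = rowMeans(Mod(fx$F)^2) / fx$U,
         Pyy = rowMeans(Mod(fy$F)^2) / fx$U,
         n_segments = L),
    class = "olf_csd"
  )
}

# sum two CSD objects bin-wise, weighting by segment counts (epoch pooling)
csd_pool <- function(a, b) {
  if (is.null(a)) return(b)
  wa <- a$n_segments
  wb <- b$n_segments
  structure(
    list(freqs = a$freqs,
         Pxy = (wa * a$Pxy + wb * b$Pxy) / (wa + wb),
         Pxx = (wa * a$Pxx + wb * b$Pxx) / (wa + wb),
         Pyy = (wa * a$Pyy + wb * b$Pyy) / (wa + wb),
         n_segments = wa + wb),
    class = "olf_csd"
  )
}

#' Imaginary-coherence spectrum from a cross-spectral density
#'
#' The default (squared) form is `Im(Pxy)^2 / (Pxx * Pyy)`, bounded in
#' `[0, 1]`; it ignores the real part of the cross-spectrum and is
#' therefore insensitive to zero-lag (volume-conducted) coupling. With
#' `squared = FALSE` the signed imaginary coherency
#' `Im(Pxy / sqrt(Pxx * Pyy))` is returned instead.
#'
#' Frequency bins with zero auto-power on either channel are undefined and
#' returned as `NA` with a warning.
#'
#' @param cs An `olf_csd` from [welch_csd()].
#' @param squared Use the squared form (default) or the signed coherency.
#' @return Numeric vector over `cs$freqs`.
#' @export
imcoh_spectrum <- function(cs, squared = TRUE) {
  stopifnot(inherits(cs, "olf_csd"))
  den <- cs$Pxx * cs$Pyy
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " frequency bin(s) with zero auto-power masked as NA")
    den[bad] <- NA_real_
  }
  if (squared) Im(cs$Pxy)^2 / den else Im(cs$Pxy / sqrt(den))
}

# frequency-bin selector for a closed band interval
band_bins <- function(freqs, low, high) {
  sel <- freqs >= low & freqs <= high
  if (!any(sel)) stop("band [", low, ", ", high, "] Hz contains no grid bins")
  sel
}

#' Band-averaged imaginary coherence of one electrode pair
#'
#' The coherence stage of the pipeline for a single pair and band: both
#' channels are band-pass filtered (4th-order Butterworth, zero-phase) to
#' isolate the target band, the Welch cross-spectrum is computed per epoch,
#' the imaginary-coherence spectrum is formed, and its values are averaged
#' over the frequency bins inside the band.
#'
#' Two averaging orders are available. `average = "epoch"` computes one
#' ImCoh value per epoch and returns the per-epoch values (the study's
#' stated order; their mean is the subject's band value). `average = "csd"`
#' pools the cross-spectra over all kept epochs before forming ImCoh and
#' returns a single value; pooling over `n_epochs * n_segments` segments
#' makes the estimator's finite-segment bias negligible, which matters when
#' comparing against the analytic mixing-model value.
#'
#' @param epochs An `olf_epochs` object.
#' @param pair Electrode pair, e.g. `"Fz-Cz"`.
#' @param band Band name from [olf_bands()].
#' @param average `"epoch"` (per-epoch values) or `"csd"` (pooled).
#' @param seg_len,overlap Welch parameters, see [welch_csd()].
#' @param squared See [imcoh_spectrum()].
#' @return For `"epoch"`, a numeric vector with one value per kept epoch;
#'   for `"csd"`, a single number.
#' @export
band_filter_then_imcoh <- function(epochs, pair = "Fz-Cz", band = "beta",
                                   average = c("epoch", "csd"),
                                   seg_len = 1.0, overlap = 0.5,
                                   squared = TRUE) {
  average <- match.arg(average)
  stopifnot(inherits(epochs, "olf_epochs"))
  bands <- olf_bands()
  if (!band %in% bands$band) stop("unknown band: ", band)
  b <- bands[bands$band == band, ]
  ch <- strsplit(pair, "-", fixed = TRUE)[[1]]
  idx <- match(ch, epochs$channel_names)
  if (anyNA(idx)) stop("pair channels not present: ", pair)
  keep <- which(epochs$kept)
  if (!length(keep)) stop("no kept epochs")
  per_epoch <- numeric(length(keep))
  pooled <- NULL
  for (j in seq_along(keep)) {
    e <- keep[j]
    x <- bp_filtfilt(epochs$data[e, idx[1], ], epochs$fs, b$low, b$high)
    y <- bp_filtfilt(epochs$data[e, idx[2], ], epochs$fs, b$low, b$high)
    cs <- welch_csd(x, y, epochs$fs, seg_len, overlap)
    if (average == "epoch") {
      sel <- band_bins(cs$freqs, b$low, b$high)
      per_epoch[j] <- mean(imcoh_spectrum(cs, squared)[sel])
    } else {
      pooled <- csd_pool(pooled, cs)
    }
  }
  if (average == "epoch") {
    per_epoch
  } else {
    sel <- band_bins(pooled$freqs, b$low, b$high)
    mean(imcoh_spectrum(pooled, squared)[sel])
  }
}

#' The 30-value ImCoh feature set of one subject
#'
#' Band-averaged imaginary coherence for every electrode pair (Fp1-Fz,
#' Fp1-Cz, Fp1-Pz, Fz-Cz, Fz-Pz, Cz-Pz) and every oscillatory band (delta,
#' theta, alpha, beta, gamma): 6 x 5 = 30 values per subject, each the
#' average over kept epochs (or the epoch-pooled estimate, see
#' [band_filter_then_imcoh()]).
#'
#' @param epochs An `olf_epochs` object with at least one kept epoch.
#' @param pairs,bands Subsets of pairs/bands to compute (defaults: all 6
#'   pairs, all 5 bands). Restricting them speeds up simulations that only
#'   need the classifier's Fz-Cz beta/gamma features.
#' @param average,seg_len,overlap,squared See [band_filter_then_imcoh()].
#' @return A named numeric vector, names `<pair>_<band>`; length 30 for the
#'   full feature set.
#' @export
subject_features <- function(epochs, pairs = OLF_PAIRS,
                             bands = olf_bands()$band,
                             average = c("epoch", "csd"),
                             seg_len = 1.0, overlap = 0.5, squared = TRUE) {
  average <- match.arg(average)
  stopifnot(inherits(epochs, "olf_epochs"))
  if (!any(epochs$kept)) stop("no kept epochs: cannot compute subject features")
  band_tab <- olf_bands()
  keep <- which(epochs$kept)
  out <- numeric(0)
  for (band in bands) {
    b <- band_tab[band_tab$band == band, ]
    # filter each channel once per (band, epoch), reuse FFTs across pairs
    used_ch <- unique(unlist(strsplit(pairs, "-", fixed = TRUE)))
    idx <- match(used_ch, epochs$channel_names)
    if (anyNA(idx)) stop("channels missing: ", paste(used_ch[is.na(idx)], collapse = ", "))
    acc <- setNames(vector("list", length(pairs)), pairs)  # pooled CSDs or sums
    n_ep <- 0L
    for (e in keep) {
      ffts <- setNames(vector("list", length(used_ch)), used_ch)
      for (ci in seq_along(used_ch)) {
        xf <- bp_filtfilt(epochs$data[e, idx[ci], ], epochs$fs, b$low, b$high)
        ffts[[used_ch[ci]]] <- segment_ffts(xf, epochs$fs, seg_len, overlap)
      }
      n_ep <- n_ep + 1L
      for (pr in pairs) {
        ch <- strsplit(pr, "-", fixed = TRUE)[[1]]
        fx <- ffts[[ch[1]]]
        fy <- ffts[[ch[2]]]
        cs <- structure(
          list(freqs = fx$freqs,
               Pxy = rowMeans(fx$F * Conj(fy$F)) / fx$U,
               Pxx = rowMeans(Mod(fx$F)^2) / fx$U,
               Pyy = rowMeans(Mod(fy$F)^2) / fx$U,
               n_segments = ncol(fx$F)),
          class = "olf_csd")
        if (average == "csd") {
          acc[[pr]] <- csd_pool(acc[[pr]], cs)
        } else {
          sel <- band_bins(cs$freqs, b$low, b$high)
          v <- mean(imcoh_spectrum(cs, squared)[sel])
          acc[[pr]] <- (acc[[pr]] %||% 0) + v
        }
      }
    }
    vals <- vapply(pairs, function(pr) {
      if (average == "csd") {
        sel <- band_bins(acc[[pr]]$freqs, b$low, b$high)
        mean(imcoh_spectrum(acc[[pr]], squared)[sel])
      } else {
        acc[[pr]] / n_ep
      }
    }, numeric(1))
    out <- c(out, setNames(vals, paste0(pairs, "_", band)))
  }
  # pair-major order to match the canonical feature layout
  want <- as.vector(t(outer(pairs, bands, paste, sep = "_")))
  out[want]
}
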