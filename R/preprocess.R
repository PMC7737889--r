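#' Zero-phase band limiting of a recording
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, so event latencies are preserved) to every channel. The
#' study setting is 0.5--40.5 Hz, which also removes DC offsets and
#' power-line components.
#'
#' @param rec An [recording()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order per pass.
#' @return A new band-limited [recording()].
#' @export
bandlimit <- function(rec, low = 0.5, high = 40.5, order = 4) {
  stopifnot(inherits(rec, "olf_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("invalid band edges: need 0 < low < high < fs/2, got [",
         low, ", ", high, "] at fs = ", rec$fs)
  }
  out <- apply(rec$samples, 2, function(ch) bp_filtfilt(ch, rec$fs, low, high, order))
  colnames(out) <- colnames(rec$samples)
  recording(out, rec$fs, rec$events)
}

#' Downsample a recording
#'
#' Integer-factor decimation with anti-alias filtering
#' ([signal::decimate()], 8th-order Chebyshev low-pass). Event onsets are
#' in seconds and are unchanged. The study decimates 2000 Hz acquisitions
#' to the 200 Hz analysis rate. Upsampling and non-integer ratios are not
#' supported.
#'
#' @param rec An [recording()].
#' @param target_fs Target sampling rate in Hz, a divisor of `rec$fs`.
#' @return A new [recording()] at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "olf_recording"))
  if (target_fs > rec$fs) stop("upsampling is not supported (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop("fs/target_fs must be an integer decimation factor, got ", q)
  }
  out <- apply(rec$samples, 2, function(ch) signal::decimate(ch, round(q)))
  colnames(out) <- colnames(rec$samples)
  recording(out, target_fs, rec$events)
}

# symmetric fixed-point ICA (tanh contrast) on whitened data; the identity
# initialisation makes the decomposition fully deterministic. EEG band
# components are near-Gaussian, so the rotation within their subspace is
# not identifiable and the iteration need not be driven to machine
# precision -- only the non-Gaussian (blink) component matters, and it
# stabilises within a few iterations. The unmixing matrix is estimated on
# a deterministic stride subsample for speed and applied to all samples.
fastica_decompose <- function(X, max_iter = 100, tol = 1e-5) {
  n <- nrow(X)
  p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(crossprod(Xc) / n, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) {
    stop("ICA decomposition failed: rank-deficient channel covariance ",
         "(eigenvalues ", paste(signif(eg$values, 3), collapse = ", "), ")")
  }
  K <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- Xc %*% K
  stride <- max(1L, floor(n / 60000))
  Zf <- Z[seq(1, n, by = stride), , drop = FALSE]
  nf <- nrow(Zf)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    solve_sqrt %*% W
  }
  W <- diag(p)
  for (it in seq_len(max_iter)) {
    G <- tanh(Zf %*% t(W))
    W1 <- t(G) %*% Zf / nf - diag(colMeans(1 - G^2)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- Z %*% t(W)                       # component time courses (n x p)
  list(S = S, mixing = W %*% solve(K),  # Xc = S %*% mixing (W orthogonal)
       mu = mu)
}

#' Remove the eye-blink component by ICA
#'
#' Decomposes all channels with a deterministic fixed-point ICA, identifies
#' the single component whose time course has the largest absolute
#' correlation with the Fp1 channel (the peri-orbital electrode that picks
#' up blinks most strongly), zeroes it, and projects the remaining
#' components back to the electrodes. Removal only happens when the
#' candidate component is actually blink-like: it must reach the
#' `floor_cor` correlation with Fp1 *and* be clearly super-Gaussian
#' (excess kurtosis above `kurt_min`), the signature of sparse transients.
#' On blink-free data some component always aligns with Fp1 by chance, but
#' its near-Gaussian kurtosis fails the gate and the recording is returned
#' unchanged.
#'
#' @param rec An [recording()] containing an Fp1 channel.
#' @param floor_cor Minimum |correlation| with Fp1 for a component to be
#'   considered the blink component.
#' @param kurt_min Minimum excess kurtosis of the candidate component.
#' @return A new [recording()]; attribute `blink_cor` carries the selected
#'   component's correlation with Fp1 (`NA` if none removed).
#' @export
remove_blinks <- function(rec, floor_cor = 0.5, kurt_min = 1) {
  stopifnot(inherits(rec, "olf_recording"))
  if (!"Fp1" %in% colnames(rec$samples)) stop("Fp1 channel is required for blink removal")
  if (ncol(rec$samples) < 4) stop("blink removal expects the full 4-channel montage")
  dec <- fastica_decompose(rec$samples)
  cors <- abs(cor(dec$S, rec$samples[, "Fp1"]))
  k <- which.max(cors)
  exkurt <- mean(scale(dec$S[, k])^4) - 3
  if (cors[k] < floor_cor || exkurt < kurt_min) {
    out <- rec
    attr(out, "blink_cor") <- NA_real_
    return(out)
  }
  S <- dec$S
  S[, k] <- 0
  clean <- S %*% dec$mixing
  clean <- sweep(clean, 2, dec$mu, `+`)
  colnames(clean) <- colnames(rec$samples)
  out <- recording(clean, rec$fs, rec$events)
  attr(out, "blink_cor") <- as.numeric(cors[k])
  out
}

#' Extract stimulus-locked epochs
#'
#' Cuts one fixed-length epoch per event, spanning the half-open window
#' `[onset - t_pre, onset + t_post)`. At the 200 Hz analysis rate with 1 s
#' pre- and 2 s post-stimulus data each epoch has exactly 600 samples and
#' the stimulus onset falls on 0-based sample index `fs * t_pre` = 200.
#' Events whose window does not fit inside the recording are skipped with a
#' warning.
#'
#' @param rec An [recording()] (already at the analysis rate).
#' @param t_pre,t_post Pre-/post-stimulus window in seconds.
#' @return An object of class `olf_epochs`: a list with `data` (array
#'   `n_epochs x n_channels x n_samples`), `fs`, `t_pre`, `t_post`,
#'   `channel_names`, `labels`, and the logical `kept` flags (all `TRUE`
#'   initially).
#' @export
extract_epochs <- function(rec, t_pre = 1.0, t_post = 2.0) {
  stopifnot(inherits(rec, "olf_recording"))
  if (!nrow(rec$events)) stop("recording has no events to epoch")
  n_samp <- round(rec$fs * (t_pre + t_post))
  starts <- round((rec$events$onset_s - t_pre) * rec$fs) + 1
  ok <- starts >= 1 & (starts + n_samp - 1) <= nrow(rec$samples)
  if (!all(ok)) {
    warning(sum(!ok), " event(s) too close to a recording edge were skipped")
  }
  if (!any(ok)) stop("no event window fits inside the recording")
  starts <- starts[ok]
  nch <- ncol(rec$samples)
  data <- array(NA_real_, c(length(starts), nch, n_samp))
  for (i in seq_along(starts)) {
    data[i, , ] <- t(rec$samples[starts[i]:(starts[i] + n_samp - 1), ])
  }
  structure(
    list(data = data, fs = rec$fs, t_pre = t_pre, t_post = t_post,
         channel_names = colnames(rec$samples),
         labels = rec$events$label[ok],
         kept = rep(TRUE, length(starts))),
    class = "olf_epochs"
  )
}

#' @export
print.olf_epochs <- function(x, ...) {
  cat(sprintf("<olf_epochs> %d epochs (%d kept) x %d ch x %d samples @ %g Hz\n",
              length(x$labels), sum(x$kept), dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

#' Reject artifact-contaminated epochs by peak-to-average ratio
#'
#' For every epoch and channel the peak-to-average ratio max|x| / RMS(x) is
#' computed; an epoch is rejected when any channel exceeds `par_threshold`.
#' Data are retained, only the `kept` flags change. A Gaussian-noise epoch
#' of 600 samples stays below a threshold of 8 with overwhelming
#' probability, while spike and movement artifacts exceed it.
#'
#' @param epochs An `olf_epochs` object.
#' @param par_threshold Rejection threshold (> 1).
#' @return The epoch set with updated `kept` flags; attribute `par` holds
#'   the per-epoch worst-channel ratios.
#' @export
reject_artifacts <- function(epochs, par_threshold = 8) {
  stopifnot(inherits(epochs, "olf_epochs"), par_threshold > 1)
  par_epoch <- apply(epochs$data, 1, function(ep) {
    max(apply(ep, 1, function(ch) max(abs(ch)) / sqrt(mean(ch^2))))
  })
  bad <- par_epoch > par_threshold
  out <- epochs
  out$kept <- epochs$kept & !bad
  if (!any(out$kept)) {
    stop("all epochs rejected at peak-to-average threshold ", par_threshold,
         "; review the threshold or the data")
  }
  attr(out, "par") <- par_epoch
  out
}

#' Restrict epochs to one stimulus condition
#'
#' Keeps only epochs of the requested condition (the coherence analysis
#' uses the frequent, standard-odor trials). Flags are combined with prior
#' rejections.
#'
#' @param epochs An `olf_epochs` object.
#' @param label Condition label, `"frequent"` or `"rare"`.
#' @return The epoch set with updated `kept` flags.
#' @export
select_condition <- function(epochs, label = "frequent") {
  stopifnot(inherits(epochs, "olf_epochs"))
  if (!label %in% epochs$labels) stop("condition '", label, "' not present in epochs")
  out <- epochs
  out$kept <- epochs$kept & (epochs$labels == label)
  if (!any(out$kept)) stop("no epochs of condition '", label, "' remain after rejection")
  out
}

#' Full preprocessing chain for one recording
#'
#' Runs the pipeline stages in their canonical order: band limiting,
#' decimation to the analysis rate, ICA blink removal, epoch extraction,
#' peak-to-average artifact rejection, and condition selection.
#'
#' @param rec An [recording()].
#' @param low,high Band-limit edges in Hz.
#' @param target_fs Analysis sampling rate in Hz.
#' @param t_pre,t_post Epoch window in seconds.
#' @param par_threshold Artifact-rejection threshold.
#' @param condition Condition to retain.
#' @return An `olf_epochs` object restricted to the requested condition.
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 40.5, target_fs = 200,
                                 t_pre = 1.0, t_post = 2.0,
                                 par_threshold = 8, condition = "frequent") {
  rec |>
    bandlimit(low, high) |>
    resample_recording(target_fs) |>
    remove_blinks() |>
    extract_epochs(t_pre, t_post) |>
    reject_artifacts(par_threshold) |>
    select_condition(condition)
}
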