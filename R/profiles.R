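#' Analytic imaginary coherence of the linear mixing model
#'
#' Closed form of the (squared) imaginary part of coherence for the
#' two-channel mixing model `x = s + n1`, `y = a * s_phi + n2`, where `s` is
#' a shared band-limited source of power `ps`, `s_phi` is `s` phase-shifted
#' by `phi` radians, and `n1`, `n2` are independent noises of powers `n1`,
#' `n2` with the same spectral shape as `s`. Under this model the imaginary
#' coherence is flat across the band and equals
#' \deqn{\frac{a^2 \sin^2(\phi)\, P_s^2}{(P_s + N_1)(a^2 P_s + N_2)}.}
#'
#' This is the oracle against which the spectral pipeline is validated: an
#' in-phase pair (`phi = 0`) has zero imaginary coherence regardless of
#' powers, a noiseless quadrature pair (`phi = pi/2`) reaches 1.
#'
#' @param a Source gain into the second channel.
#' @param phi Phase lag in radians, in `[-pi, pi]`.
#' @param ps Source power (variance).
#' @param n1,n2 Independent noise powers on the two channels.
#' @return The population squared imaginary coherence, in `[0, 1]`.
#' @export
#' @examples
#' expected_imcoh(1, pi / 4, 1, 1, 1) # 0.125
expected_imcoh <- function(a, phi, ps, n1, n2) {
  stopifnot(ps >= 0, n1 >= 0, n2 >= 0)
  d1 <- ps + n1
  d2 <- a^2 * ps + n2
  if (d1 <= 0 || d2 <= 0) stop("degenerate mixing model: zero total power on a channel")
  a^2 * sin(phi)^2 * ps^2 / (d1 * d2)
}

# nominal per-band channel power (uV^2); sums to ~230 uV^2 (~15 uV RMS),
# a realistic scalp EEG level with the usual 1/f-ish band profile
olf_band_power <- function() {
  c(delta = 80, theta = 50, alpha = 60, beta = 30, gamma = 10)
}

#' Construct a synthetic subject profile
#'
#' A subject profile parameterizes the generative model behind one subject's
#' EEG recording and smell-test responses: per-(pair, band) linear-mixing
#' coupling parameters, per-item correct-answer probabilities, and a blink
#' rate. Coupling for a (pair, band) not listed in `coupling` defaults to
#' uncoupled (independent band-limited noise on each channel).
#'
#' @param group `"healthy"` or `"AD"`.
#' @param age Age in years.
#' @param coupling A data.frame with columns `pair` (e.g. `"Fz-Cz"`),
#'   `band`, `a`, `phi`, `ps`, `n1`, `n2`. May be `NULL` (no coupling).
#' @param item_probs Numeric vector of 24 per-odor correct-answer
#'   probabilities in `[0, 1]`.
#' @param blink_rate Eye-blink rate in events per minute.
#' @return An object of class `olf_profile`.
#' @export
subject_profile <- function(group = c("healthy", "AD"), age = 70,
                            coupling = NULL,
                            item_probs = rep(0.5, 24),
                            blink_rate = 12) {
  group <- match.arg(group)
  stopifnot(all(item_probs >= 0 & item_probs <= 1), blink_rate >= 0)
  if (!is.null(coupling)) {
    stopifnot(is.data.frame(coupling),
              all(c("pair", "band", "a", "phi", "ps", "n1", "n2") %in% names(coupling)))
    stopifnot(all(coupling$ps >= 0), all(coupling$n1 >= 0), all(coupling$n2 >= 0),
              all(coupling$phi >= -pi & coupling$phi <= pi),
              all(coupling$pair %in% OLF_PAIRS),
              all(coupling$band %in% olf_bands()$band))
  }
  structure(
    list(group = group, age = age, coupling = coupling,
         item_probs = item_probs, blink_rate = blink_rate),
    class = "olf_profile"
  )
}

# coupling rows for one pair across a set of bands, with target population
# ImCoh tau: a = 1, phi = pi/3 and the source share r = sqrt(tau / sin^2(phi))
# of the band's nominal power, so expected_imcoh(...) == tau exactly.
coupling_for_tau <- function(tau, pair = "Fz-Cz", bands = c("beta", "gamma"),
                             phi = pi / 3) {
  stopifnot(length(tau) == length(bands))
  smax <- sin(phi)^2
  tau <- pmin(pmax(tau, 0), smax * 0.999)
  pw <- olf_band_power()[bands]
  r <- sqrt(tau / smax)
  data.frame(pair = pair, band = bands, a = 1, phi = phi,
             ps = r * pw, n1 = (1 - r) * pw, n2 = (1 - r) * pw,
             stringsAsFactors = FALSE)
}

#' Default per-odor correct-answer probabilities
#'
#' Baseline identification probabilities for the 24-item smell test,
#' anchored to the published cohort: the healthy profile mixes a few
#' near-ceiling odors (including the two AD-discriminative ones, items 6 and
#' 21), a majority of mid-range odors, and two floor odors that neither
#' group identifies (culturally unfamiliar scents), for an expected total of
#' about 15.2/24. The AD profile lowers the discriminative items to 0.3 and
#' the mid-range items to 0.3 (expected total about 8.6/24), matching the
#' reported group totals of 15.5 +/- 2.8 and 8.2 +/- 3.9.
#'
#' @param group `"healthy"` or `"AD"`.
#' @return Numeric vector of 24 probabilities.
#' @export
default_item_probs <- function(group = c("healthy", "AD")) {
  group <- match.arg(group)
  high <- c(1, 6, 9, 15, 19, 21)   # near-ceiling for healthy; 6/21 discriminative
  floor_items <- c(12, 23)         # unfamiliar odors, both groups near floor
  p <- rep(0.6, 24)
  p[high] <- 0.9
  p[floor_items] <- 0.1
  if (group == "AD") {
    p[p == 0.6] <- 0.3
    p[high] <- 0.75
    p[c(6, 21)] <- 0.3
  }
  p
}

#' Cohort configuration for the synthetic generator
#'
#' Bundles every knob of the cohort generator. Defaults reproduce the study
#' conditions: 13 healthy and 11 AD subjects, ages drawn around the reported
#' group means (healthy 68.2 +/- 6.2, AD 76.6 +/- 9.2 years), the default
#' item-probability profiles, an age-linear decline of smell performance on
#' the logit scale, a per-subject ability random effect, and Fz-Cz coupling
#' in the beta and gamma bands that is weaker in the AD group.
#'
#' `effects` selects a preset for the group effect structure:
#' \describe{
#'   \item{`"study"`}{defaults anchored to the published group totals.}
#'   \item{`"recovery"`}{effect cohort for pipeline-recovery simulations:
#'     the behavioral deficit is concentrated in the two discriminative
#'     items (0.95 vs 0.15) with a mild deficit elsewhere, so that the
#'     EEG and behavioral channels are individually informative and
#'     complementary.}
#'   \item{`"null"`}{zero group effects everywhere (identical item
#'     probabilities, identical coupling, matched age distributions); used
#'     for calibration tests.}
#' }
#'
#' @param n_healthy,n_ad Group sizes.
#' @param seed Integer master seed; all randomness derives from it.
#' @param effects Effect-structure preset, see Details.
#' @param age_mean,age_sd Named numeric vectors (`healthy`, `AD`) for the
#'   age distributions (years).
#' @param item_probs_healthy,item_probs_ad Per-odor probabilities (length 24).
#' @param subject_sigma SD of the per-subject ability random effect on the
#'   logit scale; 0.5 reproduces the published total-score SDs.
#' @param age_slope Logit-scale change of item probability per year of age
#'   (applied relative to age 70).
#' @param imcoh_mean,imcoh_sd Named (`healthy`, `AD`) mean / SD of the
#'   per-subject target Fz-Cz ImCoh in the coupled bands.
#' @param imcoh_rho Between-band (beta vs gamma) correlation of the
#'   per-subject ImCoh targets.
#' @param blink_rate Blinks per minute.
#' @param n_trials,p_rare,trial_period,stim_duration Oddball schedule
#'   parameters (defaults: 120 trials, 0.25, 10 s, 2 s).
#' @param fs Sampling rate of the generated recordings in Hz.
#' @return An object of class `olf_config` (a list).
#' @export
cohort_config <- function(n_healthy = 13, n_ad = 11, seed = 1,
                          effects = c("study", "recovery", "null"),
                          age_mean = c(healthy = 68.2, AD = 76.6),
                          age_sd = c(healthy = 6.2, AD = 9.2),
                          item_probs_healthy = default_item_probs("healthy"),
                          item_probs_ad = default_item_probs("AD"),
                          subject_sigma = 0.5,
                          age_slope = -0.03,
                          imcoh_mean = c(healthy = 0.28, AD = 0.12),
                          imcoh_sd = c(healthy = 0.07, AD = 0.07),
                          imcoh_rho = 0.5,
                          blink_rate = 12,
                          n_trials = 120, p_rare = 0.25,
                          trial_period = 10, stim_duration = 2,
                          fs = 200) {
  effects <- match.arg(effects)
  if (effects == "recovery") {
    p <- item_probs_healthy
    p[c(6, 21)] <- 0.95
    item_probs_healthy <- p
    pa <- p
    pa[c(6, 21)] <- 0.15
    pa[p == 0.6] <- 0.45
    pa[p == 0.9] <- 0.8
    item_probs_ad <- pa
  } else if (effects == "null") {
    item_probs_ad <- item_probs_healthy
    imcoh_mean["AD"] <- imcoh_mean["healthy"]
    imcoh_sd["AD"] <- imcoh_sd["healthy"]
    age_mean["AD"] <- age_mean["healthy"]
    age_sd["AD"] <- age_sd["healthy"]
  }
  stopifnot(n_healthy >= 1, n_ad >= 1,
            length(item_probs_healthy) == 24, length(item_probs_ad) == 24)
  structure(
    list(n_healthy = n_healthy, n_ad = n_ad, seed = as.integer(seed),
         effects = effects,
         age_mean = age_mean, age_sd = age_sd,
         item_probs_healthy = item_probs_healthy,
         item_probs_ad = item_probs_ad,
         subject_sigma = subject_sigma, age_slope = age_slope,
         imcoh_mean = imcoh_mean, imcoh_sd = imcoh_sd, imcoh_rho = imcoh_rho,
         blink_rate = blink_rate,
         n_trials = n_trials, p_rare = p_rare,
         trial_period = trial_period, stim_duration = stim_duration,
         fs = fs),
    class = "olf_config"
  )
}
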