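logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic cohort
#'
#' Draws a full cohort under an [cohort_config()]: per-subject ages, smell
#' test item responses (group profile + per-subject ability random effect +
#' age-linear decline, all on the logit scale), Fz-Cz beta/gamma coupling
#' targets (weaker in the AD group), and optionally the EEG recordings
#' themselves. All subjects share one preset oddball schedule, as in the
#' study protocol. Every random draw derives from `config$seed`, so a fixed
#' seed reproduces the cohort exactly.
#'
#' @param config An [cohort_config()].
#' @param recordings If `FALSE`, skip EEG synthesis (the cohort table and
#'   item responses are enough for behavioral/statistical simulations and
#'   are orders of magnitude faster to produce).
#' @return An object of class `olf_cohort`: a list with `config`,
#'   `schedule`, `cohort` (one row per subject: `subject`, `group`, `age`,
#'   `q1`..`q24`, `upsit_total`, `upsit_modified`, `truth_imcoh_beta`,
#'   `truth_imcoh_gamma`), `profiles`, and `recordings` (a named list or
#'   `NULL`).
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(seed = 42), recordings = FALSE)
#' nrow(sim$cohort) # 24
generate_cohort <- function(config, recordings = TRUE) {
  stopifnot(inherits(config, "olf_config"))
  n <- config$n_healthy + config$n_ad
  groups <- c(rep("healthy", config$n_healthy), rep("AD", config$n_ad))

  draws <- withr::with_seed(config$seed, {
    ages <- pmin(pmax(rnorm(n, config$age_mean[groups], config$age_sd[groups]), 55), 92)
    ability <- rnorm(n, 0, config$subject_sigma)
    z1 <- rnorm(n)
    z2 <- config$imcoh_rho * z1 + sqrt(1 - config$imcoh_rho^2) * rnorm(n)
    tau_mu <- config$imcoh_mean[groups]
    tau_sd <- config$imcoh_sd[groups]
    list(ages = ages, ability = ability,
         tau_beta  = pmin(pmax(tau_mu + tau_sd * z1, 0.02), 0.70),
         tau_gamma = pmin(pmax(tau_mu + tau_sd * z2, 0.02), 0.70),
         subj_seeds = sample.int(.Machine$integer.max - 1, 2 * n))
  })

  schedule <- generate_schedule(config$n_trials, config$p_rare,
                                config$trial_period, seed = config$seed,
                                stim_duration = config$stim_duration)

  profiles <- vector("list", n)
  items <- matrix(NA_integer_, n, 24)
  recs <- if (recordings) vector("list", n) else NULL
  ids <- sprintf("S%02d", seq_len(n))

  for (i in seq_len(n)) {
    base <- if (groups[i] == "healthy") config$item_probs_healthy else config$item_probs_ad
    base <- pmin(pmax(base, 0.005), 0.995)
    p_i <- expit(logit(base) + draws$ability[i] +
                   config$age_slope * (draws$ages[i] - 70))
    profiles[[i]] <- subject_profile(
      group = groups[i], age = draws$ages[i],
      coupling = coupling_for_tau(c(draws$tau_beta[i], draws$tau_gamma[i])),
      item_probs = p_i, blink_rate = config$blink_rate
    )
    items[i, ] <- generate_item_responses(profiles[[i]], seed = draws$subj_seeds[i])
    if (recordings) {
      recs[[i]] <- generate_recording(profiles[[i]], schedule, fs = config$fs,
                                      seed = draws$subj_seeds[n + i])
    }
  }

  cohort <- data.frame(subject = ids, group = groups, age = draws$ages,
                       stringsAsFactors = FALSE)
  colnames(items) <- paste0("q", seq_len(24))
  cohort <- cbind(cohort, as.data.frame(items))
  cohort$upsit_total <- rowSums(items)
  cohort$upsit_modified <- items[, 6] + items[, 21]
  cohort$truth_imcoh_beta <- draws$tau_beta
  cohort$truth_imcoh_gamma <- draws$tau_gamma

  if (recordings) names(recs) <- ids
  structure(list(config = config, schedule = schedule, cohort = cohort,
                 profiles = setNames(profiles, ids), recordings = recs),
            class = "olf_cohort")
}

#' @export
print.olf_cohort <- function(x, ...) {
  cat(sprintf("<olf_cohort> %d healthy + %d AD (effects: %s, seed %d)%s\n",
              x$config$n_healthy, x$config$n_ad, x$config$effects,
              x$config$seed,
              if (is.null(x$recordings)) ", no recordings" else ""))
  invisible(x)
}
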