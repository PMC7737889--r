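#' Generate an olfactory oddball stimulus schedule
#'
#' Builds a fixed-composition oddball sequence: `n_trials * p_rare` rare
#' (deviant) stimuli permuted at random among the frequent (standard)
#' stimuli, one trial every `trial_period` seconds. The study protocol is a
#' 120-trial sequence with rare probability 0.25 (90 frequent, 30 rare),
#' a 2 s odor presentation followed by 8 s of rest, i.e. a 10 s trial.
#'
#' In fixed-composition mode (the default and only mode) the rare count must
#' be integral: `n_trials * p_rare` is required to be a whole number.
#'
#' @param n_trials Number of trials.
#' @param p_rare Probability of the rare stimulus, in (0, 1).
#' @param trial_period Trial length in seconds (stimulus + rest).
#' @param seed Integer seed; the same seed reproduces the same label order.
#' @param stim_duration Odor presentation time in seconds (metadata only).
#' @return An object of class `olf_schedule`: a list with `n_trials`,
#'   `trial_period`, `stim_duration`, `labels` (character, "frequent"/"rare")
#'   and `onsets` (seconds from task start, `0, trial_period, ...`).
#' @export
#' @examples
#' sch <- generate_schedule(120, 0.25, 10, seed = 7)
#' table(sch$labels)
generate_schedule <- function(n_trials, p_rare, trial_period = 10,
                              seed = 1, stim_duration = 2) {
  stopifnot(n_trials >= 1, trial_period > 0)
  if (p_rare <= 0 || p_rare >= 1) stop("p_rare must be strictly between 0 and 1")
  n_rare <- n_trials * p_rare
  if (abs(n_rare - round(n_rare)) > 1e-9) {
    stop("fixed-composition schedule needs an integral rare count: ",
         "n_trials * p_rare = ", n_rare)
  }
  n_rare <- as.integer(round(n_rare))
  labels <- c(rep("rare", n_rare), rep("frequent", n_trials - n_rare))
  labels <- withr::with_seed(seed, sample(labels))
  structure(
    list(
      n_trials = as.integer(n_trials),
      trial_period = trial_period,
      stim_duration = stim_duration,
      labels = labels,
      onsets = (seq_len(n_trials) - 1) * trial_period
    ),
    class = "olf_schedule"
  )
}

#' @export
print.olf_schedule <- function(x, ...) {
  cat(sprintf("<olf_schedule> %d trials x %.1f s (%s rare), duration %.0f s\n",
              x$n_trials, x$trial_period,
              sprintf("%d", sum(x$labels == "rare")),
              x$n_trials * x$trial_period))
  invisible(x)
}
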