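#' End-to-end analysis of a synthetic cohort
#'
#' Runs the full analysis on a simulated (or re-loaded) cohort: per-subject
#' EEG preprocessing (band limiting, decimation, blink removal, epoching,
#' artifact rejection, condition selection), ImCoh feature extraction,
#' odor-level significance selection, ImCoh group statistics with the
#' effective-number-of-tests FDR correction, and the modality-comparison
#' classification table.
#'
#' @param sim An `olf_cohort` from [generate_cohort()] or [read_cohort()],
#'   with recordings present.
#' @param pairs,bands ImCoh features to compute (defaults: all 6 pairs x 5
#'   bands = 30). Restricting to `pairs = "Fz-Cz"`, `bands = c("beta",
#'   "gamma")` computes only the classifier's features.
#' @param condition Epoch condition analyzed (`"frequent"` in the study).
#' @param par_threshold Artifact-rejection threshold.
#' @param q FDR level for both the odor selection and the ImCoh contrasts.
#' @param seed Seed for the cross-validation fold assignment.
#' @param average ImCoh averaging order, see [band_filter_then_imcoh()].
#' @param specs Feature sets for the classifier comparison; defaults to all
#'   five when the full feature set is computed, otherwise to the sets the
#'   computed columns support.
#' @return A list of class `olf_report`: `cohort` (table with appended
#'   ImCoh feature columns), `counts` (per-subject epochs extracted /
#'   rejected / kept), `odors` ([select_significant_odors()] output),
#'   `imcoh_tests` (per-feature Welch tests with `m_eff`-adjusted BH flags),
#'   `m_eff`, and `comparison` ([run_comparison()] table).
#' @export
analyze_cohort <- function(sim, pairs = OLF_PAIRS, bands = olf_bands()$band,
                           condition = "frequent", par_threshold = 8,
                           q = 0.05, seed = 1,
                           average = c("epoch", "csd"), specs = NULL) {
  average <- match.arg(average)
  stopifnot(inherits(sim, "olf_cohort"))
  if (is.null(sim$recordings)) stop("cohort has no recordings to analyze")
  cohort <- sim$cohort
  ids <- cohort$subject
  feat_names <- as.vector(t(outer(pairs, bands, paste, sep = "_")))
  feats <- matrix(NA_real_, length(ids), length(feat_names),
                  dimnames = list(ids, feat_names))
  counts <- data.frame(subject = ids, extracted = NA_integer_,
                       rejected = NA_integer_, kept = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rec <- sim$recordings[[ids[i]]]
    ep <- rec |>
      bandlimit() |>
      resample_recording(200) |>
      remove_blinks() |>
      extract_epochs()
    n_ext <- length(ep$labels)
    ep <- reject_artifacts(ep, par_threshold)
    n_rej <- n_ext - sum(ep$kept)
    ep <- select_condition(ep, condition)
    counts$extracted[i] <- n_ext
    counts$rejected[i] <- n_rej
    counts$kept[i] <- sum(ep$kept)
    feats[i, ] <- subject_features(ep, pairs = pairs, bands = bands,
                                   average = average)[feat_names]
  }
  cohort <- cbind(cohort, as.data.frame(feats, check.names = FALSE))

  odors <- select_significant_odors(cohort, q = q)

  m_eff <- if (length(feat_names) >= 2) effective_test_count(feats) else NULL
  gh <- cohort$group == "healthy"
  imcoh_tests <- do.call(rbind, lapply(feat_names, function(fn) {
    wt <- welch_t(feats[gh, fn], feats[!gh, fn])
    data.frame(feature = fn, t = wt$t, p = wt$p, stringsAsFactors = FALSE)
  }))
  imcoh_tests$significant <- bh_fdr(imcoh_tests$p, q, m_eff)

  if (is.null(specs)) {
    specs <- names(FEATURE_SPECS)[vapply(FEATURE_SPECS, function(cols) {
      all(cols %in% names(cohort))
    }, logical(1))]
  }
  comparison <- run_comparison(cohort, spec_names = specs, seed = seed)

  structure(list(cohort = cohort, counts = counts, odors = odors,
                 imcoh_tests = imcoh_tests, m_eff = m_eff,
                 comparison = comparison),
            class = "olf_report")
}

#' @export
print.olf_report <- function(x, ...) {
  cat(sprintf("<olf_report> %d subjects; odors selected: %s; m_eff %.2f\n",
              nrow(x$cohort),
              if (length(x$odors$selected)) {
                paste0("Q", x$odors$selected, collapse = ", ")
              } else "none",
              x$m_eff %||% NA))
  print(x$comparison[, c("spec", "age_mode", "accuracy_pct", "auc")],
        row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to tab-separated files
#'
#' Persists the tables of an [analyze_cohort()] report: the cohort with its
#' ImCoh feature columns (`cohort_features.tsv`), per-odor test results
#' (`odor_tests.tsv`), per-feature ImCoh tests (`imcoh_tests.tsv`), the
#' modality comparison (`comparison.tsv`) and the per-subject epoch counts
#' (`counts.tsv`).
#'
#' @param report An `olf_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "olf_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE,
                                   fileEncoding = "UTF-8")
  wt(report$cohort, "cohort_features.tsv")
  wt(report$odors$results, "odor_tests.tsv")
  wt(report$imcoh_tests, "imcoh_tests.tsv")
  wt(report$comparison, "comparison.tsv")
  wt(report$counts, "counts.tsv")
  invisible(dir)
}

#' Summary statistics of the packaged cognitive-screen table
#'
#' Group sizes, MMSE mean +/- sample SD per diagnosis group, and the Welch
#' t-test p-value for the group separation, recomputed from the packaged
#' per-subject table (see [load_mmse_fixture()]).
#'
#' @return A list with `n` (named counts), `mmse_mean`, `mmse_sd` (exact,
#'   plus 1 d.p. `_rounded` copies), and `welch_p`.
#' @export
#' @examples
#' fixture_stats()$n
fixture_stats <- function() {
  tab <- suppressWarnings(load_mmse_fixture())
  h <- tab$mmse[tab$diagnosis == "Normal"]
  a <- tab$mmse[tab$diagnosis == "Mild AD"]
  wt <- welch_t(h, a)
  list(n = c(healthy = length(h), AD = length(a)),
       mmse_mean = c(healthy = mean(h), AD = mean(a)),
       mmse_sd = c(healthy = sd(h), AD = sd(a)),
       mmse_mean_rounded = round(c(healthy = mean(h), AD = mean(a)), 1),
       mmse_sd_rounded = round(c(healthy = sd(h), AD = sd(a)), 1),
       welch_p = wt$p)
}
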