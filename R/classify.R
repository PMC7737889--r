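# canonical feature-set specifications (the five modality comparisons)
FEATURE_SPECS <- list(
  total_upsit            = "upsit_total",
  modified_upsit         = "upsit_modified",
  imcoh_beta_gamma_FzCz  = c("Fz-Cz_beta", "Fz-Cz_gamma"),
  `imcoh+total`          = c("Fz-Cz_beta", "Fz-Cz_gamma", "upsit_total"),
  `imcoh+modified`       = c("Fz-Cz_beta", "Fz-Cz_gamma", "upsit_modified")
)

#' Feature-set specification
#'
#' Names one of the five canonical feature sets compared in the study:
#' the total smell score, the modified (two-odor) smell score, the two
#' significant ImCoh features (Fz-Cz beta and gamma), and the two
#' multimodal combinations. `age_mode` selects whether features enter raw
#' (`"disregarded"`, age excluded) or as residuals from the healthy-group
#' age line (`"adjusted"`).
#'
#' @param name One of `"total_upsit"`, `"modified_upsit"`,
#'   `"imcoh_beta_gamma_FzCz"`, `"imcoh+total"`, `"imcoh+modified"`.
#' @param age_mode `"disregarded"` or `"adjusted"`.
#' @return An object of class `olf_spec`.
#' @export
feature_spec <- function(name = names(FEATURE_SPECS),
                         age_mode = c("disregarded", "adjusted")) {
  name <- match.arg(name)
  age_mode <- match.arg(age_mode)
  structure(list(name = name, age_mode = age_mode,
                 columns = FEATURE_SPECS[[name]]),
            class = "olf_spec")
}

#' Build a classification design matrix from a cohort table
#'
#' Extracts the spec's feature columns and labels. In `age_mode =
#' "adjusted"` every column is replaced by its residual from the
#' healthy-group age regression fitted on the full cohort (the study's
#' fit-once adjustment); healthy column means are then ~0 by construction.
#' Age itself is never a feature.
#'
#' @param cohort Cohort data.frame with `group`, `age` and the spec's
#'   feature columns.
#' @param spec An [feature_spec()].
#' @return A list with `X` (numeric matrix), `labels` (factor healthy/AD)
#'   and `ages`.
#' @export
build_features <- function(cohort, spec) {
  stopifnot(inherits(spec, "olf_spec"))
  missing_cols <- setdiff(spec$columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(cohort[, spec$columns, drop = FALSE])
  storage.mode(X) <- "double"
  labels <- factor(cohort$group, levels = c("healthy", "AD"))
  if (anyNA(labels)) stop("group labels must be 'healthy' or 'AD'")
  if (spec$age_mode == "adjusted") {
    hm <- labels == "healthy"
    for (j in seq_len(ncol(X))) {
      line <- fit_age_line(X[, j], cohort$age, hm)
      X[, j] <- age_adjust(X[, j], cohort$age, line)
    }
  }
  list(X = X, labels = labels, ages = cohort$age)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (g in levels(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated linear SVM classification
#'
#' Stratified k-fold cross-validation of a linear-kernel support vector
#' machine. Within each fold the features are standardized by the training
#' fold's statistics, and (optionally) age-adjusted with a healthy-group
#' age line refitted on the training fold only, so no test-fold information
#' leaks into training. Out-of-fold class predictions are pooled into the
#' accuracy; pooled decision scores give the AUC (scores oriented so that
#' larger means more AD-like).
#'
#' @param X Numeric feature matrix (subjects x features).
#' @param labels Factor with levels `healthy`, `AD`.
#' @param n_folds Number of folds (5 in the study).
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM regularization constant C.
#' @param ages Optional ages, required for in-fold age adjustment.
#' @param adjust_age If `TRUE`, residualize features against the healthy
#'   training-fold age line inside each fold.
#' @param fit_once If `TRUE` (with `adjust_age`), fit the age line once on
#'   the full cohort instead of per fold -- the study's original, slightly
#'   leaky procedure, kept for fidelity comparisons.
#' @return An object of class `olf_cv`: list with `accuracy`, `auc`,
#'   `fold`, `pred`, `scores`, `labels`, `seed`.
#' @export
cv_linear_classifier <- function(X, labels, n_folds = 5, seed = 1, cost = 1,
                                 ages = NULL, adjust_age = FALSE,
                                 fit_once = FALSE) {
  X <- as.matrix(X)
  labels <- factor(labels, levels = c("healthy", "AD"))
  stopifnot(nrow(X) == length(labels), !anyNA(labels))
  if (adjust_age && is.null(ages)) stop("ages required for age adjustment")
  if (min(table(labels)) < n_folds) {
    stop("stratified ", n_folds, "-fold CV needs at least ", n_folds,
         " subjects per class; re-stratify with fewer folds")
  }
  fold <- stratified_folds(labels, n_folds, seed)
  if (adjust_age && fit_once) {
    for (j in seq_len(ncol(X))) {
      line <- fit_age_line(X[, j], ages, labels == "healthy")
      X[, j] <- age_adjust(X[, j], ages, line)
    }
  }
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  scores <- numeric(length(labels))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2) stop("training split lost a class")
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (adjust_age && !fit_once) {
      for (j in seq_len(ncol(X))) {
        line <- fit_age_line(Xtr[, j], ages[tr], labels[tr] == "healthy")
        Xte[, j] <- age_adjust(Xte[, j], ages[!tr], line)
        Xtr[, j] <- age_adjust(Xtr[, j], ages[tr], line)
      }
    }
    mu <- colMeans(Xtr)
    sds <- apply(Xtr, 2, sd)
    sds[sds == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sds, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sds, "/")
    fit <- e1071::svm(Xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pr <- predict(fit, Xte, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # orient decision values so that larger = more AD-like
    if (grepl("^healthy/", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
    pred[!tr] <- pr
    scores[!tr] <- dv
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("healthy", "AD"), direction = "<",
                   quiet = TRUE)
  structure(list(accuracy = mean(pred == labels),
                 auc = as.numeric(pROC::auc(roc)),
                 fold = fold, pred = pred, scores = scores,
                 labels = labels, seed = seed),
            class = "olf_cv")
}

#' @export
print.olf_cv <- function(x, ...) {
  cat(sprintf("<olf_cv> accuracy %.1f%%, AUC %.3f (%d folds, seed %d)\n",
              100 * x$accuracy, x$auc, length(unique(x$fold)), x$seed))
  invisible(x)
}

#' Compare single- and multi-modal classifiers
#'
#' Runs the cross-validated linear SVM for every requested feature set and
#' age mode and tabulates accuracy and AUC -- the package's analogue of the
#' study's modality-comparison table (five feature sets, with age
#' disregarded and age adjusted).
#'
#' @param cohort Cohort data.frame with the needed feature columns.
#' @param spec_names Feature-set names, see [feature_spec()].
#' @param age_modes Age handling modes to evaluate.
#' @param seed,n_folds,cost Passed to [cv_linear_classifier()].
#' @param fit_once Use the fit-once age adjustment (see
#'   [cv_linear_classifier()]).
#' @return A data.frame with columns `spec`, `age_mode`, `accuracy`
#'   (fraction), `accuracy_pct` (1 d.p.), `auc` (3 d.p.).
#' @export
run_comparison <- function(cohort, spec_names = names(FEATURE_SPECS),
                           age_modes = c("disregarded", "adjusted"),
                           seed = 1, n_folds = 5, cost = 1,
                           fit_once = FALSE) {
  rows <- list()
  for (mode in age_modes) {
    for (nm in spec_names) {
      sp <- feature_spec(nm, age_mode = "disregarded")  # adjustment done in CV
      bf <- build_features(cohort, sp)
      cv <- cv_linear_classifier(bf$X, bf$labels, n_folds = n_folds,
                                 seed = seed, cost = cost, ages = bf$ages,
                                 adjust_age = (mode == "adjusted"),
                                 fit_once = fit_once)
      rows[[length(rows) + 1]] <- data.frame(
        spec = nm, age_mode = mode,
        accuracy = cv$accuracy,
        accuracy_pct = round(100 * cv$accuracy, 1),
        auc = round(cv$auc, 3),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
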