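#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test with Welch-Satterthwaite degrees of freedom
#' (via [stats::t.test()]). Requires at least two observations per sample
#' and non-degenerate variance in at least one sample.
#'
#' @param a,b Numeric samples.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    stop("both samples have zero variance; Welch t-test undefined")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up procedure: sort the p-values ascending and find the
#' largest rank `k` with `p_(k) <= k * q / m`; the `k` smallest p-values
#' are declared significant. When an effective number of tests `m_eff` is
#' supplied (see [effective_test_count()]) it replaces `m` in the
#' threshold, de-conservatizing the correction for correlated features.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @param m_eff Optional effective number of tests, `1 <= m_eff <=
#'   length(pvals)`; may be fractional.
#' @return Logical significance mask aligned with `pvals`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.03, 0.9)) # first three TRUE
bh_fdr <- function(pvals, q = 0.05, m_eff = NULL) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("invalid FDR level q = ", q)
  m <- m_eff %||% length(pvals)
  if (m > length(pvals) || m < 1) stop("m_eff must lie in [1, number of tests]")
  o <- order(pvals)
  ps <- pvals[o]
  k <- which(ps <= seq_along(ps) * q / m)
  sig <- logical(length(pvals))
  if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
  sig
}

#' Effective number of independent tests
#'
#' Eigenvalue-based count of effectively independent hypotheses among
#' correlated features: from the eigenvalues `lambda_i` of the feature
#' correlation matrix,
#' \deqn{m_{eff} = m - \sum_{\lambda_i > 1} (\lambda_i - 1),}
#' clamped to `[1, m]`. Duplicated features collapse to 1; independent
#' features approach `m`; `m_eff` decreases monotonically with increasing
#' pairwise correlation.
#'
#' @param features Numeric matrix, subjects x features (>= 3 subjects,
#'   >= 2 features, no constant column).
#' @return The (possibly fractional) effective test count.
#' @export
effective_test_count <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need at least two features")
  if (nrow(features) < 3) stop("need at least three subjects")
  sds <- apply(features, 2, sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  lam <- eigen(cor(features), symmetric = TRUE, only.values = TRUE)$values
  m <- ncol(features)
  min(max(m - sum(pmax(lam - 1, 0)), 1), m)
}

# Welch t on a binary item column with degenerate-variance guards:
# both groups constant & equal -> no evidence (p = 1); both constant but
# different -> fall back to Fisher's exact test (t undefined)
item_test <- function(a, b, method = c("welch", "fisher")) {
  method <- match.arg(method)
  if (method == "fisher") {
    tab <- rbind(c(sum(a), length(a) - sum(a)), c(sum(b), length(b) - sum(b)))
    return(list(t = NA_real_, p = fisher.test(tab)$p.value))
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    tab <- rbind(c(sum(a), length(a) - sum(a)), c(sum(b), length(b) - sum(b)))
    return(list(t = NA_real_, p = fisher.test(tab)$p.value))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Select the odors that separate the groups
#'
#' Per-item two-sample test of the binary responses (AD vs healthy) over
#' the 24 odors, followed by Benjamini-Hochberg FDR control at level `q`.
#' Returns the surviving items -- in the study these were item 6 (grape)
#' and item 21 (chocolate).
#'
#' @param cohort A cohort data.frame with a `group` column and item columns
#'   `q1`..`q24` (as produced by [generate_cohort()]), or a plain binary
#'   matrix plus `group` vector.
#' @param group Group labels if `cohort` is a bare matrix.
#' @param q FDR level.
#' @param method Per-item test: `"welch"` (the study's choice) or
#'   `"fisher"` (exact alternative).
#' @param m_eff Optional effective test count passed to [bh_fdr()].
#' @return A list with `selected` (integer item indices) and `results`
#'   (data.frame: `item`, `t`, `p`, `significant`, one row per odor).
#' @export
select_significant_odors <- function(cohort, group = NULL, q = 0.05,
                                     method = c("welch", "fisher"),
                                     m_eff = NULL) {
  method <- match.arg(method)
  if (is.data.frame(cohort)) {
    items <- as.matrix(cohort[, paste0("q", 1:24)])
    group <- cohort$group
  } else {
    items <- as.matrix(cohort)
    if (is.null(group)) stop("group labels required with a bare item matrix")
  }
  if (length(unique(group)) < 2) stop("both groups must be present")
  gh <- group == "healthy"
  res <- lapply(seq_len(ncol(items)), function(j) {
    item_test(items[gh, j], items[!gh, j], method)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  sig <- bh_fdr(p, q, m_eff)
  results <- data.frame(item = paste0("Q", seq_len(ncol(items))),
                        t = vapply(res, `[[`, numeric(1), "t"),
                        p = p, significant = sig,
                        stringsAsFactors = FALSE)
  list(selected = which(sig), results = results)
}

#' Fit the healthy-group age regression line
#'
#' Ordinary least squares of a score or feature on age, fitted on the
#' healthy subjects only. The line models the decline expected from normal
#' aging; residuals from it (for both groups) are the age-adjusted values.
#'
#' @param values Per-subject numeric values.
#' @param ages Ages in years.
#' @param healthy_mask Logical vector marking the healthy subjects.
#' @return An object of class `olf_age_line`: list with `slope`,
#'   `intercept`, `n`.
#' @export
fit_age_line <- function(values, ages, healthy_mask) {
  stopifnot(length(values) == length(ages), length(ages) == length(healthy_mask))
  v <- values[healthy_mask]
  a <- ages[healthy_mask]
  if (length(v) < 3) stop("need at least 3 healthy subjects to fit the age line")
  if (var(a) == 0) stop("zero age variance in the healthy group")
  fit <- lm(v ~ a)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(v)),
            class = "olf_age_line")
}

#' Age-adjust values against the healthy-group line
#'
#' Residual distances of all subjects' values from the regression line
#' fitted to the healthy group: `value - (intercept + slope * age)`. The
#' healthy residuals average zero by construction; an AD-group level shift
#' below the healthy line appears as negative mean residual.
#'
#' @param values Per-subject numeric values (both groups).
#' @param ages Ages in years.
#' @param line An [fit_age_line()] result.
#' @return Numeric residuals aligned with `values`.
#' @export
age_adjust <- function(values, ages, line) {
  stopifnot(inherits(line, "olf_age_line"), length(values) == length(ages))
  values - (line$intercept + line$slope * ages)
}

#' Pearson correlation with significance test
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-degenerate).
#' @return A list with `r` and the two-sided `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need equal-length vectors, n >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}
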