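#' Per-feature two-sample t-tests
#'
#' Two-sided Student's t-test with pooled variance for every feature (row)
#' of an abundance matrix, comparing the two label groups. Zeros standing in
#' for below-detection missing values are included as observations, matching
#' the zero-imputation convention of the upstream matrix. Welch's unequal
#' variance form is available via `var_equal = FALSE`. Features with zero
#' variance in both groups and equal means give p = 1; zero variance with
#' unequal means gives p = 0.
#'
#' @param matrix numeric features x samples matrix.
#' @param labels per-sample class labels (two groups, e.g. cancer/healthy).
#' @param var_equal pooled-variance Student form (default) or Welch.
#' @return named vector of two-sided p-values.
#' @export
tTestPerFeature <- function(matrix, labels, var_equal = TRUE) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, ncol(matrix) == length(labels))
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  x1 <- matrix[, g1, drop = FALSE]; x2 <- matrix[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(matrix))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  p <- 2 * pt(-abs(t), df)
  p[se == 0 & m1 != m2] <- 0
  setNames(p, rownames(matrix))
}

#' Volcano table: per-feature p-values and mean-fold ratios
#'
#' Computes, per feature, the two-sample t-test p-value and the mean-fold
#' ratio MFR (case group mean / control group mean), and applies the volcano
#' selection rule: up-selected iff p < `p_max` and log2(MFR) >
#' `log2_mfr_min`; down-selected iff p < `p_max` and log2(MFR) <
#' -`log2_mfr_min`. Defaults are p < 1e-10 and |log2 MFR| > 0.5 (fold change
#' beyond 2^0.5 ~ 1.41 in either direction). No multiple-testing correction
#' is applied: the stringent raw p cutoff is itself the selection rule.
#'
#' @param matrix features x samples abundance matrix.
#' @param labels per-sample labels.
#' @param case label value of the case (numerator) group, default "cancer".
#' @param p_max,log2_mfr_min selection thresholds.
#' @return data.frame with `feature`, `p_value`, `mfr`, `log2_mfr`,
#'   `selected` ("up", "down" or "none").
#' @export
volcanoTable <- function(matrix, labels, case = "cancer",
                         p_max = 1e-10, log2_mfr_min = 0.5) {
  stopifnot(case %in% labels)
  p <- tTestPerFeature(matrix, labels)
  mc <- rowMeans(matrix[, labels == case, drop = FALSE])
  mh <- rowMeans(matrix[, labels != case, drop = FALSE])
  mfr <- mc / mh
  l2 <- log2(mfr)
  selected <- rep("none", nrow(matrix))
  selected[p < p_max & l2 > log2_mfr_min] <- "up"
  selected[p < p_max & l2 < -log2_mfr_min] <- "down"
  data.frame(feature = if (is.null(rownames(matrix)))
    sprintf("F%04d", seq_len(nrow(matrix))) else rownames(matrix),
    p_value = unname(p), mfr = unname(mfr), log2_mfr = unname(l2),
    selected = selected, row.names = NULL)
}

#' @rdname volcanoTable
#' @param records a `volcanoTable()` data.frame (re-thresholded with the
#'   given cutoffs).
#' @return `volcanoSelect`: the selected feature ids, split into `up` and
#'   `down`.
#' @export
volcanoSelect <- function(records, p_max = 1e-10, log2_mfr_min = 0.5) {
  up <- records$p_value < p_max & records$log2_mfr > log2_mfr_min
  down <- records$p_value < p_max & records$log2_mfr < -log2_mfr_min
  list(up = records$feature[up], down = records$feature[down])
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney concordance probability (rank-based, tie
#' handling by rank midpoints), which coincides with trapezoidal integration
#' of the empirical ROC curve over all thresholds. The curve itself is
#' returned as aligned threshold / sensitivity / specificity vectors.
#'
#' @param scores numeric predictor (higher = more case-like).
#' @param labels class labels; `positive` names the case class.
#' @param positive value of `labels` treated as positive; defaults to
#'   `"cancer"` when present, otherwise the second sorted label value.
#' @return an object of class `ROCResult`: list with `auc`, `thresholds`,
#'   `sensitivities`, `specificities`, `n_pos`, `n_neg`.
#' @export
rocAUC <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (is.null(positive))
    positive <- if ("cancer" %in% labels) "cancer" else sort(unique(labels))[2]
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[y] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!y] <= t), numeric(1))
  structure(list(auc = auc, thresholds = thr, sensitivities = sens,
                 specificities = spec, n_pos = n1, n_neg = n0),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Correlation between a glycopeptide and a tumor marker
#'
#' Pearson correlation; with `log_transform = TRUE` the marker axis is
#' log10(x + eps) where eps is half the smallest positive observed marker
#' value (so zero concentrations stay finite).
#'
#' @param x tumor-marker concentrations.
#' @param y glycopeptide levels.
#' @param log_transform log-transform the marker axis first.
#' @return Pearson correlation coefficient; NA with attribute
#'   `"undefined" = TRUE` if either variable has zero variance.
#' @export
markerCorrelation <- function(x, y, log_transform = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (log_transform) {
    pos <- x[x > 0]
    if (!length(pos)) stop("no positive marker values to define log offset")
    x <- log10(x + min(pos) * 0.5)
  }
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  cor(x, y)
}
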