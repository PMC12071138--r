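#' Classify CSGSA scores at a cutoff
#'
#' Positive iff score is strictly greater than the cutoff (default 1, i.e.
#' predicted probability above 0.9). The strict inequality at the boundary
#' is a documented convention; a score exactly at the cutoff is negative.
#'
#' @param scores numeric CSGSA scores.
#' @param cutoff nonnegative decision cutoff.
#' @return logical vector of screening decisions.
#' @export
classifyScores <- function(scores, cutoff = 1.0) {
  stopifnot(cutoff >= 0)
  scores > cutoff
}

#' 2x2 screening contingency table
#'
#' @param decisions logical (or 0/1) screening decisions.
#' @param labels true states; `positive` names the diseased class.
#' @param positive value of `labels` counted as true positive state
#'   (default `"cancer"` when present, else `TRUE`/1).
#' @return a `ContingencyTable`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
contingencyTable <- function(decisions, labels, positive = NULL) {
  if (length(decisions) != length(labels))
    stop("decisions and labels must have equal length")
  decisions <- as.logical(decisions)
  if (is.null(positive))
    positive <- if ("cancer" %in% labels) "cancer" else TRUE
  truth <- labels == positive
  structure(list(tp = sum(decisions & truth),
                 fp = sum(decisions & !truth),
                 fn = sum(!decisions & truth),
                 tn = sum(!decisions & !truth)),
            class = "ContingencyTable")
}

#' @export
print.ContingencyTable <- function(x, ...) {
  cat("            Diseased  Healthy\n")
  cat(sprintf("  Positive  %8d  %7d\n", x$tp, x$fp))
  cat(sprintf("  Negative  %8d  %7d\n", x$fn, x$tn))
  invisible(x)
}

#' Sensitivity and specificity of a contingency table
#'
#' sensitivity = tp / (tp + fn); specificity = tn / (fp + tn).
#'
#' @param table a [contingencyTable()] result (or list with tp/fp/fn/tn).
#' @return list with `sensitivity` and `specificity` (proportions).
#' @export
sensSpec <- function(table) {
  if (table$tp + table$fn == 0) stop("no diseased samples: sensitivity undefined")
  if (table$fp + table$tn == 0) stop("no healthy samples: specificity undefined")
  list(sensitivity = table$tp / (table$tp + table$fn),
       specificity = table$tn / (table$fp + table$tn))
}

#' Prevalence-corrected screening table
#'
#' Re-expresses a classifier's operating point in a hypothetical screening
#' population at a stated disease prevalence: exact corrected counts are
#' tp = N * prev * sens, fn = N * prev * (1 - sens),
#' fp = N * (1 - prev) * (1 - spec), tn = N * (1 - prev) * spec, from which
#' PPV = tp / (tp + fp) and NPV = tn / (tn + fn) are computed on the exact
#' values; counts are additionally rounded to integers for display (rounded
#' margins may differ from N by at most a unit or two; the exact values are
#' authoritative). At a prevalence equal to the observed dataset prevalence
#' this reproduces the observed PPV/NPV exactly.
#'
#' @param sensitivity,specificity operating characteristics in \[0, 1\].
#' @param prevalence disease prevalence (default 100 per 100,000).
#' @param population hypothetical screening population size.
#' @return a `PrevalenceCorrectedTable`: exact and display counts, `ppv`,
#'   `npv` (NA with attribute `undefined` when prevalence is 0).
#' @export
prevalenceCorrect <- function(sensitivity, specificity, prevalence = 1e-3,
                              population = 1e5) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1,
            population > 0)
  tp <- population * prevalence * sensitivity
  fn <- population * prevalence * (1 - sensitivity)
  fp <- population * (1 - prevalence) * (1 - specificity)
  tn <- population * (1 - prevalence) * specificity
  ppv <- if (tp + fp > 0) tp / (tp + fp) else
    structure(NA_real_, undefined = TRUE)
  if (prevalence == 0) ppv <- structure(NA_real_, undefined = TRUE)
  npv <- if (tn + fn > 0) tn / (tn + fn) else
    structure(NA_real_, undefined = TRUE)
  structure(list(population = population, prevalence = prevalence,
                 exact = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 counts = round(c(tp = tp, fp = fp, fn = fn, tn = tn)),
                 ppv = ppv, npv = npv),
            class = "PrevalenceCorrectedTable")
}

#' @export
print.PrevalenceCorrectedTable <- function(x, ...) {
  cat(sprintf("Prevalence-corrected to %g per %s:\n",
              x$prevalence * x$population,
              format(x$population, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  Positive  %8d  %8d   PPV %.1f%%\n",
              x$counts["tp"], x$counts["fp"], 100 * x$ppv))
  cat(sprintf("  Negative  %8d  %8d   NPV %.2f%%\n",
              x$counts["fn"], x$counts["tn"], 100 * x$npv))
  invisible(x)
}

#' Full screening evaluation report
#'
#' From pooled CSGSA scores and true labels: classifies at the cutoff,
#' tabulates the observed 2x2 block, computes sensitivity/specificity, and
#' appends the prevalence-corrected block with PPV/NPV. The observed block
#' counts pooled test-set predictions (a sample scored in several repeats
#' contributes each time), so pool sizes, not subject counts, are reported.
#'
#' @param scores pooled CSGSA scores.
#' @param labels true states aligned with `scores`.
#' @param cutoff decision cutoff on the score scale.
#' @param prevalence,population see [prevalenceCorrect()].
#' @return a `ScreeningReport` list: `observed` (ContingencyTable),
#'   `sensitivity`, `specificity`, `observed_ppv`, `observed_npv`,
#'   `corrected` (PrevalenceCorrectedTable).
#' @export
screeningReport <- function(scores, labels, cutoff = 1.0, prevalence = 1e-3,
                            population = 1e5) {
  tab <- contingencyTable(classifyScores(scores, cutoff), labels)
  ss <- sensSpec(tab)
  corrected <- prevalenceCorrect(ss$sensitivity, ss$specificity,
                                 prevalence, population)
  structure(list(observed = tab, sensitivity = ss$sensitivity,
                 specificity = ss$specificity,
                 observed_ppv = tab$tp / (tab$tp + tab$fp),
                 observed_npv = tab$tn / (tab$tn + tab$fn),
                 corrected = corrected, cutoff = cutoff),
            class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat(sprintf("Screening at score cutoff %g\nObserved (pooled predictions):\n",
              x$cutoff))
  print(x$observed)
  cat(sprintf("  Sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  print(x$corrected)
  invisible(x)
}
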