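#' Diagnostic confusion counts
#'
#' Tallies a binary test against truth using the diseased / non-diseased
#' convention: `M` diseased & test-positive, `N` diseased & test-negative,
#' `P` non-diseased & test-positive, `Q` non-diseased & test-negative.
#' Label 1 means diseased / positive.
#'
#' @param predicted,truth equal-length 0/1 vectors.
#' @return named list `M`, `N`, `P`, `Q` of class `confusion_counts`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("labels must be binary (0 = non-diseased, 1 = diseased)")
  }
  structure(list(M = sum(truth == 1 & predicted == 1),
                 N = sum(truth == 1 & predicted == 0),
                 P = sum(truth == 0 & predicted == 1),
                 Q = sum(truth == 0 & predicted == 0)),
            class = "confusion_counts")
}

#' Sensitivity and specificity
#'
#' `sensitivity = M / (M + N)` (true-positive rate over the diseased
#' group); `specificity = Q / (P + Q)` (true-negative rate over the
#' non-diseased group).
#'
#' @param counts a [confusion_counts].
#' @return scalar in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  if (counts$M + counts$N < 1) stop("undefined rate: no diseased subjects (M + N = 0)")
  counts$M / (counts$M + counts$N)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  if (counts$P + counts$Q < 1) stop("undefined rate: no non-diseased subjects (P + Q = 0)")
  counts$Q / (counts$P + counts$Q)
}

check_rate <- function(x, name) {
  if (x < 0 || x > 1) stop(sprintf("%s must lie in [0, 1]", name))
}

#' Predictive values at a given disease prevalence
#'
#' Bayes-rule combinations of sensitivity s, specificity sp and prevalence
#' pi: `PPV = s pi / (s pi + (1 - sp)(1 - pi))` and
#' `NPV = sp (1 - pi) / ((1 - s) pi + sp (1 - pi))`.
#'
#' @param sens,spec sensitivity and specificity in `[0, 1]`.
#' @param prevalence disease prevalence in `(0, 1)`.
#' @return scalar in `[0, 1]`.
#' @export
ppv <- function(sens, spec, prevalence) {
  check_rate(sens, "sensitivity"); check_rate(spec, "specificity")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  den <- sens * prevalence + (1 - spec) * (1 - prevalence)
  if (den == 0) stop("undefined value: no positive tests possible (denominator 0)")
  sens * prevalence / den
}

#' @rdname ppv
#' @export
npv <- function(sens, spec, prevalence) {
  check_rate(sens, "sensitivity"); check_rate(spec, "specificity")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  den <- (1 - sens) * prevalence + spec * (1 - prevalence)
  if (den == 0) stop("undefined value: no negative tests possible (denominator 0)")
  spec * (1 - prevalence) / den
}

#' Prevalence-weighted accuracy
#'
#' `accuracy = sens * pi + spec * (1 - pi)`. At the empirical prevalence
#' `pi = (M + N) / (M + N + P + Q)` this equals the count-based accuracy
#' `(M + Q) / total`.
#'
#' @inheritParams ppv
#' @param percent return the value times 100 (paper-style percentage).
#' @return scalar in `[0, 1]` (or `[0, 100]` when `percent = TRUE`).
#' @export
prevalence_accuracy <- function(sens, spec, prevalence, percent = FALSE) {
  check_rate(sens, "sensitivity"); check_rate(spec, "specificity")
  check_rate(prevalence, "prevalence")
  acc <- sens * prevalence + spec * (1 - prevalence)
  if (percent) 100 * acc else acc
}

#' Full diagnostic report from labels
#'
#' @param predicted,truth 0/1 label vectors.
#' @param prevalence optional prevalence; defaults to the empirical value
#'   `(M + N) / total`.
#' @return list with counts, sensitivity, specificity, PPV, NPV, accuracy
#'   (fraction) and accuracy_percent.
#' @export
evaluate_predictions <- function(predicted, truth, prevalence = NULL) {
  cc <- confusion_counts(predicted, truth)
  s <- sensitivity(cc); sp <- specificity(cc)
  total <- cc$M + cc$N + cc$P + cc$Q
  if (is.null(prevalence)) prevalence <- (cc$M + cc$N) / total
  list(M = cc$M, N = cc$N, P = cc$P, Q = cc$Q,
       prevalence = prevalence,
       sensitivity = s, specificity = sp,
       ppv = ppv(s, sp, prevalence), npv = npv(s, sp, prevalence),
       accuracy = prevalence_accuracy(s, sp, prevalence),
       accuracy_percent = prevalence_accuracy(s, sp, prevalence, percent = TRUE))
}
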