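# The composite 10-point PH-prediction score: age > 53 years and
# TLC/DLCO > 1.67 earn three points each; 6MWD < 507.5 m and sixth-minute
# saturation < 93% earn two points each.  A total of >= 6 points flags an
# increased probability of PH.

#' Composite score weights
#'
#' @param items data.frame with columns `variable`, `cutoff`, `direction`,
#'   `points`; defaults to the published four-item, 10-point rule.
#' @param decision_cutoff integer; scores at or above it are called
#'   increased-probability (default 6).
#' @return object of class `"score_weights"`.
#' @export
score_weights <- function(items = NULL, decision_cutoff = 6L) {
  if (is.null(items)) {
    items <- data.frame(
      variable = c("age", "tlc_dlco", "six_mwd", "sat6"),
      cutoff = c(53, 1.67, 507.5, 93),
      direction = c("above_is_risk", "above_is_risk",
                    "below_is_risk", "below_is_risk"),
      points = c(3L, 3L, 2L, 2L),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("variable", "cutoff", "direction", "points")
                %in% names(items)))
  if (any(items$points <= 0)) stop("points must be > 0", call. = FALSE)
  structure(list(items = items,
                 decision_cutoff = as.integer(decision_cutoff)),
            class = "score_weights")
}

#' @export
print.score_weights <- function(x, ...) {
  cat(sprintf("composite score (max %d, decision cutoff >= %d):\n",
              sum(x$items$points), x$decision_cutoff))
  for (i in seq_len(nrow(x$items))) {
    it <- x$items[i, ]
    op <- if (it$direction == "above_is_risk") ">" else "<"
    cat(sprintf("  %s %s %g -> %d points\n", it$variable, op, it$cutoff,
                it$points))
  }
  invisible(x)
}

#' Per-patient composite score
#'
#' Sums the points of every satisfied (strict-inequality) criterion.  With
#' the default weights the attainable totals are
#' {0, 2, 3, 4, 5, 6, 7, 8, 10}; 1 and 9 cannot occur.
#'
#' @param cohort a cohort data.frame (TLC/DLCO is derived on demand).
#' @param weights a [score_weights()] object.
#' @return integer vector of scores.
#' @examples
#' rec <- patient_record(id = "p", age = 60, sex = "male",
#'                       diagnosis = "IPF", pack_years = 10, six_mwd = 478,
#'                       sat0 = 95, sat6 = 89, fev1_fvc = 76, fvc_pct = 95,
#'                       tlc_pct = 93, dlco_pct = 50, ntprobnp = 150)
#' composite_score(rec) # 10
#' @export
composite_score <- function(cohort, weights = score_weights()) {
  stopifnot(inherits(weights, "score_weights"))
  total <- integer(nrow(cohort))
  for (i in seq_len(nrow(weights$items))) {
    it <- weights$items[i, ]
    flag <- dichotomize(cohort,
                        threshold_spec(it$variable, it$cutoff, it$direction))
    total <- total + it$points * as.integer(flag)
  }
  total
}

#' Decision rule of the composite score
#'
#' @param score integer score(s).
#' @param weights a [score_weights()] object.
#' @return logical; `TRUE` when `score >= decision_cutoff` (increased PH
#'   probability).
#' @export
classify_score <- function(score, weights = score_weights()) {
  stopifnot(inherits(weights, "score_weights"))
  score >= weights$decision_cutoff
}

#' Operating characteristics of a confusion matrix
#'
#' @param tp,fp,fn,tn nonnegative counts; alternatively pass a list with
#'   these names as `tp`.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`; a
#'   predictive value with an empty denominator is `NA` (flagged
#'   undefined), never silently 0.
#' @examples
#' confusion_metrics(tp = 27, fp = 3, fn = 14, tn = 49)
#' @export
confusion_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.list(tp)) {
    cm <- tp; tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("need at least one record in each class", call. = FALSE)
  }
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Inverts published sensitivity/specificity (rounded rates) and the known
#' strata sizes to the unique integer confusion matrix: `tp` and `tn` are
#' rounded to the nearest integer (half away from zero), `fn` and `fp` are
#' the complements.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg class sizes (positive integers).
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @examples
#' reconstruct_confusion(0.66, 0.94, 41, 52) # tp 27, fn 14, tn 49, fp 3
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_pos >= 1, n_neg >= 1)
  rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)
  tp <- rhalf(sensitivity * n_pos)
  tn <- rhalf(specificity * n_neg)
  cm <- list(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
  if (any(unlist(cm) < 0)) {
    stop("inconsistent rates: negative reconstructed cell", call. = FALSE)
  }
  cm
}

#' Evaluate the composite score on a labelled cohort
#'
#' Scores every record, runs the ROC/AUC machinery on the integer score
#' (group B positive, higher score = more at-risk) and tabulates the
#' confusion matrix and operating characteristics at the decision cutoff.
#'
#' @param cohort labelled cohort (both `ph_group` strata present).
#' @param weights a [score_weights()] object.
#' @param level confidence level for the AUC interval.
#' @return object of class `"score_metrics"`: `auc_result` (DeLong),
#'   `at_cutoff` (sens/spec/ppv/npv at the decision rule), `confusion`,
#'   and the per-record `scores`.
#' @export
evaluate_score_on_cohort <- function(cohort, weights = score_weights(),
                                     level = 0.95) {
  y <- as_positive(cohort$ph_group)
  if (any(is.na(y))) stop("every record needs a ph_group label",
                          call. = FALSE)
  s <- composite_score(cohort, weights)
  auc_res <- auc_delong(s, y, "above_is_risk", level = level)
  pos_call <- classify_score(s, weights)
  cm <- list(tp = sum(pos_call & y), fp = sum(pos_call & !y),
             fn = sum(!pos_call & y), tn = sum(!pos_call & !y))
  structure(list(auc_result = auc_res,
                 at_cutoff = confusion_metrics(cm),
                 confusion = cm,
                 scores = s),
            class = "score_metrics")
}

#' @export
print.score_metrics <- function(x, ...) {
  print(x$auc_result)
  m <- x$at_cutoff
  cat(sprintf("at decision cutoff: sens %.2f, spec %.2f, PPV %.2f, NPV %.2f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}
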