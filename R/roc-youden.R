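# Empirical ROC machinery: staircase curves over the exhaustive candidate
# threshold set (midpoints between adjacent distinct values plus -Inf/+Inf
# sentinels), trapezoidal AUC, DeLong variance with a logit-scale
# confidence interval, and Youden-optimal operating points.
#
# The positive class is always ph_group "B_increased" (increased PH
# probability); `below_is_risk` variables are negated internally so a
# larger working value always means more at-risk.

# Standardize labels to logical (TRUE = positive class).
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  if (all(labels %in% PH_GROUP_LEVELS)) return(labels == "B_increased")
  stop("labels must be logical, 0/1, or ph_group strata", call. = FALSE)
}

#' Empirical ROC curve
#'
#' Candidate cutoffs are the midpoints between adjacent distinct observed
#' values, plus `-Inf`/`+Inf` sentinels, so the curve always contains the
#' (0,0) and (1,1) corners and every attainable operating point.  A record
#' is called at-risk when its value strictly exceeds the threshold
#' (`above_is_risk`) or falls strictly below it (`below_is_risk`).
#'
#' @param values numeric marker values.
#' @param labels class labels (`TRUE`/`"B_increased"` = positive); both
#'   classes must be present.
#' @param direction `"above_is_risk"` or `"below_is_risk"`.
#' @return object of class `"ph_roc"`: `thresholds` (original scale),
#'   `sens`, `spec`, `direction`, `n_pos`, `n_neg`, and the internal
#'   working values.
#' @examples
#' roc_points(c(3, 5, 7, 1, 2, 4), c(1, 1, 1, 0, 0, 0))
#' @export
roc_points <- function(values, labels,
                       direction = c("above_is_risk", "below_is_risk")) {
  direction <- match.arg(direction)
  y <- as_positive(labels)
  stopifnot(length(values) == length(y))
  if (any(is.na(values)) || any(is.na(y))) {
    stop("missing values/labels are not allowed", call. = FALSE)
  }
  if (!any(y) || all(y)) {
    stop("both classes must be present", call. = FALSE)
  }
  w <- if (direction == "above_is_risk") values else -values
  sv <- sort(unique(w))
  thr_w <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  wp <- w[y]; wn <- w[!y]
  sens <- vapply(thr_w, function(t) mean(wp > t), numeric(1))
  spec <- vapply(thr_w, function(t) mean(wn <= t), numeric(1))
  thresholds <- if (direction == "above_is_risk") thr_w else -thr_w
  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 direction = direction,
                 n_pos = sum(y), n_neg = sum(!y),
                 .w = w, .y = y, .thr_w = thr_w),
            class = "ph_roc")
}

#' @export
print.ph_roc <- function(x, ...) {
  cat(sprintf("empirical ROC: %d pos / %d neg, %d candidate thresholds (%s)\n",
              x$n_pos, x$n_neg, length(x$thresholds), x$direction))
  invisible(x)
}

#' Plot an empirical ROC staircase
#'
#' @param x a `"ph_roc"` curve.
#' @param ... passed to [plot()].
#' @export
plot.ph_roc <- function(x, ...) {
  ord <- order(1 - x$spec, x$sens)
  plot(1 - x$spec[ord], x$sens[ord], type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under the ROC curve via trapezoidal integration
#'
#' Equals the Mann-Whitney statistic divided by `n_pos * n_neg` (ties
#' counted half) by construction of the candidate threshold set.
#'
#' @param curve a [roc_points()] result.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "ph_roc"))
  fpr <- 1 - curve$spec
  tpr <- curve$sens
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' AUC with DeLong variance, confidence interval and test against 0.5
#'
#' The AUC is computed from placement values (exactly the tie-corrected
#' Mann-Whitney estimator); its variance follows DeLong's structural
#' components, `var(V10)/n_pos + var(V01)/n_neg`.  The confidence
#' interval is formed on the logit scale and back-transformed, which keeps
#' it inside `[0, 1]`.  Perfect separation has zero DeLong variance: the
#' interval degenerates to the point estimate with a warning.
#'
#' @param values,labels,direction as in [roc_points()]; alternatively pass
#'   a `"ph_roc"` curve as `values`.
#' @param level confidence level (default 0.95).
#' @return object of class `"auc_result"`: `auc`, `ci_low`, `ci_high`,
#'   `level`, `p_value`, `se`.
#' @examples
#' auc_delong(c(3, 5, 7, 1, 2, 4), c(1, 1, 1, 0, 0, 0)) # AUC 8/9
#' @export
auc_delong <- function(values, labels = NULL,
                       direction = c("above_is_risk", "below_is_risk"),
                       level = 0.95) {
  if (inherits(values, "ph_roc")) {
    curve <- values
  } else {
    curve <- roc_points(values, labels, direction)
  }
  wp <- curve$.w[curve$.y]
  wn <- curve$.w[!curve$.y]
  v10 <- vapply(wp, function(x) mean((wn < x) + 0.5 * (wn == x)), numeric(1))
  v01 <- vapply(wn, function(x) mean((wp > x) + 0.5 * (wp == x)), numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / length(v10) + stats::var(v01) / length(v01))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (!is.finite(se) || se == 0) {
    warning("zero DeLong variance (perfect or degenerate separation); ",
            "confidence interval collapses to the point estimate")
    ci <- c(auc, auc)
    p <- if (auc == 0.5) 1 else 0
  } else {
    if (auc <= 0 || auc >= 1) {
      ci <- c(auc, auc)
    } else {
      lg <- stats::qlogis(auc)
      half <- z * se / (auc * (1 - auc))
      ci <- stats::plogis(c(lg - half, lg + half))
    }
    p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
  }
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 level = level, p_value = p, se = se,
                 n_pos = curve$n_pos, n_neg = curve$n_neg),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%g%% CI %.3f-%.3f), p=%.4g vs 0.5\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

# Predictive values at a given prevalence by Bayes' rule.
ppv_npv <- function(sens, spec, prevalence) {
  denom_p <- sens * prevalence + (1 - spec) * (1 - prevalence)
  denom_n <- (1 - sens) * prevalence + spec * (1 - prevalence)
  list(ppv = if (denom_p > 0) sens * prevalence / denom_p else NA_real_,
       npv = if (denom_n > 0) spec * (1 - prevalence) / denom_n else NA_real_)
}

#' Youden-optimal operating point of an ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the candidate
#' thresholds.  Ties are broken towards higher specificity (the screening
#' emphasis of the source analysis), then towards the cutoff farthest from
#' the pooled median (stability).  PPV and NPV are evaluated at the study
#' prevalence `n_pos / (n_pos + n_neg)`.
#'
#' @param curve a [roc_points()] result.
#' @return object of class `"cutoff_result"`: `cutoff` (original scale),
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden_j`.
#' @examples
#' youden_optimal(roc_points(c(3, 5, 7, 1, 2, 4), c(1, 1, 1, 0, 0, 0)))
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "ph_roc"))
  j <- curve$sens + curve$spec - 1
  med <- stats::median(curve$.w)
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[curve$spec[cand] >= max(curve$spec[cand]) - 1e-12]
  dist <- abs(curve$.thr_w[cand] - med)
  best <- cand[which.max(dist)]
  prev <- curve$n_pos / (curve$n_pos + curve$n_neg)
  pv <- ppv_npv(curve$sens[best], curve$spec[best], prev)
  structure(list(cutoff = curve$thresholds[best],
                 sensitivity = curve$sens[best],
                 specificity = curve$spec[best],
                 ppv = pv$ppv, npv = pv$npv,
                 youden_j = j[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "cutoff %g: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f, J=%.3f\n",
    x$cutoff, x$sensitivity, x$specificity, x$ppv, x$npv, x$youden_j))
  invisible(x)
}
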