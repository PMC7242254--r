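# Two-group descriptive and comparative statistics, with the published
# test-selection rule: Shapiro-Wilk normality in both groups plus an F
# test of variance homogeneity gate a pooled Student t-test; otherwise
# the Mann-Whitney U test is used.  Both gates use alpha = 0.05.

#' Mean, sample SD and n of a numeric vector
#'
#' @param x numeric values (no missing values; empty input errors).
#' @return list with `mean`, `sd` (`NA` when n < 2) and `n`.
#' @export
summarize_values <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || any(is.na(x))) {
    stop("summarize_values needs at least one non-missing value",
         call. = FALSE)
  }
  list(mean = mean(x),
       sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
       n = length(x))
}

#' Mann-Whitney U test (rank formula; exact at toy scale)
#'
#' U counts the pairs where a group-`a` value exceeds a group-`b` value,
#' plus half the ties.  For `max(n) <= 8` the two-sided p-value is exact
#' by complete enumeration of group assignments; above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param exact force (`TRUE`)/forbid (`FALSE`) exact enumeration;
#'   `NULL` picks by sample size.
#' @return list with `u`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  u_stat <- function(xa, xb) {
    r <- rank(c(xa, xb))
    sum(r[seq_along(xa)]) - length(xa) * (length(xa) + 1) / 2
  }
  u <- u_stat(a, b)
  if (is.null(exact)) exact <- max(n1, n2) <= 8
  if (exact) {
    pooled <- c(a, b)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-12)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    r <- rank(c(a, b))
    ties <- table(r)
    nn <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * (nn + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    method <- "normal_approx"
  }
  list(u = u, p_value = min(p, 1), method = method)
}

# Pooled-variance two-sample Student t-test (two-sided).
pooled_t_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("t-test needs n >= 2 per group", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) return(list(statistic = 0, p_value = 1))
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tt, p_value = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2))
}

# Default normality gate: Shapiro-Wilk p-value (Royston approximation via
# stats::shapiro.test).  Degenerate samples (zero range) return 0 so the
# pipeline falls back to the rank test rather than erroring.
shapiro_gate <- function(x) {
  if (length(unique(x)) < 3) return(0)
  stats::shapiro.test(x)$p.value
}

# F test of variance homogeneity, two-sided p.
f_test_p <- function(a, b) {
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) return(1)
  if (v1 == 0 || v2 == 0) return(0)
  f <- v1 / v2
  p <- stats::pf(f, length(a) - 1, length(b) - 1)
  2 * min(p, 1 - p)
}

#' Compare one variable between the two PH-probability groups
#'
#' Applies the published selection rule: if Shapiro-Wilk normality holds
#' in both groups and the F test finds homogeneous variances (all at
#' alpha = 0.05), a pooled Student t-test is used; otherwise the
#' Mann-Whitney U test.  The normality gate is pluggable: any function
#' mapping a numeric vector to a p-value conforms.
#'
#' @param a,b numeric samples for group A and group B (n >= 3 each).
#' @param variable label carried into the result.
#' @param normality_test function(x) -> p-value; defaults to Shapiro-Wilk.
#' @param gate_alpha significance level of both gates.
#' @param force `NULL` for the automatic rule, or `"t_student"` /
#'   `"mann_whitney_u"` to override.
#' @return object of class `"group_summary"`: per-group mean/sd/n,
#'   `p_value` and `test_used`.
#' @export
compare_groups <- function(a, b, variable = "x",
                           normality_test = shapiro_gate,
                           gate_alpha = 0.05, force = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs n >= 3", call. = FALSE)
  }
  sa <- summarize_values(a); sb <- summarize_values(b)
  if (is.null(force)) {
    normal_ok <- normality_test(a) > gate_alpha &&
      normality_test(b) > gate_alpha
    var_ok <- f_test_p(a, b) > gate_alpha
    test <- if (normal_ok && var_ok) "t_student" else "mann_whitney_u"
  } else {
    test <- match.arg(force, c("t_student", "mann_whitney_u"))
  }
  p <- if (test == "t_student") pooled_t_test(a, b)$p_value
       else mann_whitney_u(a, b)$p_value
  structure(list(variable = variable,
                 mean_a = sa$mean, sd_a = sa$sd, n_a = sa$n,
                 mean_b = sb$mean, sd_b = sb$sd, n_b = sb$n,
                 p_value = p, test_used = test),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: A %.2f +/- %.2f (n=%d) vs B %.2f +/- %.2f (n=%d), p=%.4g [%s]\n",
              x$variable, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
              x$p_value, x$test_used))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic with optional Yates continuity correction; by default
#' the correction switches on when any expected count is below 5.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param correct `TRUE`/`FALSE`, or `NULL` for the expected-count rule.
#' @return list with `statistic`, `p_value`, `corrected`.
#' @examples
#' chi_square_2x2(matrix(c(20, 5, 5, 20), 2))
#' @export
chi_square_2x2 <- function(tab, correct = NULL) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("a zero marginal leaves the test undefined; use an exact test",
         call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  if (is.null(correct)) correct <- any(expected < 5)
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       corrected = correct)
}
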