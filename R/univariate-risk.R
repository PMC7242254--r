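# Univariate risk estimation: logistic regression fitted by hand via
# iteratively reweighted least squares (IRLS), and the closed-form 2x2
# odds ratio with its Wald interval.  For a single binary covariate the
# two routes agree exactly, which the test suite exploits as a
# cross-check.

#' Univariate logistic regression by IRLS
#'
#' Fits `logit P(y = 1) = beta0 + beta1 * x` by Newton scoring
#' (iteratively reweighted least squares) to a gradient norm below `tol`.
#' Standard errors come from the inverse observed information; the odds
#' ratio per unit of `x` and its Wald confidence interval are reported on
#' the exponential scale.  Perfectly separated data cannot converge: the
#' fit is flagged (`converged = FALSE`) rather than returning silent
#' garbage.
#'
#' @param x numeric covariate (not constant).
#' @param y binary outcome (logical, 0/1, or ph_group strata).
#' @param tol convergence tolerance on the max absolute score (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @param level confidence level of the Wald interval.
#' @return object of class `"logistic_fit"`: `beta0`, `beta1`, `se1`,
#'   `or_per_unit`, `ci_low`, `ci_high`, `converged`, `iterations`.
#' @examples
#' x <- c(rep(1, 31), rep(0, 62))
#' y <- c(rep(1, 27), rep(0, 4), rep(1, 14), rep(0, 48))
#' fit_logistic_irls(x, y)$or_per_unit # (27*48)/(4*14)
#' @export
fit_logistic_irls <- function(x, y, tol = 1e-8, max_iter = 50L,
                              level = 0.95) {
  y <- as.numeric(as_positive(y))
  x <- as.numeric(x)
  stopifnot(length(x) == length(y))
  if (any(is.na(x)) || any(is.na(y))) stop("missing data", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  X <- cbind(1, x, deparse.level = 0)
  beta <- c(stats::qlogis(mean(y)), 0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # dampen huge steps so quasi-separated data walk instead of exploding
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (abs(beta[2]) > 30) break  # drifting to infinity: separation
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X, X * w)
  se1 <- tryCatch(sqrt(solve(info)[2, 2]), error = function(e) NA_real_)
  # a single covariate separates completely iff the class-wise ranges are
  # disjoint; the MLE then sits at infinity even when the score already
  # looks flat, so the fit must be flagged
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    converged <- FALSE
  }
  if (!converged) {
    warning("IRLS did not converge (possible complete separation)")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  beta <- unname(beta)
  structure(list(beta0 = beta[1], beta1 = beta[2], se1 = se1,
                 or_per_unit = exp(beta[2]),
                 ci_low = exp(beta[2] - z * se1),
                 ci_high = exp(beta[2] + z * se1),
                 converged = converged, iterations = iter),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: OR %.4g (CI %.4g-%.4g)%s, %d iterations\n",
              x$or_per_unit, x$ci_low, x$ci_high,
              if (x$converged) "" else " [NOT CONVERGED]", x$iterations))
  invisible(x)
}

#' Odds ratio of a 2x2 exposure table with Wald interval
#'
#' For the table `[[a, b], [c, d]]` (rows: exposed/unexposed, columns:
#' case/non-case), OR = (a d)/(b c) with log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`.  A zero cell leaves the OR undefined;
#' with `correct = TRUE` the Haldane-Anscombe +0.5 correction is applied
#' to every cell and the result flagged.
#'
#' @param a,b,c,d cell counts, or pass a 2x2 matrix as `a`.
#' @param correct apply the +0.5 correction when a cell is zero.
#' @param level confidence level.
#' @return list with `or`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio_2x2(27, 4, 14, 48) # OR about 23.1
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           correct = FALSE, level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("counts must be nonnegative", call. = FALSE)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correct) {
      stop("zero cell: odds ratio undefined (set correct = TRUE for the ",
           "Haldane-Anscombe correction)", call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = unname(or),
       ci_low = unname(or * exp(-z * se)),
       ci_high = unname(or * exp(z * se)),
       corrected = corrected)
}
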