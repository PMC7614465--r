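#' Test results
#'
#' Light container for the t- and F-tests used throughout the pipeline.
#'
#' @param statistic test statistic.
#' @param p_value two-sided p-value.
#' @param df degrees of freedom.
#' @param n sample size(s).
#' @param method identifier of the procedure.
#' @param seed seed, when the procedure is randomized.
#' @return object of class `TestResult`.
#' @export
test_result <- function(statistic, p_value, df, n, method, seed = NA_integer_) {
  structure(list(statistic = statistic, p_value = p_value, df = df, n = n,
                 method = method, seed = seed), class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$df, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Student t-tests
#'
#' Classical two-sided Student t-tests: one-sample against `mu0`, two-sample
#' (pooled variance by default, Welch behind `welch = TRUE`), and paired.
#' Thin wrappers around [stats::t.test()] that return a [test_result()];
#' zero-variance inputs yield a degenerate result (`p = NA`,
#' `degenerate = TRUE` attribute) instead of an error.
#'
#' @param x,y numeric samples (paired inputs must have equal length).
#' @param mu0 null mean for the one-sample test.
#' @param welch use the Welch (unequal-variance) two-sample test.
#' @return a `TestResult`.
#' @export
t_test_one_sample <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) return(.degenerate("t_one_sample", length(x)))
  ht <- stats::t.test(x, mu = mu0)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              length(x), "t_one_sample")
}

#' @rdname t_test_one_sample
#' @export
t_test_two_sample <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(c(x, y)) == 0) {
    return(.degenerate("t_two_sample", c(length(x), length(y))))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              c(length(x), length(y)),
              if (welch) "t_two_sample_welch" else "t_two_sample_pooled")
}

#' @rdname t_test_one_sample
#' @export
t_test_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 2)
  if (stats::sd(x - y) == 0) {
    if (all(x == y)) {
      # identical samples: difference identically 0, no evidence against H0
      return(test_result(0, 1, length(x) - 1, length(x), "t_paired"))
    }
    return(.degenerate("t_paired", length(x)))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              length(x), "t_paired")
}

.degenerate <- function(method, n) {
  warning(sprintf("%s: zero-variance input, degenerate result", method))
  res <- test_result(NA_real_, NA_real_, NA_real_, n, method)
  attr(res, "degenerate") <- TRUE
  res
}

#' OLS linear trend with overall F-test
#'
#' Ordinary least squares of `y` on `x`; reports slope, intercept, R-squared
#' and the p-value of the overall F statistic.
#'
#' @param x predictor (e.g. timepoint in hours).
#' @param y response.
#' @return list with `slope`, `intercept`, `r_squared`, `test` (a
#'   `TestResult` with the F statistic).
#' @export
regression_f_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor: rank-deficient design",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  p <- stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]],
                 lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       test = test_result(unname(fs[["value"]]), p,
                          unname(fs[["dendf"]]), length(x), "ols_f"))
}
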