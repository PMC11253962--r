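#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SSE/SST} with \eqn{SSE = \sum_i (obs_i - pred_i)^2} and
#' \eqn{SST = \sum_i (obs_i - \bar{obs})^2}. Unbounded below: a fit worse
#' than the observed mean yields a negative value, which is reported
#' unclipped.
#'
#' @param observed,predicted equal-length numeric vectors, n >= 2.
#' @return A single number in \eqn{(-\infty, 1]}.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("R-squared is undefined: observed values are constant (SST = 0)",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' Root-mean-square error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum_i (obs_i - pred_i)^2}}.
#'
#' @param observed,predicted equal-length numeric vectors, n >= 1.
#' @return A single non-negative number in the units of the inputs.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4)) # sqrt(1/3)
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 1L)
  sqrt(mean((observed - predicted)^2))
}

#' Mean absolute percentage error
#'
#' \eqn{MAPE = \frac{100}{n}\sum_i |obs_i - pred_i| / |obs_i|}, in
#' percent. Observed values of exactly zero make the quantity undefined
#' and raise an error (no silent epsilon).
#'
#' @param observed,predicted equal-length numeric vectors, n >= 1; all
#'   `observed` must be non-zero.
#' @return A single non-negative percentage.
#' @examples
#' mape(c(2, 4), c(1, 5)) # 37.5
#' @export
mape <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 1L)
  if (any(observed == 0))
    stop("MAPE is undefined when any observed value is 0", call. = FALSE)
  100 * mean(abs(observed - predicted) / abs(observed))
}

check_pair <- function(observed, predicted, min_n) {
  if (!is.numeric(observed) || !is.numeric(predicted))
    stop("inputs must be numeric", call. = FALSE)
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (length(observed) < min_n)
    stop("need at least ", min_n, " observation(s)", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted))
    stop("inputs may not contain NA", call. = FALSE)
  invisible(TRUE)
}

#' Fit-quality report: R-squared, RMSE and MAPE together
#'
#' @param observed,predicted equal-length numeric vectors, n >= 2.
#' @return An object of class `"eval_report"`: list with `r2`, `rmse`,
#'   `mape` (percent) and `n`.
#' @export
eval_report <- function(observed, predicted) {
  structure(list(r2 = r_squared(observed, predicted),
                 rmse = rmse(observed, predicted),
                 mape = mape(observed, predicted),
                 n = length(observed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Fit over n = %d: R2 = %.*g, RMSE = %.*g, MAPE = %.*g%%\n",
              x$n, digits, x$r2, digits, x$rmse, digits, x$mape))
  invisible(x)
}
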