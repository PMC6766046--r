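#' Geometric mean and geometric standard deviation
#'
#' Multiplicative-scale location and spread for log-normally distributed
#' concentrations: \code{geometric_mean(x) = exp(mean(log x))} and
#' \code{geometric_sd(x) = exp(sd(log x))}.
#'
#' @param x numeric vector of strictly positive values.
#' @return A single numeric value.
#' @examples
#' geometric_mean(c(25, 100))  # 50
#' @export
geometric_mean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("geometric mean requires finite, strictly positive values")
  exp(mean(log(x)))
}

#' @rdname geometric_mean
#' @export
geometric_sd <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("geometric sd requires finite, strictly positive values")
  exp(stats::sd(log(x)))
}

# internal: fail with the caller-supplied message unless all values are
# finite, numeric and satisfy `ok`
check_num <- function(x, what, ok = function(v) TRUE, msg = "invalid value") {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  if (!all(ok(x)))
    stop(sprintf("'%s': %s", what, msg), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, what) {
  check_num(x, what, function(v) v >= 0, "must be non-negative")
}

check_pos <- function(x, what) {
  check_num(x, what, function(v) v > 0, "must be strictly positive")
}
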