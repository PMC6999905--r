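#' AR(1) variance and bias kernels for N-of-1 serial t-tests
#'
#' Under the working model \eqn{Y \sim N(X\beta, R\sigma^2)} with
#' \eqn{R_{jk} = \rho^{|j-k|}} (a first-order autoregressive correlation
#' matrix), the ordinary-least-squares estimate of the location parameter of
#' interest has variance \eqn{c(\rho)\sigma^2}, and the OLS residual variance
#' \eqn{s^2} has expectation \eqn{b(\rho)\sigma^2}. The effective sample size
#' \eqn{m'} re-expresses \eqn{b} as
#' \eqn{b = m(m'-p) / \{m'(m-p)\}} where \eqn{p} is the number of location
#' parameters per series (1 for a level-change design, 2 for rate-change).
#'
#' `c_level()`, `b_level()` and `m_prime_level()` are the kernels for an
#' intercept-only (level-change) design; `c_rate()`, `b_rate()` and
#' `m_prime_rate()` for an intercept-plus-slope (rate-change) design with the
#' centered time index \eqn{x = (1,\dots,m) - (m+1)/2}. All are closed-form
#' and O(1); [ar1_matrix_oracle()] evaluates the same quantities by dense
#' matrix algebra and exists for verification.
#'
#' @param m integer series length; at least 2 for level kernels, at least 3
#'   for rate kernels.
#' @param rho AR(1) lag-1 correlation, strictly inside (-1, 1). The formulas
#'   are singular at \eqn{\rho = 1}; estimated correlations are clamped to
#'   \eqn{|\rho| \le 0.999} upstream (see [fuller_r()]).
#' @return A positive scalar: the variance factor `c` (multiplies
#'   \eqn{\sigma^2}), the unitless bias factor `b`, or the effective sample
#'   size `m'` (in observations).
#' @examples
#' c_level(4, 0)          # 1/m when uncorrelated
#' m_prime_level(8, 0.5)  # fewer effective observations under positive rho
#' @seealso [ar1_kernel()] for the bundled triple, [ar1_matrix_oracle()].
#' @name ar1-kernels
NULL

check_kernel_args <- function(m, rho, min_m) {
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < min_m)
    stop("m must be a single integer >= ", min_m, call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop("rho must lie strictly inside (-1, 1)", call. = FALSE)
  invisible(TRUE)
}

#' @rdname ar1-kernels
#' @export
c_level <- function(m, rho) {
  check_kernel_args(m, rho, 2L)
  (m + 2 * rho^(m + 1) - m * rho^2 - 2 * rho) / (m^2 * (rho - 1)^2)
}

#' @rdname ar1-kernels
#' @export
b_level <- function(m, rho) {
  check_kernel_args(m, rho, 2L)
  m * (1 - c_level(m, rho)) / (m - 1)
}

#' @rdname ar1-kernels
#' @export
m_prime_level <- function(m, rho) {
  check_kernel_args(m, rho, 2L)
  m / (m - (m - 1) * b_level(m, rho))
}

#' @rdname ar1-kernels
#' @export
c_rate <- function(m, rho) {
  check_kernel_args(m, rho, 3L)
  12 / (m^2 - 1)^2 * (
    -6 * rho * (rho + 1)^2 * (rho^m - 1) / (m^2 * (rho - 1)^4) +
      2 * rho * (6 * rho^(m + 1) + 6 * rho^m + rho^2 - 2 * rho + 1) /
        (m * (rho - 1)^3) -
      6 * rho * (rho^m + 1) / (rho - 1)^2 -
      2 * m * rho / (rho - 1) +
      (m^2 - 1) / m
  )
}

#' @rdname ar1-kernels
#' @export
b_rate <- function(m, rho) {
  check_kernel_args(m, rho, 3L)
  (m - 1 -
     2 * rho * (rho^m - m * rho + m - 1) / (m * (rho - 1)^2) -
     m * (m^2 - 1) * c_rate(m, rho) / 12) / (m - 2)
}

#' @rdname ar1-kernels
#' @export
m_prime_rate <- function(m, rho) {
  check_kernel_args(m, rho, 3L)
  2 * m / (m - (m - 2) * b_rate(m, rho))
}

#' Bundle the AR(1) kernel triple for one series
#'
#' Convenience constructor returning `c`, `b` and `m'` for a series of length
#' `m` at correlation `rho` under the given change type, together with the
#' number of location parameters `p` (1 for level, 2 for rate).
#'
#' @inheritParams ar1-kernels
#' @param change_type `"level"` or `"rate"`.
#' @return A list of class `"ar1_kernel"` with elements `m`, `rho`,
#'   `change_type`, `c`, `b`, `m_prime`, `p`.
#' @export
ar1_kernel <- function(m, rho, change_type = c("level", "rate")) {
  change_type <- match.arg(change_type)
  out <- if (change_type == "level") {
    list(c = c_level(m, rho), b = b_level(m, rho),
         m_prime = m_prime_level(m, rho), p = 1L)
  } else {
    list(c = c_rate(m, rho), b = b_rate(m, rho),
         m_prime = m_prime_rate(m, rho), p = 2L)
  }
  structure(c(list(m = as.integer(m), rho = rho, change_type = change_type),
              out),
            class = "ar1_kernel")
}

#' Dense matrix-algebra oracle for the AR(1) kernels
#'
#' Builds \eqn{R_{jk} = \rho^{|j-k|}} explicitly and evaluates
#' \eqn{(X'X)^{-1}X'RX(X'X)^{-1}} (variance factor of the parameter of
#' interest) and \eqn{\{m - tr(P_X R)\}/\{m - p\}} (bias factor of
#' \eqn{s^2}) for the intercept-only or intercept-plus-centered-slope design.
#' O(m^2) storage; intended for verifying the closed-form kernels, not for
#' production use.
#'
#' @inheritParams ar1_kernel
#' @return A list with elements `c` and `b`.
#' @export
ar1_matrix_oracle <- function(m, rho, change_type = c("level", "rate")) {
  change_type <- match.arg(change_type)
  check_kernel_args(m, rho, if (change_type == "level") 2L else 3L)
  if (m > 200L) stop("oracle limited to m <= 200", call. = FALSE)
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  X <- if (change_type == "level") matrix(1, m, 1L)
       else cbind(1, seq_len(m) - (m + 1) / 2)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  V <- XtXi %*% crossprod(X, R %*% X) %*% XtXi
  P <- X %*% XtXi %*% t(X)
  list(c = V[p, p], b = (m - sum(diag(P %*% R))) / (m - p))
}

#' @export
print.ar1_kernel <- function(x, ...) {
  cat(sprintf(
    "AR(1) %s-change kernel: m = %d, rho = %.4f\n  c = %.6g  b = %.6g  m' = %.4f  (p = %d)\n",
    x$change_type, x$m, x$rho, x$c, x$b, x$m_prime, x$p))
  invisible(x)
}
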