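#' Residuals of an N-of-1 series from its fitted mean structure
#'
#' The serial correlation is estimated from OLS residuals, whose definition
#' depends on the design: level-change designs subtract the series mean;
#' rate-change designs subtract an intercept-plus-slope fit on the centered
#' time index \eqn{x = (1,\dots,m) - (m+1)/2}. Two-sample designs fit each
#' arm separately; this function handles one series, callers combine arms.
#'
#' @param values numeric vector, one equally spaced series (a treatment arm
#'   or within-pair A-B differences), oldest first.
#' @param change_type `"level"` or `"rate"`.
#' @return Numeric vector of residuals; their mean is zero by construction.
#' @export
serial_residuals <- function(values, change_type = c("level", "rate")) {
  change_type <- match.arg(change_type)
  values <- check_series(values)
  m <- length(values)
  if (change_type == "level") {
    if (m < 2L) stop("insufficient observations: need at least 2", call. = FALSE)
    values - mean(values)
  } else {
    if (m < 3L) stop("insufficient observations: need at least 3 to detrend",
                     call. = FALSE)
    x <- seq_len(m) - (m + 1) / 2
    beta <- sum(x * values) / sum(x^2)   # x is centered, so slope decouples
    values - mean(values) - beta * x
  }
}

#' Lag-1 serial correlation: simplified MLE from residuals
#'
#' Because the residuals sum to zero, the maximum-likelihood estimator of the
#' AR(1) parameter reduces to the ratio of the lag-1 cross-product sum to the
#' full sum of squares:
#' \eqn{\hat\rho = \sum_{j=2}^m e_j e_{j-1} / \sum_{j=1}^m e_j^2}.
#'
#' @param e numeric vector of residuals (see [serial_residuals()]).
#' @return The estimate \eqn{\hat\rho}.
#' @export
rho_hat_mle <- function(e) {
  e <- check_series(e)
  m <- length(e)
  if (m < 2L) stop("insufficient observations", call. = FALSE)
  ss <- sum(e^2)
  if (ss <= 0)
    stop("zero residual variance: serial correlation (and the t-statistic) is undefined",
         call. = FALSE)
  sum(e[-1] * e[-m]) / ss
}

#' Fuller's bias-corrected serial correlation estimate
#'
#' The simplified MLE \eqn{\hat\rho} is biased by roughly \eqn{-2\rho/(m-1)}
#' in short series. Fuller's small-sample correction
#' \eqn{r = \hat\rho + (1-\hat\rho^2)/(m-1)} removes most of that bias and is
#' the estimator recommended for series of ten or fewer observations. The
#' result is clamped to \eqn{[-0.999, 0.999]} so the downstream kernels (which
#' are singular at \eqn{\rho = 1}) stay finite; clamping is flagged.
#'
#' @param rho_hat uncorrected estimate, in \eqn{[-1, 1]}.
#' @param m series length used in the estimate; at least 3.
#' @return A list of class `"serial_r"`: `rho_hat`, `r` (corrected, clamped),
#'   `m`, `clamped`.
#' @examples
#' fuller_r(0, 5)$r  # 0.25: the pure correction term
#' @export
fuller_r <- function(rho_hat, m) {
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 3L)
    stop("too few observations for correlation estimation (need m >= 3)",
         call. = FALSE)
  if (!is.numeric(rho_hat) || length(rho_hat) != 1L || !is.finite(rho_hat) ||
      abs(rho_hat) > 1)
    stop("rho_hat must lie in [-1, 1]", call. = FALSE)
  r <- rho_hat + (1 - rho_hat^2) / (m - 1)
  clamped <- abs(r) > 0.999
  structure(list(rho_hat = rho_hat,
                 r = max(-0.999, min(0.999, r)),
                 m = as.integer(m),
                 clamped = clamped),
            class = "serial_r")
}

#' Length-weighted pooled serial correlation for 2-sample designs
#'
#' The 2-sample tests estimate one correlation per arm and combine them as
#' \eqn{\bar r = (m_A r_A + m_B r_B) / (m_A + m_B)}; the kernels for both
#' arms are then evaluated at the common \eqn{\bar r}.
#'
#' @param r_a,r_b per-arm Fuller estimates.
#' @param m_a,m_b per-arm series lengths.
#' @return The pooled estimate.
#' @export
pooled_r <- function(r_a, m_a, r_b, m_b) {
  (m_a * r_a + m_b * r_b) / (m_a + m_b)
}

#' End-to-end serial correlation estimate for one series
#'
#' Residual construction, simplified MLE and Fuller correction in one call.
#'
#' @inheritParams serial_residuals
#' @return As [fuller_r()].
#' @export
estimate_serial_r <- function(values, change_type = c("level", "rate")) {
  e <- serial_residuals(values, change_type)
  fuller_r(rho_hat_mle(e), length(e))
}

#' @export
print.serial_r <- function(x, ...) {
  cat(sprintf("serial correlation (m = %d): rho_hat = %.4f, Fuller r = %.4f%s\n",
              x$m, x$rho_hat, x$r, if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

# shared input validation: finite, numeric, no NA
check_series <- function(values) {
  if (!is.numeric(values))
    stop("series values must be numeric", call. = FALSE)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite observations are not supported; ",
         "series must be complete and equally spaced", call. = FALSE)
  values
}
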