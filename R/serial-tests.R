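#' Serial t-tests for N-of-1 trials
#'
#' Four t-tests comparing two treatments within a single individual while
#' accounting for AR(1) serial correlation in the repeated observations:
#'
#' * `paired_serial_level(d)` — level-change on a series of within-pair
#'   A-B differences (multiple-crossover designs); minimum 4 pairs.
#' * `two_sample_serial_level(a, b)` — level-change between two independent
#'   series (bi-phase "AB", pre-post designs); each arm at least 3 and
#'   at least 7 observations in total.
#' * `paired_serial_rate(d)` — rate-change (difference in linear time
#'   trends) on a difference series; minimum 5 pairs.
#' * `two_sample_serial_rate(a, b)` — rate-change between two independent
#'   series; each arm at least 4 and at least 9 in total.
#'
#' Each test replaces the unknown serial correlation with the Fuller
#' bias-corrected estimate from the design's own residuals (pooled across
#' arms, weighted by length, for the 2-sample tests), evaluates the AR(1)
#' kernels \eqn{c(\rho)} and \eqn{b(\rho)} at that estimate, and refers
#' \deqn{t = \hat\beta \Big/ \sqrt{c(r)\, s^2 / b(r)}}
#' to a Student-t distribution with fractional degrees of freedom
#' \eqn{m' - p} (summed over arms, minus \eqn{2p}, for 2-sample tests).
#' Positive serial correlation shrinks the effective sample size \eqn{m'}
#' and inflates the standard error, tempering the inference relative to the
#' classical tests (see [usual_paired_level()] and friends).
#'
#' When estimated correlation is extreme at very small `m` the fractional
#' degrees of freedom can drop below 1; the result is still computed (the
#' t distribution is defined for any df > 0) and flagged via `df_lt_1`.
#'
#' @param d numeric vector of within-pair differences (A minus B), in time
#'   order.
#' @param a,b numeric vectors: the two arms' series, in time order.
#' @param ci_level confidence level for the interval, default 0.95.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   direction refers to the estimate (mean difference, or difference in
#'   slopes, first argument minus second).
#' @param rho optional known serial correlation. `NULL` (default) estimates
#'   it from the residuals; a number bypasses estimation (e.g. `rho = 0`
#'   reproduces the classical test exactly, and simulation studies use the
#'   true value).
#' @return An object of class `"serial_ttest"`: a list with the estimate,
#'   `s2` (OLS residual variance), `se`, `r_used` and the full correlation
#'   estimate(s), per-arm kernels, fractional `df`, `statistic`,
#'   `p.value` (for the requested alternative), `p_one_sided`,
#'   `p_two_sided`, `conf.int`, and bookkeeping fields.
#' @examples
#' set.seed(1)
#' d <- rnorm(6) + 0.8
#' paired_serial_level(d, alternative = "greater")
#' @name serial-tests
NULL

#' @rdname serial-tests
#' @export
paired_serial_level <- function(d, ci_level = 0.95,
                                alternative = c("two.sided", "greater", "less"),
                                rho = NULL) {
  d <- check_series(d)
  if (length(d) < 4L)
    stop("minimum m is 4 for the paired serial t-test for level-change",
         call. = FALSE)
  serial_engine("paired_level", d, NULL, rho, ci_level, match.arg(alternative),
                method = "serial")
}

#' @rdname serial-tests
#' @export
two_sample_serial_level <- function(a, b, ci_level = 0.95,
                                    alternative = c("two.sided", "greater", "less"),
                                    rho = NULL) {
  a <- check_series(a); b <- check_series(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each arm needs at least 3 observations for the 2-sample serial t-test for level-change",
         call. = FALSE)
  if (length(a) + length(b) < 7L)
    stop("the 2-sample serial t-test for level-change requires m_A + m_B >= 7",
         call. = FALSE)
  serial_engine("two_sample_level", a, b, rho, ci_level, match.arg(alternative),
                method = "serial")
}

#' @rdname serial-tests
#' @export
paired_serial_rate <- function(d, ci_level = 0.95,
                               alternative = c("two.sided", "greater", "less"),
                               rho = NULL) {
  d <- check_series(d)
  if (length(d) < 5L)
    stop("minimum m is 5 for the paired serial t-test for rate-change",
         call. = FALSE)
  serial_engine("paired_rate", d, NULL, rho, ci_level, match.arg(alternative),
                method = "serial")
}

#' @rdname serial-tests
#' @export
two_sample_serial_rate <- function(a, b, ci_level = 0.95,
                                   alternative = c("two.sided", "greater", "less"),
                                   rho = NULL) {
  a <- check_series(a); b <- check_series(b)
  if (length(a) < 4L || length(b) < 4L)
    stop("each arm needs at least 4 observations for the 2-sample serial t-test for rate-change",
         call. = FALSE)
  if (length(a) + length(b) < 9L)
    stop("the 2-sample serial t-test for rate-change requires m_A + m_B >= 9",
         call. = FALSE)
  serial_engine("two_sample_rate", a, b, rho, ci_level, match.arg(alternative),
                method = "serial")
}

#' Classical t-test analogues of the serial tests
#'
#' The usual tests that ignore serial correlation, with the same signatures
#' and result container as their serial counterparts: one-sample t
#' (paired level), pooled two-sample t (2-sample level), simple-regression
#' slope t (paired rate), and difference-of-slopes t with a pooled residual
#' variance (2-sample rate). Each equals the corresponding serial test with
#' the correlation fixed at zero; degrees of freedom are the usual integers.
#'
#' @inheritParams serial-tests
#' @return An object of class `"serial_ttest"` with `method = "usual"` and
#'   `r_used = NA`.
#' @name usual-tests
NULL

#' @rdname usual-tests
#' @export
usual_paired_level <- function(d, ci_level = 0.95,
                               alternative = c("two.sided", "greater", "less")) {
  d <- check_series(d)
  if (length(d) < 2L) stop("minimum m is 2", call. = FALSE)
  serial_engine("paired_level", d, NULL, 0, ci_level, match.arg(alternative),
                method = "usual")
}

#' @rdname usual-tests
#' @export
usual_two_sample_level <- function(a, b, ci_level = 0.95,
                                   alternative = c("two.sided", "greater", "less")) {
  a <- check_series(a); b <- check_series(b)
  if (length(a) < 2L || length(b) < 2L || length(a) + length(b) < 4L)
    stop("each arm needs at least 2 observations", call. = FALSE)
  serial_engine("two_sample_level", a, b, 0, ci_level, match.arg(alternative),
                method = "usual")
}

#' @rdname usual-tests
#' @export
usual_paired_rate <- function(d, ci_level = 0.95,
                              alternative = c("two.sided", "greater", "less")) {
  d <- check_series(d)
  if (length(d) < 3L) stop("minimum m is 3", call. = FALSE)
  serial_engine("paired_rate", d, NULL, 0, ci_level, match.arg(alternative),
                method = "usual")
}

#' @rdname usual-tests
#' @export
usual_two_sample_rate <- function(a, b, ci_level = 0.95,
                                  alternative = c("two.sided", "greater", "less")) {
  a <- check_series(a); b <- check_series(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each arm needs at least 3 observations", call. = FALSE)
  serial_engine("two_sample_rate", a, b, 0, ci_level, match.arg(alternative),
                method = "usual")
}

# ---- engine ----------------------------------------------------------------

# slope of y on the centered index x = (1..m) - (m+1)/2 and its residuals
centered_fit <- function(y) {
  m <- length(y)
  x <- seq_len(m) - (m + 1) / 2
  beta <- sum(x * y) / sum(x^2)
  list(beta = beta, resid = y - mean(y) - beta * x, x = x)
}

serial_engine <- function(design, a, b, rho, ci_level, alternative, method) {
  change <- if (grepl("level", design)) "level" else "rate"
  paired <- grepl("paired", design)
  p <- if (change == "level") 1L else 2L
  m_a <- length(a)

  if (paired) {
    if (change == "level") {
      estimate <- mean(a)
      e <- a - estimate
      s2 <- sum(e^2) / (m_a - 1)
    } else {
      fit <- centered_fit(a)
      estimate <- fit$beta
      e <- fit$resid
      s2 <- sum(e^2) / (m_a - 2)
    }
    if (s2 <= 0)
      stop("zero residual variance: the t-statistic is undefined", call. = FALSE)
    r_est <- if (is.null(rho)) fuller_r(rho_hat_mle(e), m_a) else NULL
    r_used <- if (is.null(rho)) r_est$r else rho
    k <- ar1_kernel(m_a, r_used, change)
    se <- sqrt(k$c * s2 / k$b)
    df <- k$m_prime - p
    kernels <- list(k)
    m <- m_a
    r_details <- r_est
  } else {
    m_b <- length(b)
    if (change == "level") {
      est_a <- mean(a); est_b <- mean(b)
      e_a <- a - est_a; e_b <- b - est_b
      estimate <- est_a - est_b
      s2 <- (sum(e_a^2) + sum(e_b^2)) / (m_a + m_b - 2)
    } else {
      fit_a <- centered_fit(a); fit_b <- centered_fit(b)
      e_a <- fit_a$resid; e_b <- fit_b$resid
      estimate <- fit_a$beta - fit_b$beta
      s2 <- (sum(e_a^2) + sum(e_b^2)) / (m_a + m_b - 4)
    }
    if (s2 <= 0)
      stop("zero residual variance: the t-statistic is undefined", call. = FALSE)
    if (is.null(rho)) {
      r_a <- fuller_r(rho_hat_mle(e_a), m_a)
      r_b <- fuller_r(rho_hat_mle(e_b), m_b)
      r_used <- pooled_r(r_a$r, m_a, r_b$r, m_b)
      r_details <- list(A = r_a, B = r_b)
    } else {
      r_used <- rho
      r_details <- NULL
    }
    k_a <- ar1_kernel(m_a, r_used, change)
    k_b <- ar1_kernel(m_b, r_used, change)
    se <- sqrt(s2 * (k_a$c / k_a$b + k_b$c / k_b$b))
    df <- k_a$m_prime + k_b$m_prime - 2 * p
    kernels <- list(A = k_a, B = k_b)
    m <- c(m_a, m_b)
  }

  if (!is.finite(df) || df <= 0)
    stop("effective sample size too small at the estimated correlation; ",
         "collect more observations", call. = FALSE)

  stat <- estimate / se
  inf <- t_p_ci(stat, df, alternative, ci_level, estimate, se)

  structure(list(design = design, method = method,
                 estimate = estimate, s2 = s2, s = sqrt(s2),
                 r_used = if (method == "usual") NA_real_ else r_used,
                 r_details = if (method == "usual") NULL else r_details,
                 kernels = kernels, m = m, df = df,
                 statistic = stat, se = se,
                 p.value = inf$p.value,
                 p_one_sided = inf$p_one_sided,
                 p_two_sided = inf$p_two_sided,
                 alternative = alternative, ci_level = ci_level,
                 conf.int = inf$conf.int,
                 df_lt_1 = df < 1),
            class = "serial_ttest")
}

#' Student-t tail probabilities and confidence interval at fractional df
#'
#' Shared inference plumbing for the serial tests: one- and two-sided
#' p-values and the central confidence interval
#' \eqn{\hat\beta \pm t_{df,\,\alpha/2}\, SE}, with real-valued degrees of
#' freedom.
#'
#' @param statistic observed t value.
#' @param df degrees of freedom, any positive real.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param ci_level confidence level in (0, 1).
#' @param estimate,se point estimate and its standard error.
#' @return A list: `p.value` (for the requested alternative),
#'   `p_one_sided` (tail in the requested — or, for two-sided, the
#'   observed — direction), `p_two_sided`, `conf.int` (length-2 vector).
#' @export
t_p_ci <- function(statistic, df, alternative = "two.sided", ci_level = 0.95,
                   estimate = NA_real_, se = NA_real_) {
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0)
    stop("df must be a positive real", call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  upper <- stats::pt(statistic, df, lower.tail = FALSE)
  lower <- stats::pt(statistic, df, lower.tail = TRUE)
  p_two <- 2 * min(upper, lower)
  p_one <- switch(alternative,
                  greater = upper,
                  less = lower,
                  two.sided = min(upper, lower))
  q <- stats::qt(1 - (1 - ci_level) / 2, df)
  list(p.value = if (alternative == "two.sided") p_two else p_one,
       p_one_sided = p_one,
       p_two_sided = p_two,
       conf.int = c(estimate - q * se, estimate + q * se))
}

#' Bonferroni screen for any change between two independent series
#'
#' Runs the 2-sample (or, with `paired = TRUE` on equal-length arms, the
#' paired) serial t-tests for both level- and rate-change, each at level
#' `alpha / 2`, and reports which — if either — is significant. A patient is
#' classified as "changed" if either test rejects, keeping the familywise
#' error at `alpha`.
#'
#' @inheritParams serial-tests
#' @param alpha overall two-sided significance level, default 0.05.
#' @param paired analyze within-pair differences `a - b` instead of two
#'   independent arms.
#' @return A list: `level` and `rate` (the two `"serial_ttest"` results),
#'   logical flags `level_change`, `rate_change`, `any_change`, and `alpha`.
#' @export
screen_change <- function(a, b, alpha = 0.05, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b))
      stop("paired screening needs equal-length arms", call. = FALSE)
    d <- a - b
    lev <- paired_serial_level(d)
    rat <- paired_serial_rate(d)
  } else {
    lev <- two_sample_serial_level(a, b)
    rat <- two_sample_serial_rate(a, b)
  }
  list(level = lev, rate = rat,
       level_change = lev$p_two_sided <= alpha / 2,
       rate_change = rat$p_two_sided <= alpha / 2,
       any_change = lev$p_two_sided <= alpha / 2 || rat$p_two_sided <= alpha / 2,
       alpha = alpha)
}

#' @export
print.serial_ttest <- function(x, digits = 3, ...) {
  lab <- c(paired_level = "Paired t-test for level-change",
           two_sample_level = "2-sample t-test for level-change",
           paired_rate = "Paired t-test for rate-change",
           two_sample_rate = "2-sample t-test for rate-change")[[x$design]]
  cat(sprintf("%s (%s)\n", lab,
              if (x$method == "serial") "serial: AR(1)-adjusted" else "usual"))
  cat(sprintf("  m = %s   estimate = %.*f   s = %.*f\n",
              paste(x$m, collapse = " + "), digits, x$estimate, digits, x$s))
  if (x$method == "serial")
    cat(sprintf("  serial correlation r = %.*f   effective df = %.2f%s\n",
                digits, x$r_used, x$df,
                if (isTRUE(x$df_lt_1)) "  [df < 1: interpret with caution]" else ""))
  else
    cat(sprintf("  df = %g\n", x$df))
  cat(sprintf("  t = %.*f   p = %.4g (%s)\n",
              digits, x$statistic, x$p.value, x$alternative))
  cat(sprintf("  %g%% CI: [%.*f, %.*f]\n", 100 * x$ci_level,
              digits, x$conf.int[1], digits, x$conf.int[2]))
  invisible(x)
}
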