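#' Study-planning calculators for N-of-1 serial t-tests
#'
#' Before running an N-of-1 trial, two questions decide how many crossovers
#' (or observations per arm) to collect: how wide will the confidence
#' interval be, and how large an effect is detectable at a given power?
#' Both depend on the planned length `m`, an assumed serial correlation
#' `rho`, and the design.
#'
#' `expected_margin()` returns the plug-in half-width of a
#' \eqn{(1-\alpha)100\%} confidence interval,
#' \eqn{t_{DF,\alpha/2}\sqrt{c(\rho)\sigma^2 / b(\rho)}} (for 2-sample
#' designs the variance term is \eqn{\sigma^2(c_A/b_A + c_B/b_B)}), with the
#' fractional degrees of freedom implied by `rho`. It does not account for
#' the sampling variability of \eqn{s} or of the estimated correlation;
#' [run_margin_factor_experiment()] quantifies how much realized margins
#' deviate from this plug-in value.
#'
#' `detectable_effect_size()` maps the design onto an equivalent one-sample
#' t-test calculator: set the calculator's sample size
#' \eqn{m_{(C)} = DF + 1} (fractional), solve its noncentral-t power
#' equation for \eqn{\delta_{(C)}}, and convert back via
#' \eqn{\delta = \delta_{(C)}\sqrt{m_{(C)}\, c(\rho)}} (with
#' \eqn{c = c_A + c_B} for 2-sample designs). The returned \eqn{\delta} is in
#' \eqn{\sigma} units.
#'
#' @param design one of `"paired_level"`, `"two_sample_level"`,
#'   `"paired_rate"`, `"two_sample_rate"`.
#' @param m planned series length (number of pairs, or per-arm length when
#'   `m_a`/`m_b` are not given separately).
#' @param rho assumed serial correlation in (-1, 1).
#' @param alpha significance level. For `expected_margin()` this is the
#'   two-sided CI complement (0.10 gives a 90% interval, i.e. a 95%
#'   one-sided confidence limit); for `detectable_effect_size()` it is the
#'   test's level on the scale set by `sided`.
#' @param sigma2 assumed observation variance, default 1 (so margins are in
#'   \eqn{\sigma} units).
#' @param m_a,m_b per-arm lengths for unbalanced 2-sample designs; default
#'   both equal `m`.
#' @param power target power in (0, 1), default 0.8.
#' @param sided `"one"` (default, matching the convention that a 90% CI
#'   corresponds to a one-sided 0.05 test) or `"two"`.
#' @return A list of class `"nof1_planning"`: `design`, `m` (or per-arm
#'   lengths), `rho`, `df`, and `margin` (sigma units) or `delta`,
#'   `delta_C`, `m_C`.
#' @examples
#' expected_margin("paired_level", m = 8, rho = 0.4)
#' detectable_effect_size("paired_level", m = 8, rho = 0.4)
#' @name planning
NULL

planning_designs <- c("paired_level", "two_sample_level",
                      "paired_rate", "two_sample_rate")

# per-design kernel summary used by both calculators:
#   var_factor: Var(estimate)/sigma^2-with-bias-correction, i.e. c/b summed
#   c_eff:      c (paired) or c_A + c_B (2-sample), for the noncentrality map
#   df:         fractional degrees of freedom
design_kernels <- function(design, m, rho, m_a = NULL, m_b = NULL) {
  design <- match.arg(design, planning_designs)
  change <- if (grepl("level", design)) "level" else "rate"
  p <- if (change == "level") 1L else 2L
  if (grepl("paired", design)) {
    k <- ar1_kernel(m, rho, change)
    list(var_factor = k$c / k$b, c_eff = k$c, df = k$m_prime - p,
         m = m, change = change, p = p)
  } else {
    if (is.null(m_a)) m_a <- m
    if (is.null(m_b)) m_b <- m
    k_a <- ar1_kernel(m_a, rho, change)
    k_b <- ar1_kernel(m_b, rho, change)
    list(var_factor = k_a$c / k_a$b + k_b$c / k_b$b,
         c_eff = k_a$c + k_b$c,
         df = k_a$m_prime + k_b$m_prime - 2 * p,
         m = c(m_a, m_b), change = change, p = p)
  }
}

#' @rdname planning
#' @export
expected_margin <- function(design, m, rho, alpha = 0.10, sigma2 = 1,
                            m_a = NULL, m_b = NULL) {
  dk <- design_kernels(design, m, rho, m_a, m_b)
  if (!is.finite(dk$df) || dk$df <= 0)
    stop("design infeasible at this rho/m: non-positive degrees of freedom",
         call. = FALSE)
  margin <- stats::qt(1 - alpha / 2, dk$df) * sqrt(dk$var_factor * sigma2)
  structure(list(design = design, m = dk$m, rho = rho, alpha = alpha,
                 sigma2 = sigma2, df = dk$df, margin = margin),
            class = "nof1_planning")
}

# power of a one-sample t-test with (possibly fractional) sample size m_C
# at effect delta_C (sigma units); ncp = delta_C * sqrt(m_C)
one_sample_t_power <- function(delta_C, m_C, alpha, sided) {
  df <- m_C - 1
  ncp <- delta_C * sqrt(m_C)
  if (sided == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    q <- stats::qt(1 - alpha / 2, df)
    stats::pt(q, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-q, df, ncp = ncp)
  }
}

#' @rdname planning
#' @export
detectable_effect_size <- function(design, m, rho, power = 0.8, alpha = 0.05,
                                   sided = c("one", "two"),
                                   m_a = NULL, m_b = NULL) {
  sided <- match.arg(sided)
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop("power must be in (0, 1)", call. = FALSE)
  dk <- design_kernels(design, m, rho, m_a, m_b)
  if (!is.finite(dk$df) || dk$df <= 0)
    stop("design infeasible at this rho/m: non-positive degrees of freedom",
         call. = FALSE)
  m_C <- dk$df + 1
  f <- function(dC) one_sample_t_power(dC, m_C, alpha, sided) - power
  if (f(1e4) < 0) stop("unattainable power", call. = FALSE)
  delta_C <- stats::uniroot(f, c(1e-8, 1e4), tol = 1e-10)$root
  structure(list(design = design, m = dk$m, rho = rho, alpha = alpha,
                 power = power, sided = sided, df = dk$df,
                 m_C = m_C, delta_C = delta_C,
                 delta = delta_C * sqrt(m_C * dk$c_eff)),
            class = "nof1_planning")
}

#' Planning grids over m and rho
#'
#' Tabulates [expected_margin()] or [detectable_effect_size()] over a grid,
#' the layout used when planning a trial: one row per assumed correlation,
#' one column per candidate length. Infeasible cells are `NA`.
#'
#' @inheritParams planning
#' @param m_values integer vector of candidate lengths (columns).
#' @param rho_values numeric vector of assumed correlations (rows).
#' @param mode `"margin"` or `"delta"`.
#' @param digits round for display (half away from zero); `NULL` for full
#'   precision.
#' @return A numeric matrix with `rho_values` as rownames and `m_values`
#'   as colnames.
#' @examples
#' planning_table("paired_level", m_values = 4:8, rho_values = c(0, 0.4))
#' @export
planning_table <- function(design, m_values = 4:12,
                           rho_values = c(0, 0.2, 0.4, 0.6, 0.8),
                           mode = c("margin", "delta"),
                           alpha = NULL, power = 0.8,
                           sided = "one", sigma2 = 1, digits = 2) {
  mode <- match.arg(mode)
  if (is.null(alpha)) alpha <- if (mode == "margin") 0.10 else 0.05
  cell <- function(rho, m) {
    tryCatch(
      if (mode == "margin")
        expected_margin(design, m, rho, alpha, sigma2)$margin
      else
        detectable_effect_size(design, m, rho, power, alpha, sided)$delta,
      error = function(e) NA_real_)
  }
  out <- outer(rho_values, m_values, Vectorize(cell))
  dimnames(out) <- list(rho = format(rho_values), m = format(m_values))
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

# round half away from zero, matching hand-formatted tables
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @export
print.nof1_planning <- function(x, ...) {
  cat(sprintf("N-of-1 planning: %s, m = %s, assumed rho = %g\n",
              x$design, paste(x$m, collapse = " + "), x$rho))
  if (!is.null(x$margin))
    cat(sprintf("  expected %g%% CI margin of error: %.4g sigma (df = %.2f)\n",
                100 * (1 - x$alpha), x$margin, x$df))
  else
    cat(sprintf("  detectable effect at power %.2f (%s-sided alpha %.3g): %.4g sigma (df = %.2f)\n",
                x$power, x$sided, x$alpha, x$delta, x$df))
  invisible(x)
}
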