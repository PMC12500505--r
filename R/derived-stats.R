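# Derived statistics: N2O yields, substrate fractions, error-propagated
# rate ratios, and treatment comparisons.

#' Convert molar urea concentration to nitrogen units
#'
#' Urea carries two N atoms, so concentrations in umol urea L-1 are doubled
#' for comparison with ammonium.
#'
#' @param urea_molar Concentration(s) in umol urea L-1, >= 0.
#' @return Concentration(s) in umol N L-1.
#' @export
urea_to_N <- function(urea_molar) {
  if (!is.numeric(urea_molar) || any(!is.finite(urea_molar))) {
    stop("`urea_molar` must be finite numeric", call. = FALSE)
  }
  if (any(urea_molar < 0)) stop("urea concentrations must be >= 0", call. = FALSE)
  2 * urea_molar
}

#' Fraction of urea in the combined ammonium + urea pool
#'
#' @param urea_N Urea concentration in umol N L-1 (>= 0); vectorised.
#' @param nh4 Ammonium concentration in umol L-1 (>= 0); vectorised.
#' @return `urea_N / (urea_N + nh4)`.
#' @export
substrate_fraction <- function(urea_N, nh4) {
  if (any(urea_N < 0) || any(nh4 < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  total <- urea_N + nh4
  if (any(total <= 0)) {
    stop("total substrate pool is zero; fraction undefined", call. = FALSE)
  }
  urea_N / total
}

#' N2O yield of nitrogen oxidation
#'
#' The percentage of oxidised nitrogen emitted as N2O:
#' `100 * n2o / (n2o + no2)`. Both rates must be on the same nitrogen-atom
#' basis (a rate in nmol N2O L-1 d-1 is doubled first; see
#' [yield_from_estimates()]). Uncertainty is first-order (delta-method)
#' propagation from the input standard errors.
#'
#' @param n2o N2O production rate, nmol N L-1 d-1 (N-atom basis).
#' @param no2 Nitrite production rate, nmol N L-1 d-1.
#' @param n2o_se,no2_se Standard errors of the two rates (default 0).
#' @return A `yield_estimate` with fields `percent` and `se`.
#' @export
#' @examples
#' n2o_yield(0.0019, 0.9981) # 0.19 percent
n2o_yield <- function(n2o, no2, n2o_se = 0, no2_se = 0) {
  total <- n2o + no2
  if (!is.finite(total) || total <= 0) {
    stop("n2o + no2 must be > 0; yield undefined", call. = FALSE)
  }
  percent <- 100 * n2o / total
  se <- 100 * sqrt((no2 * n2o_se)^2 + (n2o * no2_se)^2) / total^2
  structure(list(percent = percent, se = se), class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf("<yield_estimate> %.3g +/- %.2g %%\n", x$percent, x$se))
  invisible(x)
}

#' N2O yield from a pair of rate estimates
#'
#' Convenience wrapper around [n2o_yield()] that takes the `rate_estimate`
#' objects produced by [n2o_production_rate()] and
#' [nitrite_production_rate()] and handles the unit basis: on the `"N"`
#' basis (default) the N2O rate and its SE are doubled from nmol N2O to
#' nmol N before forming the yield; `"molecule"` uses the rates as reported.
#'
#' @param n2o_est `rate_estimate` for N2O production (nmol N2O L-1 d-1).
#' @param no2_est `rate_estimate` for nitrite production (nmol N L-1 d-1).
#' @param basis `"N"` or `"molecule"`.
#' @return A `yield_estimate`.
#' @export
yield_from_estimates <- function(n2o_est, no2_est, basis = c("N", "molecule")) {
  basis <- match.arg(basis)
  k <- if (basis == "N") 2 else 1
  n2o_yield(k * n2o_est$value, no2_est$value,
            n2o_se = k * n2o_est$se, no2_se = no2_est$se)
}

as_value_se <- function(x, what) {
  if (inherits(x, "rate_estimate")) {
    list(value = x$value, se = x$se,
         below_dl = isTRUE(x$below_detection))
  } else if (is.list(x) && all(c("value", "se") %in% names(x))) {
    list(value = x$value, se = x$se, below_dl = isTRUE(x$below_detection))
  } else {
    stop("`", what, "` must be a rate_estimate or a list(value =, se =)",
         call. = FALSE)
  }
}

#' Ratio of two rate estimates with propagated uncertainty
#'
#' `value = numer / denom` with the standard quotient propagation rule
#' `sigma = |value| * sqrt((se_n/n)^2 + (se_d/d)^2)`. A zero numerator gives
#' `value = 0` with `sigma = se_n / |denom|`. Below-detection flags of both
#' inputs are carried through.
#'
#' @param numer,denom `rate_estimate` objects (or lists with `value`, `se`).
#' @return A `ratio_estimate` with fields `value`, `sigma`,
#'   `numerator_below_dl`, `denominator_below_dl`.
#' @export
#' @examples
#' a <- list(value = 2, se = 0.2); b <- list(value = 4, se = 0.4)
#' rate_ratio(a, b) # 0.5 +/- 0.0707
rate_ratio <- function(numer, denom) {
  nn <- as_value_se(numer, "numer")
  dd <- as_value_se(denom, "denom")
  if (dd$value == 0) stop("denominator rate is zero; ratio undefined",
                          call. = FALSE)
  if (nn$value == 0) {
    value <- 0
    sigma <- nn$se / abs(dd$value)
  } else {
    value <- nn$value / dd$value
    sigma <- abs(value) * sqrt((nn$se / nn$value)^2 + (dd$se / dd$value)^2)
  }
  structure(
    list(value = value, sigma = sigma,
         numerator_below_dl = nn$below_dl,
         denominator_below_dl = dd$below_dl),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  flags <- c(if (x$numerator_below_dl) "numerator < DL",
             if (x$denominator_below_dl) "denominator < DL")
  cat(sprintf("<ratio_estimate> %.4g +/- %.3g%s\n", x$value, x$sigma,
              if (length(flags)) paste0(" (", paste(flags, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Compare two rate estimates between treatments
#'
#' Two-sample t-test on the fitted slope estimates using their regression
#' standard errors, with Welch-Satterthwaite degrees of freedom. The percent
#' change is expressed relative to `b` (conventionally the in-situ,
#' untreated estimate), so inhibition appears as a negative change.
#'
#' @param a,b `rate_estimate` objects with finite `se` and `df`.
#' @return A list of class `treatment_comparison` with fields `t_statistic`,
#'   `df`, `p_value`, `percent_change`.
#' @export
compare_treatments <- function(a, b) {
  for (x in list(a, b)) {
    if (!inherits(x, "rate_estimate")) {
      stop("inputs must be rate_estimate objects", call. = FALSE)
    }
    if (!is.finite(x$se) || !is.finite(x$df) || x$df < 1) {
      stop("both estimates need a finite standard error and degrees of freedom",
           call. = FALSE)
    }
  }
  se2 <- a$se^2 + b$se^2
  if (se2 == 0) {
    tstat <- 0
    df <- a$df + b$df
  } else {
    tstat <- (a$value - b$value) / sqrt(se2)
    df <- se2^2 / (a$se^4 / a$df + b$se^4 / b$df)
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(
    list(t_statistic = tstat, df = df, p_value = p,
         percent_change = 100 * (a$value - b$value) / b$value),
    class = "treatment_comparison"
  )
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("<treatment_comparison> change %.1f %% (t = %.2f, df = %.1f, p = %.3g)\n",
              x$percent_change, x$t_statistic, x$df, x$p_value))
  invisible(x)
}
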