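# Cross-site substrate-ratio correlation framework: log-log fits of
# oxidation-rate ratios on concentration ratios, robust fits with 2-SD
# outlier flagging, subgroup fits and prediction.

site_habitats <- c("estuary", "coastal", "open_ocean", "polar", "omz")

sites_required_cols <- c("region", "station", "depth_m", "habitat", "nh4_uM",
                         "ureaN_uM", "nh4_ox", "urea_ox", "nh4_ox_below_dl",
                         "urea_ox_below_dl")

validate_sites <- function(sites) {
  missing_cols <- setdiff(sites_required_cols, names(sites))
  if (length(missing_cols)) {
    stop("sites table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(sites$habitat), site_habitats)
  if (length(bad)) {
    stop("unknown habitat value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(sites)
}

#' Which site records can enter a ratio fit?
#'
#' A record is ratio-eligible when both substrate concentrations and both
#' oxidation rates are finite and strictly positive and neither rate is
#' flagged below its detection limit. Below-detection records are excluded
#' rather than substituted at half the detection limit.
#'
#' @param sites A sites tibble (see [read_sites_table()] for the schema).
#' @return A logical vector along the rows of `sites`.
#' @export
ratio_eligible <- function(sites) {
  validate_sites(sites)
  ok <- function(x) is.finite(x) & x > 0
  ok(sites$nh4_uM) & ok(sites$ureaN_uM) & ok(sites$nh4_ox) &
    ok(sites$urea_ox) & !sites$nh4_ox_below_dl & !sites$urea_ox_below_dl
}

new_regression_fit <- function(slope, slope_se, intercept, r2, p_value, n,
                               residual_sd, method, outlier_flags,
                               n_excluded = 0L, data = NULL) {
  structure(
    list(slope = slope, slope_se = slope_se, intercept = intercept, r2 = r2,
         p_value = p_value, n = n, residual_sd = residual_sd, method = method,
         outlier_flags = outlier_flags, n_excluded = n_excluded, data = data),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s: y = %.4g x + %.4g (n = %d, r2 = %.3g, p = %.3g)\n",
              x$method, x$slope, x$intercept, x$n, x$r2, x$p_value))
  if (any(x$outlier_flags)) {
    cat(sprintf("  %d point(s) flagged beyond the residual threshold\n",
                sum(x$outlier_flags)))
  }
  invisible(x)
}

# Shared OLS on paired vectors. Degenerate x (zero variance) is either an
# error or, when allow_degenerate_x, the flat-line contract slope = 0,
# intercept = mean(y).
ols_fit_xy <- function(x, y, method_label = "ols", sd_threshold = 2,
                       allow_degenerate_x = FALSE, n_excluded = 0L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("at least 3 points are required for a fit", call. = FALSE)
  if (stats::var(x) == 0) {
    if (!allow_degenerate_x) {
      stop("predictor has zero variance; fit is degenerate", call. = FALSE)
    }
    res <- y - mean(y)
    return(new_regression_fit(
      slope = 0, slope_se = NA_real_, intercept = mean(y), r2 = NA_real_,
      p_value = NA_real_, n = n, residual_sd = stats::sd(y),
      method = method_label, outlier_flags = rep(FALSE, n),
      n_excluded = n_excluded, data = tibble::tibble(x = x, y = y)))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  res <- stats::residuals(fit)
  rsd <- sm$sigma
  tol <- 1e-8 * max(abs(y), 1)
  flags <- abs(res) > sd_threshold * rsd + tol
  new_regression_fit(
    slope = unname(coef(fit)["x"]),
    slope_se = unname(sm$coefficients["x", "Std. Error"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r2 = sm$r.squared,
    p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
    n = n, residual_sd = rsd, method = method_label, outlier_flags = flags,
    n_excluded = n_excluded,
    data = tibble::tibble(x = x, y = y, residual = res))
}

loglog_xy <- function(sites) {
  eligible <- ratio_eligible(sites)
  list(x = log10(sites$ureaN_uM / sites$nh4_uM)[eligible],
       y = log10(sites$urea_ox / sites$nh4_ox)[eligible],
       eligible = eligible)
}

#' Log-log fit of oxidation-rate ratios on substrate ratios
#'
#' Ordinary least squares of `log10(urea_ox / nh4_ox)` on
#' `log10(ureaN_uM / nh4_uM)` over the ratio-eligible records (see
#' [ratio_eligible()]); the count of excluded records is reported via a
#' message and stored in the fit. An all-constant predictor returns the flat
#' fit (slope 0, intercept at the mean response).
#'
#' @param sites A sites tibble.
#' @param sd_threshold Residual threshold (in residual SDs) for the
#'   informational `outlier_flags`.
#' @return A `regression_fit` on log10 scales.
#' @export
loglog_fit <- function(sites, sd_threshold = 2) {
  xy <- loglog_xy(sites)
  n_excl <- sum(!xy$eligible)
  if (sum(xy$eligible) < 3) {
    stop("fewer than 3 ratio-eligible records; cannot fit", call. = FALSE)
  }
  if (n_excl > 0) {
    message(n_excl, " record(s) excluded from the ratio fit (missing, zero or below-detection rates)")
  }
  ols_fit_xy(xy$x, xy$y, method_label = "ols", sd_threshold = sd_threshold,
             allow_degenerate_x = TRUE, n_excluded = n_excl)
}

theil_sen_xy <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  slopes <- dy[dx != 0] / dx[dx != 0]
  slope <- stats::median(slopes)
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' Robust log-log fit with residual outlier flagging
#'
#' Fits the same log-log relationship as [loglog_fit()] with an
#' iteratively-reweighted robust line (Huber loss, tuning constant 1.345),
#' then flags points whose absolute residual exceeds `sd_threshold` times the
#' robust residual scale. This isolates observations such as the polar-ocean
#' regime of anomalously high urea:ammonium oxidation at low substrate
#' ratios. A Theil-Sen line is available as an alternative estimator.
#'
#' @inheritParams loglog_fit
#' @param sd_threshold Flagging threshold in robust residual SDs (default 2).
#' @param method `"huber"` (default) or `"theil_sen"`.
#' @return A `regression_fit` with `outlier_flags` over the eligible records;
#'   `fit$data` carries the flagged points with their residuals.
#' @export
robust_loglog_fit <- function(sites, sd_threshold = 2,
                              method = c("huber", "theil_sen")) {
  method <- match.arg(method)
  xy <- loglog_xy(sites)
  n_excl <- sum(!xy$eligible)
  x <- xy$x; y <- xy$y
  n <- length(x)
  if (n < 3) stop("fewer than 3 ratio-eligible records; cannot fit",
                  call. = FALSE)
  if (stats::var(x) == 0) {
    stop("predictor has zero variance; robust fit is degenerate", call. = FALSE)
  }
  if (method == "huber") {
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100)
    slope <- unname(coef(fit)["x"])
    intercept <- unname(coef(fit)["(Intercept)"])
    sm <- summary(fit)
    slope_se <- unname(sm$coefficients["x", "Std. Error"])
    rsd <- fit$s
    res <- y - (intercept + slope * x)
    tstat <- slope / slope_se
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    ts <- theil_sen_xy(x, y)
    slope <- ts$slope
    intercept <- ts$intercept
    res <- y - (intercept + slope * x)
    rsd <- stats::mad(res, center = 0)
    slope_se <- NA_real_
    p <- NA_real_
  }
  tol <- 1e-8 * max(abs(y), 1)
  flags <- abs(res) > sd_threshold * rsd + tol
  fitted_r2 <- stats::cor(intercept + slope * x, y)^2
  new_regression_fit(slope, slope_se, intercept, r2 = fitted_r2, p_value = p,
                     n = n, residual_sd = rsd, method = paste0("robust_", method),
                     outlier_flags = flags, n_excluded = n_excl,
                     data = tibble::tibble(x = x, y = y, residual = res,
                                           outlier = flags))
}

#' Log-log fit restricted to selected habitats
#'
#' @inheritParams loglog_fit
#' @param habitat_filter Character vector of habitats to keep (subset of
#'   `"estuary"`, `"coastal"`, `"open_ocean"`, `"polar"`, `"omz"`). The
#'   open-ocean variant of the global relationship, for example, drops
#'   estuaries and polar records.
#' @return A `regression_fit`.
#' @export
subgroup_fit <- function(sites, habitat_filter, sd_threshold = 2) {
  validate_sites(sites)
  bad <- setdiff(habitat_filter, site_habitats)
  if (length(bad)) {
    stop("unknown habitat(s) in filter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sub <- sites[sites$habitat %in% habitat_filter, , drop = FALSE]
  if (nrow(sub) == 0 || sum(ratio_eligible(sub)) < 3) {
    stop("fewer than 3 ratio-eligible records after habitat filtering",
         call. = FALSE)
  }
  loglog_fit(sub, sd_threshold = sd_threshold)
}

#' Predict an oxidation-rate ratio from a substrate ratio
#'
#' Back-transforms a log-log `regression_fit`:
#' `10^(slope * log10(ratio) + intercept)`.
#'
#' @param fit A `regression_fit` on log10 scales.
#' @param substrate_ratio Urea-N : ammonium concentration ratio(s), > 0.
#' @return Predicted urea-oxidation : ammonium-oxidation rate ratio(s).
#' @export
predict_rate_ratio <- function(fit, substrate_ratio) {
  if (!inherits(fit, "regression_fit")) {
    stop("`fit` must be a regression_fit", call. = FALSE)
  }
  if (any(!is.finite(substrate_ratio)) || any(substrate_ratio <= 0)) {
    stop("`substrate_ratio` must be > 0", call. = FALSE)
  }
  10^(fit$slope * log10(substrate_ratio) + fit$intercept)
}

#' Fraction of observations where ammonium oxidation outpaces urea oxidation
#'
#' Counts records with `nh4_ox > urea_ox` among records where both rates are
#' present (finite and >= 0); ties count as not-higher.
#'
#' @param sites A sites tibble.
#' @return A fraction in \[0, 1\].
#' @export
fraction_preferring_ammonium <- function(sites) {
  validate_sites(sites)
  eligible <- is.finite(sites$nh4_ox) & is.finite(sites$urea_ox) &
    sites$nh4_ox >= 0 & sites$urea_ox >= 0
  if (!any(eligible)) {
    stop("no records with both oxidation rates present", call. = FALSE)
  }
  mean(sites$nh4_ox[eligible] > sites$urea_ox[eligible])
}
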