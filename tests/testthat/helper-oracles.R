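# Hand-coded closed-form OLS, independent of stats::lm, used as the oracle
# for slope fits.
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  sigma2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(sigma2 / sxx),
       r2 = 1 - sum(res^2) / sum((y - ybar)^2))
}

# A clean exact-line time course used across tests.
make_linear_tc <- function(slope_per_day = 6, reps = 1, times_h = c(0, 4, 8, 12),
                           substrate = "ammonium", F_target = 0.1) {
  pool <- substrate_pool(substrate, ambient_conc = 0.9,
                         tracer_conc = tracer_conc_for_F(0.9, F_target))
  t_h <- rep(times_h, each = reps)
  n <- length(t_h)
  tibble::tibble(
    time_h = t_h, bottle_id = paste0("b", seq_len(n)),
    n2o44_nM = 10, n2o45_nM = 0.1, n2o46_nM = 0.01,
    no2_15N_nM = slope_per_day * t_h / 24
  ) -> pts
  time_course("T1", 5, substrate, "in_situ", pool, pts)
}
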