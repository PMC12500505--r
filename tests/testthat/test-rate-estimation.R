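test_that("slope fits convert hours to per-day and match the closed-form oracle", {
  tc <- make_linear_tc(slope_per_day = 6)
  fit <- fit_time_course(tc, "no2_15N")
  expect_equal(fit$slope, 6)
  expect_equal(fit$r2, 1)

  # duplicate bottles are pooled as independent points; compare against the
  # hand-coded OLS oracle on noisy data
  set.seed(7)
  t_h <- rep(c(0, 4, 8, 12), each = 2)
  y <- 0.5 * t_h / 24 + rnorm(8, 0, 0.05)
  pool <- substrate_pool("ammonium", 0.9, 0.1)
  tc2 <- time_course("T1", 5, "ammonium", "in_situ", pool,
                     tibble::tibble(time_h = t_h,
                                    bottle_id = paste0("b", 1:8),
                                    n2o44_nM = 10, n2o45_nM = 0.1,
                                    n2o46_nM = 0.01, no2_15N_nM = pmax(y, 0)))
  fit2 <- fit_time_course(tc2, "no2_15N")
  orc <- ols_oracle(t_h / 24, pmax(y, 0))
  expect_equal(fit2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(fit2$slope_se, orc$slope_se, tolerance = 1e-10)
  expect_equal(fit2$r2, orc$r2, tolerance = 1e-10)
  expect_equal(fit2$n, 8L)
  expect_equal(fit2$df, 6L)
})

test_that("time course validation enforces the design contracts", {
  pool <- substrate_pool("ammonium", 0.9, 0.1)
  one_time <- tibble::tibble(time_h = c(0, 0), bottle_id = c("a", "b"),
                             n2o44_nM = 1, n2o45_nM = 0, n2o46_nM = 0,
                             no2_15N_nM = 0)
  expect_error(time_course("T", 1, "ammonium", "in_situ", pool, one_time),
               "2 distinct time")
  two_times <- tibble::tibble(time_h = c(0, 4), bottle_id = c("a", "b"),
                              n2o44_nM = 1, n2o45_nM = 0, n2o46_nM = 0,
                              no2_15N_nM = c(0, 1))
  expect_warning(time_course("T", 1, "ammonium", "in_situ", pool, two_times),
                 "poorly constrained")
  neg <- two_times; neg$no2_15N_nM <- c(-1, 1)
  expect_error(time_course("T", 1, "ammonium", "in_situ", pool, neg),
               "negative concentration")
})

test_that("noisy slope estimates land within 3 SE at the expected frequency", {
  set.seed(101)
  true_slope <- 2.5
  hits <- vapply(1:500, function(i) {
    t_h <- rep(c(0, 4, 8, 12), each = 2)
    y <- 5 + true_slope * t_h / 24 + rnorm(8, 0, 0.33)
    orc <- ols_oracle(t_h / 24, y)
    abs(orc$slope - true_slope) <= 3 * orc$slope_se
  }, logical(1))
  # with 6 residual df the slope t-ratio is within +/-3 with probability
  # pt(3, 6) - pt(-3, 6) = 0.976; allow binomial noise below that
  expect_gte(mean(hits), 0.95)
})

test_that("tracer-dilution correction divides rates and SEs by F", {
  tc <- make_linear_tc(slope_per_day = 0.5, F_target = 0.1)
  est <- nitrite_production_rate(tc)
  expect_equal(est$value, 0.5 / 0.1, tolerance = 1e-9)
  expect_equal(est$product, "nitrite")

  # fully labelled pool: rate equals the slope
  tc1 <- make_linear_tc(slope_per_day = 0.5, F_target = 0.989999)
  est1 <- nitrite_production_rate(tc1)
  expect_equal(est1$value, 0.5 / 0.989999, tolerance = 1e-9)

  # homogeneity of degree -1 in F
  tcA <- make_linear_tc(slope_per_day = 1, F_target = 0.1)
  tcB <- make_linear_tc(slope_per_day = 1, F_target = 0.2)
  expect_equal(nitrite_production_rate(tcA)$value,
               2 * nitrite_production_rate(tcB)$value, tolerance = 1e-9)
})

test_that("rates are invariant to row order and replicate relabelling", {
  cfg <- sim_config(seed = 5)
  tc <- simulate_incubation(cfg, "ammonium")
  shuffled <- tc
  set.seed(1)
  perm <- sample(nrow(tc$points))
  shuffled$points <- tc$points[perm, ]
  shuffled$points$bottle_id <- paste0("z", seq_len(nrow(tc$points)))
  expect_equal(nitrite_production_rate(shuffled)$value,
               nitrite_production_rate(tc)$value, tolerance = 1e-12)
  expect_equal(n2o_production_rate(shuffled)$value,
               n2o_production_rate(tc)$value, tolerance = 1e-12)
})

test_that("N2O rates invert the binomial model exactly on noiseless data", {
  cfg <- sim_config(seed = 2)
  tc <- simulate_incubation(cfg, "ammonium", noise = FALSE,
                            true_rates = list(nitrite = 10, n2o = 0.05),
                            f_target = 0.1)
  est <- n2o_production_rate(tc)
  expect_equal(est$value, 0.05, tolerance = 1e-9)
})

test_that("a zero true N2O rate is reported near zero and below detection", {
  cfg <- sim_config(seed = 9)
  below <- vapply(1:20, function(i) {
    tc <- simulate_incubation(cfg, "urea",
                              true_rates = list(nitrite = 2, n2o = 0),
                              stream_tag = paste0("null", i))
    est <- n2o_production_rate(tc)
    isTRUE(est$below_detection) && abs(est$value) < 10 * est$detection_limit
  }, logical(1))
  expect_gte(mean(below), 0.9)
})

test_that("near-natural-abundance pools trigger the label floor warning", {
  pool <- substrate_pool("ammonium", 1, tracer_conc = 0.005)
  pts <- make_linear_tc(1)$points
  tc <- time_course("T", 1, "ammonium", "in_situ", pool, pts)
  expect_warning(nitrite_production_rate(tc), "below the floor")
})

test_that("detection limits follow the design formula and its scalings", {
  expect_equal(rate_detection_limit(c(0, 4, 8, 12), 2, noise_sd = 0,
                                    F = 0.1), 0)
  # doubling F halves the DL
  d1 <- rate_detection_limit(c(0, 4, 8, 12), 2, 0.01, F = 0.1)
  d2 <- rate_detection_limit(c(0, 4, 8, 12), 2, 0.01, F = 0.2)
  expect_equal(d1, 2 * d2, tolerance = 1e-12)
  # N2O DL carries the extra factor of 2 from the two-atom excess
  dn <- rate_detection_limit(c(0, 4, 8, 12), 2, 0.01, F = 0.1,
                             product = "n2o")
  expect_equal(dn, d1 / 2, tolerance = 1e-12)
  expect_error(rate_detection_limit(c(4, 4, 4), 2, 0.01, 0.1), "equal")
})

test_that("analytic detection limit matches a Monte-Carlo null-slope quantile", {
  # oracle: 95% quantile of |slope| over pure-noise incubations, divided by F
  times <- c(0, 4, 8, 12); reps <- 2; sd0 <- 0.01; F <- 0.1
  dl <- rate_detection_limit(times, reps, sd0, F)
  set.seed(202)
  t_d <- rep(times, each = reps) / 24
  null_rates <- vapply(1:10000, function(i) {
    abs(ols_oracle(t_d, rnorm(length(t_d), 0, sd0))$slope) / F
  }, numeric(1))
  mc <- quantile(null_rates, 0.95, names = FALSE)
  expect_lt(abs(dl - mc) / mc, 0.10)
})

test_that("simulated incubations recover the generating rates within 2 SE", {
  cfg <- sim_config(seed = 31)
  hits <- vapply(1:40, function(i) {
    tc <- simulate_incubation(cfg, "urea",
                              true_rates = list(nitrite = 2.0, n2o = 0.004),
                              f_target = 0.12, stream_tag = paste0("rt", i))
    e1 <- nitrite_production_rate(tc)
    e2 <- n2o_production_rate(tc)
    abs(e1$value - 2.0) <= 2 * e1$se && abs(e2$value - 0.004) <= 2 * e2$se
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("rates_table emits one row per incubation and product", {
  cfg <- sim_config(seed = 4)
  tcs <- list(simulate_incubation(cfg, "ammonium", depth_m = 5),
              simulate_incubation(cfg, "urea", depth_m = 5))
  tab <- rates_table(tcs)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$product, c("nitrite", "n2o"))
  expect_setequal(tab$substrate, c("ammonium", "urea"))
  expect_true(all(is.finite(tab$rate)))
})
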