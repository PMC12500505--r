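test_that("configuration validates its study conditions", {
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$time_grid_h, c(0, 4, 8, 12))
  expect_equal(cfg$replicates, 2L)
  expect_error(sim_config(no2_noise_sd = -1), ">= 0")
  expect_error(sim_config(f_targets = c(ammonium = 0, urea = 0.1)), "\\(0, 1\\)")
  expect_error(sim_config(outlier_fraction = 1.5), "\\[0, 1\\]")
})

test_that("generators are deterministic given the seed and diverge across seeds", {
  cfg <- sim_config(seed = 123)
  a <- simulate_incubation(cfg, "ammonium")
  b <- simulate_incubation(cfg, "ammonium")
  expect_identical(a$points, b$points)
  g1 <- simulate_global_dataset(cfg, 50)
  g2 <- simulate_global_dataset(cfg, 50)
  expect_identical(g1, g2)
  c1 <- simulate_coverage_table(cfg, 12)
  c2 <- simulate_coverage_table(cfg, 12)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  other <- simulate_incubation(sim_config(seed = 124), "ammonium")
  expect_false(identical(a$points, other$points))
})

test_that("noiseless incubations follow the forward model exactly", {
  cfg <- sim_config(seed = 1)
  tc <- simulate_incubation(cfg, "ammonium", noise = FALSE,
                            true_rates = list(nitrite = 5, n2o = 0.01),
                            f_target = 0.1)
  fit <- fit_time_course(tc, "no2_15N")
  expect_equal(fit$slope, 5 * 0.1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  fit2 <- fit_time_course(tc, "n2o_excess")
  expect_equal(fit2$slope, 2 * 0.1 * 0.01, tolerance = 1e-9)
})

test_that("generated time courses satisfy the container invariants", {
  cfg <- sim_config(seed = 17)
  for (s in c("ammonium", "urea")) {
    tc <- simulate_incubation(cfg, s, stream_tag = paste0("inv", s))
    expect_s3_class(tc, "time_course")
    expect_true(all(tc$points$no2_15N_nM >= 0))
    expect_true(all(tc$points$n2o45_nM >= 0))
    expect_equal(nrow(tc$points),
                 length(cfg$time_grid_h) * cfg$replicates)
    F <- label_fraction(tc$pool)
    lo <- if (s == "ammonium") 0.085 else 0.061
    hi <- if (s == "ammonium") 0.372 else 0.180
    expect_gte(F, lo); expect_lte(F, hi)
  }
})

test_that("generate-estimate round trip recovers both rates within 2 SE", {
  cfg <- sim_config(seed = 29)
  hits <- vapply(1:60, function(i) {
    tc <- simulate_incubation(cfg, "urea",
                              true_rates = list(nitrite = 2.0, n2o = 0.004),
                              stream_tag = paste0("roundtrip", i))
    e1 <- nitrite_production_rate(tc)
    e2 <- n2o_production_rate(tc)
    c(abs(e1$value - 2.0) <= 2 * e1$se, abs(e2$value - 0.004) <= 2 * e2$se)
  }, logical(2))
  # each rate lands within 2 SE with probability pt(2,6)-pt(-2,6) = 0.908
  expect_gte(mean(hits[1, ]), 0.8)
  expect_gte(mean(hits[2, ]), 0.8)
})

test_that("manipulation treatments move pools, labels and rates as designed", {
  cfg <- sim_config(seed = 41, inhibition_factor = 0.27)

  # paper protocol: tracer resized to the amended pool keeps F at target
  pa <- simulate_manipulation(cfg, "plus_ammonium")
  expect_equal(pa$ammonium$pool$ambient_conc, cfg$ambient$nh4_uM + 2)
  expect_equal(label_fraction(pa$ammonium$pool),
               unname(cfg$f_targets["ammonium"]), tolerance = 1e-12)

  # fixed tracer mass: F drops as the ammonium pool is enlarged
  pf <- simulate_manipulation(cfg, "plus_ammonium", rescale_tracer = FALSE)
  tracer <- tracer_conc_for_F(cfg$ambient$nh4_uM,
                              unname(cfg$f_targets["ammonium"]))
  expected_F <- label_fraction(
    substrate_pool("ammonium", cfg$ambient$nh4_uM + 2, tracer))
  expect_equal(label_fraction(pf$ammonium$pool), expected_F,
               tolerance = 1e-12)
  expect_lt(expected_F, unname(cfg$f_targets["ammonium"]) / 5)

  # urea addition enlarges the urea pool; ammonium oxidation unchanged
  pu <- simulate_manipulation(cfg, "plus_urea", noise = FALSE)
  expect_equal(pu$urea$pool$ambient_conc, cfg$ambient$urea_uMN + 18)
  base <- simulate_manipulation(cfg, "in_situ", noise = FALSE)
  expect_equal(nitrite_production_rate(pu$ammonium)$value,
               nitrite_production_rate(base$ammonium)$value,
               tolerance = 1e-9)

  # ammonium amendment scales true urea oxidation by the inhibition factor
  pa0 <- simulate_manipulation(cfg, "plus_ammonium", noise = FALSE)
  expect_equal(nitrite_production_rate(pa0$urea)$value,
               0.27 * nitrite_production_rate(base$urea)$value,
               tolerance = 1e-9)
  cmp <- compare_treatments(nitrite_production_rate(pa0$urea),
                            nitrite_production_rate(base$urea))
  expect_equal(cmp$percent_change, -73, tolerance = 1e-6)
})

test_that("a null inhibition factor leaves treatments indistinguishable", {
  cfg <- sim_config(seed = 61, inhibition_factor = 1)
  sig <- vapply(1:30, function(i) {
    base <- simulate_incubation(cfg, "urea", stream_tag = paste0("n0", i))
    trt <- simulate_incubation(cfg, "urea", treatment = "plus_ammonium",
                               stream_tag = paste0("n1", i))
    compare_treatments(nitrite_production_rate(trt),
                       nitrite_production_rate(base))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.2)
})

test_that("the cross-site generator carries its power law and polar regime", {
  cfg0 <- sim_config(seed = 7, scatter_log10 = 0, outlier_fraction = 0)
  sites0 <- simulate_global_dataset(cfg0, 100)
  fit0 <- suppressMessages(loglog_fit(sites0))
  expect_equal(fit0$slope, cfg0$global_slope, tolerance = 1e-9)
  expect_equal(fit0$intercept, cfg0$global_intercept, tolerance = 1e-9)

  cfg <- sim_config(seed = 7, outlier_fraction = 0.1)
  sites <- simulate_global_dataset(cfg, 200)
  expect_equal(sum(sites$habitat == "polar"), 20)
  rob <- suppressMessages(robust_loglog_fit(sites))
  polar_in_fit <- sites$habitat[ratio_eligible(sites)] == "polar"
  expect_gte(mean(rob$outlier_flags[polar_in_fit]), 0.8)
})

test_that("the coverage generator encodes the gene-ratio relation", {
  cfg <- sim_config(seed = 3)
  cov0 <- simulate_coverage_table(cfg, 30, poisson_noise = FALSE)
  tr0 <- attr(cov0, "truth")
  r0 <- sample_gene_ratios(cov0)
  expect_equal(r0$urec_amoa, tr0$true_ratio, tolerance = 1e-12)
  fit <- ratio_vs_substrate_fit(tr0$substrate_ratio, r0$urec_amoa)
  expect_equal(fit$slope, cfg$generatio_slope, tolerance = 1e-9)
  expect_equal(fit$intercept, cfg$generatio_intercept, tolerance = 1e-9)

  # zero substrate ratio clamps the true gene ratio at zero: no ureC records
  covz <- simulate_coverage_table(cfg, 5, substrate_ratio = 0)
  expect_false(any(covz$gene == "ureC"))
  rz <- sample_gene_ratios(covz)
  expect_true(all(rz$urec_amoa == 0, na.rm = TRUE))
})
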