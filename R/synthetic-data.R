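# Seeded generators emulating every input the pipeline consumes: incubation
# time courses, substrate-manipulation pairs, the cross-site compilation and
# gene-coverage tables. All draws derive from one configuration seed via
# deterministic per-call substreams.

#' Simulation configuration
#'
#' Collects the study conditions the generators emulate: the incubation
#' design (four time points, duplicate bottles), measurement noise, true
#' rates, labelled-fraction targets, the global power-law coupling of rate
#' ratios to substrate ratios, the polar outlier regime, ammonium inhibition
#' of urea oxidation, and the linear coupling of ureC:amoA gene ratios to
#' substrate ratios.
#'
#' @param seed Integer seed governing all draws.
#' @param time_grid_h Sampling times, hours.
#' @param replicates Bottles per time point.
#' @param n2o_noise_sd Noise SD of total N2O (mass-44) concentration, nM.
#' @param n2o_excess_noise_sd Noise SD of the mass-45/46 15N-atom excess
#'   series, nM; reflects isotope-ratio (not concentration) precision.
#' @param no2_noise_sd Noise SD of measured 15N-nitrite, nmol N L-1.
#' @param true_rates Per-substrate true production rates: a list with
#'   elements `ammonium` and `urea`, each `list(nitrite =, n2o =)` in
#'   nmol N L-1 d-1 and nmol N2O L-1 d-1.
#' @param f_targets Target labelled fractions per substrate (tracer at
#'   roughly ten percent of the ambient pool).
#' @param ambient Ambient concentrations: `nh4_uM`, `urea_uMN`, `no2_uMN`
#'   (nitrite pool carrying the natural-abundance 15N baseline) and
#'   `n2o_nM`.
#' @param global_slope,global_intercept Coefficients of the global log-log
#'   relation between oxidation-rate ratios and substrate ratios.
#' @param scatter_log10 Lognormal scatter (SD in log10) about that relation.
#' @param outlier_fraction Fraction of sites drawn in the polar outlier
#'   regime (high rate ratio at low substrate ratio).
#' @param polar_shift_log10 Intercept shift (log10 rate ratio) of the polar
#'   regime.
#' @param inhibition_factor Multiplier on true urea-oxidation rates under
#'   ammonium amendment (0.4 emulates the observed 52-73 percent decreases).
#' @param generatio_slope,generatio_intercept Linear coefficients coupling
#'   ureC:amoA gene ratios to substrate ratios.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       time_grid_h = c(0, 4, 8, 12),
                       replicates = 2L,
                       n2o_noise_sd = 0.33,
                       n2o_excess_noise_sd = 5e-5,
                       no2_noise_sd = 0.005,
                       true_rates = list(
                         ammonium = list(nitrite = 50, n2o = 0.04),
                         urea = list(nitrite = 2, n2o = 0.002)),
                       f_targets = c(ammonium = 0.10, urea = 0.10),
                       ambient = list(nh4_uM = 0.17, urea_uMN = 1.12,
                                      no2_uMN = 2, n2o_nM = 10),
                       global_slope = 1.113,
                       global_intercept = -0.97,
                       scatter_log10 = 0.3,
                       outlier_fraction = 0.05,
                       polar_shift_log10 = 1.0,
                       inhibition_factor = 0.4,
                       generatio_slope = 0.083,
                       generatio_intercept = -0.018) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  sds <- c(n2o_noise_sd, n2o_excess_noise_sd, no2_noise_sd, scatter_log10)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("noise and scatter SDs must be >= 0", call. = FALSE)
  }
  if (any(f_targets <= 0) || any(f_targets >= 1)) {
    stop("`f_targets` must lie in (0, 1)", call. = FALSE)
  }
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    stop("`outlier_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (inhibition_factor < 0) stop("`inhibition_factor` must be >= 0",
                                  call. = FALSE)
  if (length(time_grid_h) < 2 || any(time_grid_h < 0)) {
    stop("`time_grid_h` needs at least 2 nonnegative times", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(seed = as.integer(seed), time_grid_h = time_grid_h,
         replicates = as.integer(replicates), n2o_noise_sd = n2o_noise_sd,
         n2o_excess_noise_sd = n2o_excess_noise_sd,
         no2_noise_sd = no2_noise_sd, true_rates = true_rates,
         f_targets = f_targets, ambient = ambient,
         global_slope = global_slope, global_intercept = global_intercept,
         scatter_log10 = scatter_log10, outlier_fraction = outlier_fraction,
         polar_shift_log10 = polar_shift_log10,
         inhibition_factor = inhibition_factor,
         generatio_slope = generatio_slope,
         generatio_intercept = generatio_intercept),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d time points x %d bottles, F targets %s\n",
              x$seed, length(x$time_grid_h), x$replicates,
              paste(sprintf("%s %.2f", names(x$f_targets), x$f_targets),
                    collapse = ", ")))
  invisible(x)
}

# Deterministic per-call substream seed: polynomial hash of the tag folded
# with the configuration seed, kept well inside 32-bit integer range.
substream_seed <- function(seed, tag) {
  h <- 7
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% 32768
  (abs(seed) %% 32768) * 32768 + h
}

set_substream <- function(cfg, tag) {
  set.seed(substream_seed(cfg$seed, tag))
}

#' Simulate one tracer incubation time course
#'
#' Forward-simulates 15N-nitrite accumulation at `rate * F * t` over the
#' natural-abundance baseline of the ambient nitrite pool, and N2O
#' isotopologue accumulation through the binomial single-pool model at the
#' configured gross N2O rate. Gaussian measurement noise is added on
#' concentrations (mass-44 at the concentration precision; mass-45/46 at the
#' much smaller isotope-ratio precision, split evenly over the excess
#' series) and measured values are censored at zero. Deterministic per
#' (seed, station, depth, substrate, treatment) unless `stream_tag`
#' overrides the tag.
#'
#' @param cfg A [sim_config()].
#' @param substrate `"ammonium"` or `"urea"` (the traced pool).
#' @param station,depth_m Station metadata.
#' @param treatment Treatment label recorded on the result.
#' @param true_rates Optional `list(nitrite =, n2o =)` overriding
#'   `cfg$true_rates[[substrate]]`.
#' @param ambient_conc Optional ambient substrate concentration override,
#'   umol N L-1.
#' @param f_target Optional labelled-fraction target override.
#' @param noise If `FALSE`, noiseless forward model (for exact-recovery
#'   checks).
#' @param stream_tag Optional explicit substream tag.
#' @return A [time_course()].
#' @export
simulate_incubation <- function(cfg, substrate = c("ammonium", "urea"),
                                station = "SYN1", depth_m = 10,
                                treatment = "in_situ",
                                true_rates = NULL, ambient_conc = NULL,
                                f_target = NULL, noise = TRUE,
                                stream_tag = NULL) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config",
                                         call. = FALSE)
  substrate <- match.arg(substrate)
  if (is.null(true_rates)) true_rates <- cfg$true_rates[[substrate]]
  if (is.null(ambient_conc)) {
    ambient_conc <- if (substrate == "ammonium") cfg$ambient$nh4_uM else cfg$ambient$urea_uMN
  }
  if (is.null(f_target)) f_target <- unname(cfg$f_targets[[substrate]])
  tag <- if (is.null(stream_tag)) {
    paste(station, depth_m, substrate, treatment, sep = "|")
  } else stream_tag
  set_substream(cfg, tag)

  tracer <- tracer_conc_for_F(ambient_conc, f_target)
  pool <- substrate_pool(substrate, ambient_conc, tracer)
  F <- label_fraction(pool)

  t_h <- rep(cfg$time_grid_h, each = cfg$replicates)
  t_d <- t_h / 24
  npts <- length(t_h)
  bottle <- paste0("b", seq_len(npts))

  fn <- natural_abundance_15N()
  # 15N-nitrite: natural-abundance baseline of the ambient pool + labelled
  # accumulation; concentrations in nmol N / L.
  no2_base <- cfg$ambient$no2_uMN * 1000 * fn
  no2 <- no2_base + true_rates$nitrite * F * t_d
  # N2O isotopologues: ambient pool at natural abundance + binomial
  # production at atom fraction F.
  amb <- isotopologue_fractions(fn)
  prod <- isotopologue_fractions(F)
  n2o44 <- cfg$ambient$n2o_nM * amb$p44 + true_rates$n2o * t_d * prod$p44
  n2o45 <- cfg$ambient$n2o_nM * amb$p45 + true_rates$n2o * t_d * prod$p45
  n2o46 <- cfg$ambient$n2o_nM * amb$p46 + true_rates$n2o * t_d * prod$p46
  if (noise) {
    s_iso <- cfg$n2o_excess_noise_sd / sqrt(5)
    no2 <- pmax(0, no2 + stats::rnorm(npts, 0, cfg$no2_noise_sd))
    n2o44 <- pmax(0, n2o44 + stats::rnorm(npts, 0, cfg$n2o_noise_sd))
    n2o45 <- pmax(0, n2o45 + stats::rnorm(npts, 0, s_iso))
    n2o46 <- pmax(0, n2o46 + stats::rnorm(npts, 0, s_iso))
  }
  time_course(station = station, depth_m = depth_m, substrate = substrate,
              treatment = treatment, pool = pool,
              points = tibble::tibble(time_h = t_h, bottle_id = bottle,
                                      n2o44_nM = n2o44, n2o45_nM = n2o45,
                                      n2o46_nM = n2o46, no2_15N_nM = no2))
}

#' Simulate a substrate-manipulation experiment
#'
#' Returns the pair of tracer incubations (ammonium-traced and urea-traced)
#' for one treatment. `"plus_ammonium"` adds 2 umol L-1 ammonium to the
#' ambient pool and multiplies the true urea-oxidation rates by
#' `cfg$inhibition_factor`; `"plus_urea"` adds 18 umol N L-1 urea and leaves
#' ammonium oxidation unchanged. By default the tracer is re-sized to reach
#' the target labelled fraction of the amended pool (the field protocol);
#' with `rescale_tracer = FALSE` the tracer amount of the unamended design is
#' kept, so F drops as the pool is enlarged.
#'
#' @inheritParams simulate_incubation
#' @param treatment `"in_situ"`, `"plus_ammonium"` or `"plus_urea"`.
#' @param rescale_tracer Re-size tracer to the amended pool (default TRUE).
#' @return A list with elements `ammonium` and `urea`, each a
#'   [time_course()].
#' @export
simulate_manipulation <- function(cfg,
                                  treatment = c("in_situ", "plus_ammonium",
                                                "plus_urea"),
                                  station = "SYN1", depth_m = 10,
                                  rescale_tracer = TRUE, noise = TRUE) {
  treatment <- match.arg(treatment)
  nh4_amb <- cfg$ambient$nh4_uM + if (treatment == "plus_ammonium") 2 else 0
  urea_amb <- cfg$ambient$urea_uMN + if (treatment == "plus_urea") 18 else 0
  urea_rates <- cfg$true_rates$urea
  if (treatment == "plus_ammonium") {
    urea_rates <- lapply(urea_rates, `*`, cfg$inhibition_factor)
  }
  f_for <- function(substrate, amb_base, amb_now) {
    target <- unname(cfg$f_targets[[substrate]])
    if (rescale_tracer) return(target)
    # fixed tracer mass, sized for the unamended pool
    tracer <- tracer_conc_for_F(amb_base, target)
    label_fraction(substrate_pool(substrate, amb_now, tracer))
  }
  list(
    ammonium = simulate_incubation(
      cfg, "ammonium", station = station, depth_m = depth_m,
      treatment = treatment, true_rates = cfg$true_rates$ammonium,
      ambient_conc = nh4_amb,
      f_target = f_for("ammonium", cfg$ambient$nh4_uM, nh4_amb),
      noise = noise),
    urea = simulate_incubation(
      cfg, "urea", station = station, depth_m = depth_m,
      treatment = treatment, true_rates = urea_rates,
      ambient_conc = urea_amb,
      f_target = f_for("urea", cfg$ambient$urea_uMN, urea_amb),
      noise = noise)
  )
}

habitat_conc_params <- list(
  # lognormal meanlog/sdlog for nh4 (uM) and urea (uM N) per habitat,
  # spanning eutrophic estuaries to oligotrophic gyres
  estuary    = list(nh4 = c(log(2.0), 0.9), urea = c(log(0.6), 0.7)),
  coastal    = list(nh4 = c(log(0.5), 0.9), urea = c(log(0.4), 0.7)),
  open_ocean = list(nh4 = c(log(0.05), 0.8), urea = c(log(0.10), 0.8)),
  omz        = list(nh4 = c(log(0.04), 0.8), urea = c(log(0.08), 0.8)),
  polar      = list(nh4 = c(log(0.4), 0.7), urea = c(log(0.08), 0.7))
)

#' Simulate a cross-site compilation of paired rates and concentrations
#'
#' Draws habitat-structured lognormal substrate concentrations, couples the
#' urea:ammonium oxidation-rate ratio to the substrate ratio through the
#' configured global power law with lognormal scatter, scales absolute
#' ammonium-oxidation rates to ammonium concentration, and injects a
#' configurable fraction of polar-regime sites with a positive intercept
#' shift at low substrate ratios. Detection flags are set against detection
#' limits of 0.09 (ammonium oxidation) and 0.02 (urea oxidation)
#' nmol N L-1 d-1.
#'
#' @inheritParams simulate_incubation
#' @param n_sites Number of records (>= 10).
#' @param stream_tag Optional explicit substream tag.
#' @return A sites tibble (schema of [read_sites_table()]).
#' @export
simulate_global_dataset <- function(cfg, n_sites = 300, stream_tag = "global") {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config",
                                         call. = FALSE)
  if (n_sites < 10) stop("`n_sites` must be >= 10", call. = FALSE)
  set_substream(cfg, stream_tag)
  n_polar <- round(cfg$outlier_fraction * n_sites)
  n_reg <- n_sites - n_polar
  habitats <- c(sample(c("estuary", "coastal", "open_ocean", "omz"), n_reg,
                       replace = TRUE, prob = c(0.25, 0.30, 0.35, 0.10)),
                rep("polar", n_polar))
  nh4 <- urea <- numeric(n_sites)
  for (h in unique(habitats)) {
    idx <- habitats == h
    p <- habitat_conc_params[[h]]
    nh4[idx] <- stats::rlnorm(sum(idx), p$nh4[1], p$nh4[2])
    urea[idx] <- stats::rlnorm(sum(idx), p$urea[1], p$urea[2])
  }
  x <- urea / nh4
  shift <- ifelse(habitats == "polar", cfg$polar_shift_log10, 0)
  log_y <- cfg$global_slope * log10(x) + cfg$global_intercept + shift +
    stats::rnorm(n_sites, 0, cfg$scatter_log10)
  y <- 10^log_y
  nh4_ox <- 10^(0.8 * log10(nh4) + 1.2 +
                  stats::rnorm(n_sites, 0, min(cfg$scatter_log10, 0.3)))
  urea_ox <- y * nh4_ox
  tibble::tibble(
    region = paste0("SYN-", habitats),
    station = sprintf("st%03d", seq_len(n_sites)),
    depth_m = round(stats::runif(n_sites, 5, 200), 1),
    habitat = habitats,
    nh4_uM = nh4,
    ureaN_uM = urea,
    nh4_ox = nh4_ox,
    urea_ox = urea_ox,
    nh4_ox_below_dl = nh4_ox < 0.09,
    urea_ox_below_dl = urea_ox < 0.02
  )
}

#' Simulate a per-gene coverage table
#'
#' Per sample, a substrate ratio is drawn and the true ureC:amoA ratio set to
#' `max(0, generatio_slope * ratio + generatio_intercept)`. AOA amoA
#' abundance (coverage per million reads) is lognormal; observed mean
#' coverages are Poisson-sampled around abundance x library depth, with
#' library sizes varied between 10 and 100 million reads. When the clamped
#' true ratio is zero, or the Poisson draw is zero, no ureC record is
#' emitted (the sample's ratio is genuinely 0). The generating truth is
#' attached as `attr(, "truth")`.
#'
#' @inheritParams simulate_incubation
#' @param n_samples Number of samples (>= 3).
#' @param poisson_noise If `FALSE`, coverages equal their expectations (for
#'   exact-recovery checks).
#' @param substrate_ratio Optional vector of substrate ratios (recycled to
#'   `n_samples`) overriding the random draw.
#' @param library_reads_millions Optional vector of library sizes.
#' @param stream_tag Optional explicit substream tag.
#' @return A coverage tibble (schema of [read_coverage_table()]) with a
#'   `truth` attribute: a tibble of `sample_id`, `region`,
#'   `substrate_ratio`, `true_ratio`, `amoa_abund`,
#'   `library_reads_millions`.
#' @export
simulate_coverage_table <- function(cfg, n_samples = 24, poisson_noise = TRUE,
                                    substrate_ratio = NULL,
                                    library_reads_millions = NULL,
                                    stream_tag = "coverage") {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config",
                                         call. = FALSE)
  if (n_samples < 3) stop("`n_samples` must be >= 3", call. = FALSE)
  set_substream(cfg, stream_tag)
  regions <- rep(c("Chesapeake Bay", "Georgia coast", "Gulf of Mexico",
                   "Equatorial Pacific", "North Pacific Subtropical Gyre",
                   "ETNP OMZ", "ETSP OMZ", "Southern Ocean"),
                 length.out = n_samples)
  x <- if (is.null(substrate_ratio)) {
    exp(stats::runif(n_samples, log(0.3), log(8)))
  } else rep(substrate_ratio, length.out = n_samples)
  lib <- if (is.null(library_reads_millions)) {
    round(stats::runif(n_samples, 10, 100), 1)
  } else rep(library_reads_millions, length.out = n_samples)
  true_ratio <- pmax(0, cfg$generatio_slope * x + cfg$generatio_intercept)
  amoa_abund <- stats::rlnorm(n_samples, log(0.5), 0.5)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    lam_amoa <- amoa_abund[i] * lib[i]
    lam_urec <- true_ratio[i] * amoa_abund[i] * lib[i]
    cov_amoa <- if (poisson_noise) stats::rpois(1, lam_amoa) else lam_amoa
    cov_urec <- if (poisson_noise) stats::rpois(1, lam_urec) else lam_urec
    rec <- tibble::tibble(
      sample_id = sprintf("smp%03d", i), region = regions[i],
      gene = "amoA", taxon_group = "AOA",
      mean_coverage = cov_amoa, library_reads_millions = lib[i])
    if (cov_urec > 0) {
      rec <- dplyr::bind_rows(rec, tibble::tibble(
        sample_id = sprintf("smp%03d", i), region = regions[i],
        gene = "ureC", taxon_group = "AOA",
        mean_coverage = cov_urec, library_reads_millions = lib[i]))
    }
    rows[[i]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- tibble::tibble(
    sample_id = sprintf("smp%03d", seq_len(n_samples)), region = regions,
    substrate_ratio = x, true_ratio = true_ratio, amoa_abund = amoa_abund,
    library_reads_millions = lib)
  out
}
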