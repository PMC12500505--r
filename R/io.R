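# Readers and writers for the three table schemas (incubations, sites,
# gene coverage) plus JSON fit output. Headers are required verbatim; units
# are embedded in column names because the data mix uM, uM N, nM and
# nmol/L/d.

incubation_cols <- c("station", "depth_m", "substrate", "treatment",
                     "bottle_id", "time_h", "n2o44_nM", "n2o45_nM",
                     "n2o46_nM", "no2_15N_nM", "ambient_conc_uMN",
                     "ambient_atom_frac15", "tracer_conc_uMN",
                     "tracer_atom_frac15")

check_header <- function(found, required, what) {
  missing_cols <- setdiff(required, found)
  if (length(missing_cols)) {
    stop(what, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(found)
}

check_numeric_cols <- function(df, cols, path) {
  for (nm in cols) {
    bad <- which(!is.finite(df[[nm]]))
    if (length(bad)) {
      stop("non-numeric or missing value in column `", nm, "` of ", path,
           " at data row(s) ", paste(head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(df)
}

check_nonnegative_cols <- function(df, cols, path) {
  for (nm in cols) {
    bad <- which(df[[nm]] < 0)
    if (length(bad)) {
      stop("negative value in column `", nm, "` of ", path,
           " at data row(s) ", paste(head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read an incubation table
#'
#' Reads a CSV of incubation measurements (one row per bottle and time
#' point) and assembles validated [time_course()] objects grouped by
#' (station, depth, substrate, treatment). The header must contain exactly
#' the documented columns; substrate-pool columns must be constant within a
#' group.
#'
#' @param path CSV file with columns `station`, `depth_m`, `substrate`,
#'   `treatment`, `bottle_id`, `time_h`, `n2o44_nM`, `n2o45_nM`, `n2o46_nM`,
#'   `no2_15N_nM`, `ambient_conc_uMN`, `ambient_atom_frac15`,
#'   `tracer_conc_uMN`, `tracer_atom_frac15`.
#' @return A list of [time_course()] objects (empty, with a warning, for a
#'   header-only file).
#' @export
read_incubation_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          station = "c", substrate = "c", treatment = "c",
                          bottle_id = "c", .default = "d"))
  check_header(names(df), incubation_cols, basename(path))
  if (nrow(df) == 0) {
    warning("no data rows in ", basename(path), call. = FALSE)
    return(list())
  }
  num_cols <- setdiff(incubation_cols,
                      c("station", "substrate", "treatment", "bottle_id"))
  check_numeric_cols(df, num_cols, basename(path))
  check_nonnegative_cols(df, setdiff(num_cols, "depth_m"), basename(path))
  key <- interaction(df$station, df$depth_m, df$substrate, df$treatment,
                     drop = TRUE)
  lapply(split(df, key), function(g) {
    pool_cols <- c("ambient_conc_uMN", "ambient_atom_frac15",
                   "tracer_conc_uMN", "tracer_atom_frac15")
    for (nm in pool_cols) {
      if (length(unique(g[[nm]])) != 1L) {
        stop("column `", nm, "` varies within the time course for station ",
             g$station[1], " depth ", g$depth_m[1], call. = FALSE)
      }
    }
    pool <- substrate_pool(g$substrate[1],
                           ambient_conc = g$ambient_conc_uMN[1],
                           tracer_conc = g$tracer_conc_uMN[1],
                           ambient_atom_frac15 = g$ambient_atom_frac15[1],
                           tracer_atom_frac15 = g$tracer_atom_frac15[1])
    time_course(station = g$station[1], depth_m = g$depth_m[1],
                substrate = g$substrate[1], treatment = g$treatment[1],
                pool = pool,
                points = g[c("time_h", "bottle_id", "n2o44_nM", "n2o45_nM",
                             "n2o46_nM", "no2_15N_nM")])
  })
}

#' Write an incubation table
#'
#' Inverse of [read_incubation_table()]; output round-trips losslessly
#' (numbers are written at full precision, deterministically).
#'
#' @param tcs A [time_course()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_incubation_table <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  rows <- lapply(tcs, function(tc) {
    tibble::tibble(
      station = tc$station, depth_m = tc$depth_m, substrate = tc$substrate,
      treatment = tc$treatment, bottle_id = tc$points$bottle_id,
      time_h = tc$points$time_h, n2o44_nM = tc$points$n2o44_nM,
      n2o45_nM = tc$points$n2o45_nM, n2o46_nM = tc$points$n2o46_nM,
      no2_15N_nM = tc$points$no2_15N_nM,
      ambient_conc_uMN = tc$pool$ambient_conc,
      ambient_atom_frac15 = tc$pool$ambient_atom_frac15,
      tracer_conc_uMN = tc$pool$tracer_conc,
      tracer_atom_frac15 = tc$pool$tracer_atom_frac15)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Read a cross-site compilation table
#'
#' @param path CSV file with columns `region`, `station`, `depth_m`,
#'   `habitat`, `nh4_uM`, `ureaN_uM`, `nh4_ox`, `urea_ox`,
#'   `nh4_ox_below_dl`, `urea_ox_below_dl`. Rates are nmol N L-1 d-1;
#'   habitat must be one of estuary, coastal, open_ocean, polar, omz.
#' @param urea_units `"N"` (default; `ureaN_uM` already in umol N L-1) or
#'   `"molar"` (umol urea L-1, converted x2 on read).
#' @return A validated sites tibble.
#' @export
read_sites_table <- function(path, urea_units = c("N", "molar")) {
  urea_units <- match.arg(urea_units)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          region = "c", station = "c", habitat = "c",
                          nh4_ox_below_dl = "l", urea_ox_below_dl = "l",
                          .default = "d"))
  check_header(names(df), sites_required_cols, basename(path))
  check_numeric_cols(df, c("nh4_uM", "ureaN_uM", "nh4_ox", "urea_ox"),
                     basename(path))
  if (urea_units == "molar") df$ureaN_uM <- urea_to_N(df$ureaN_uM)
  validate_sites(df)
  df
}

#' Write a cross-site compilation table
#'
#' @param sites A sites tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites_table <- function(sites, path) {
  validate_sites(sites)
  readr::write_csv(sites[sites_required_cols], path)
  invisible(path)
}

#' Read a per-gene coverage table
#'
#' @param path TSV file with columns `sample_id`, `region`, `gene`
#'   (amoA/ureC), `taxon_group` (AOA/AOB/comammox/other), `mean_coverage`
#'   (per-nucleotide depth) and `library_reads_millions`. Duplicated
#'   (sample, gene) rows are legitimate multiple gene hits and are summed
#'   downstream.
#' @return A validated coverage tibble.
#' @export
read_coverage_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = "c", region = "c", gene = "c",
                          taxon_group = "c", .default = "d"))
  check_header(names(df), coverage_required_cols, basename(path))
  check_numeric_cols(df, c("mean_coverage", "library_reads_millions"),
                     basename(path))
  validate_coverage(df)
  df
}

#' Write a per-gene coverage table
#'
#' @param cov A coverage tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(cov, path) {
  validate_coverage(cov)
  readr::write_tsv(tibble::as_tibble(cov)[coverage_required_cols], path)
  invisible(path)
}

#' Serialise a regression fit to JSON
#'
#' @param fit A `regression_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "regression_fit")) {
    stop("`fit` must be a regression_fit", call. = FALSE)
  }
  out <- list(method = fit$method, slope = fit$slope,
              slope_se = fit$slope_se, intercept = fit$intercept,
              r2 = fit$r2, p_value = fit$p_value, n = fit$n,
              residual_sd = fit$residual_sd,
              n_outliers = sum(fit$outlier_flags),
              n_excluded = fit$n_excluded)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
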