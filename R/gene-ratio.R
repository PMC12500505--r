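# ureC:amoA functional-gene coverage-ratio analysis: depth normalisation,
# per-sample ratios, region summaries and the linear ratio fits.

coverage_required_cols <- c("sample_id", "region", "gene", "taxon_group",
                            "mean_coverage", "library_reads_millions")
coverage_genes <- c("amoA", "ureC")
coverage_taxa <- c("AOA", "AOB", "comammox", "other")

validate_coverage <- function(cov) {
  missing_cols <- setdiff(coverage_required_cols, names(cov))
  if (length(missing_cols)) {
    stop("coverage table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_gene <- setdiff(unique(cov$gene), coverage_genes)
  if (length(bad_gene)) {
    stop("unknown gene value(s): ", paste(bad_gene, collapse = ", "),
         call. = FALSE)
  }
  bad_taxon <- setdiff(unique(cov$taxon_group), coverage_taxa)
  if (length(bad_taxon)) {
    stop("unknown taxon_group value(s): ", paste(bad_taxon, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(cov$mean_coverage)) || any(cov$mean_coverage < 0)) {
    stop("`mean_coverage` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(cov$library_reads_millions)) ||
      any(cov$library_reads_millions <= 0)) {
    stop("`library_reads_millions` must be > 0", call. = FALSE)
  }
  invisible(cov)
}

#' Normalise gene coverage to sequencing depth
#'
#' Divides per-nucleotide mean coverage by the library size in millions of
#' reads, giving coverage per million reads. Because mean coverage is already
#' per nucleotide, no gene-length adjustment is applied.
#'
#' @param mean_coverage Per-nucleotide mean coverage of a gene hit;
#'   vectorised.
#' @param library_reads_millions Library size in millions of reads, > 0.
#' @return Coverage per million reads.
#' @export
#' @examples
#' normalize_coverage(10, 20) # 0.5
normalize_coverage <- function(mean_coverage, library_reads_millions) {
  if (any(!is.finite(library_reads_millions)) ||
      any(library_reads_millions <= 0)) {
    stop("`library_reads_millions` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(mean_coverage)) || any(mean_coverage < 0)) {
    stop("`mean_coverage` must be finite and >= 0", call. = FALSE)
  }
  mean_coverage / library_reads_millions
}

#' ureC:amoA ratio for a single sample
#'
#' Sums depth-normalised coverage across gene hits per gene (multiple hits
#' approximate multiple gene variants) and forms
#' `sum(ureC) / sum(amoA)` for the requested taxon group. A sample with amoA
#' hits but no ureC has ratio 0; a sample with no amoA coverage has no
#' defined ratio and raises an error (use [sample_gene_ratios()] to map such
#' samples to missing values across a table).
#'
#' @param cov Coverage records for one sample (see [read_coverage_table()]
#'   for the schema).
#' @param taxon Taxon group whose genes enter the ratio (default `"AOA"`,
#'   the dominant marine ammonia oxidizers).
#' @return A list with `sample_id`, `region`, `amoa_norm`, `urec_norm`,
#'   `urec_amoa`.
#' @export
urec_amoa_ratio <- function(cov, taxon = "AOA") {
  validate_coverage(cov)
  ids <- unique(cov$sample_id)
  if (length(ids) != 1L) {
    stop("`cov` must contain exactly one sample_id", call. = FALSE)
  }
  sub <- cov[cov$taxon_group == taxon, , drop = FALSE]
  norm <- normalize_coverage(sub$mean_coverage, sub$library_reads_millions)
  amoa_norm <- sum(norm[sub$gene == "amoA"])
  urec_norm <- sum(norm[sub$gene == "ureC"])
  if (amoa_norm <= 0) {
    stop("sample ", ids, " has no ", taxon,
         " amoA coverage; ureC:amoA is undefined (missing, not zero)",
         call. = FALSE)
  }
  list(sample_id = ids, region = unique(cov$region)[1],
       amoa_norm = amoa_norm, urec_norm = urec_norm,
       urec_amoa = urec_norm / amoa_norm)
}

#' Per-sample ureC:amoA ratios for a coverage table
#'
#' Applies [urec_amoa_ratio()] to every sample. Samples without amoA
#' coverage in the requested taxon are reported with `urec_amoa = NA`
#' (missing, never infinity or zero) and a warning naming them.
#'
#' @inheritParams urec_amoa_ratio
#' @return A tibble with columns `sample_id`, `region`, `amoa_norm`,
#'   `urec_norm`, `urec_amoa`.
#' @export
sample_gene_ratios <- function(cov, taxon = "AOA") {
  validate_coverage(cov)
  ids <- unique(cov$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- cov[cov$sample_id == id, , drop = FALSE]
    out <- tryCatch(urec_amoa_ratio(sub, taxon = taxon), error = function(e) NULL)
    if (is.null(out)) {
      tibble::tibble(sample_id = id, region = unique(sub$region)[1],
                     amoa_norm = 0, urec_norm = NA_real_,
                     urec_amoa = NA_real_)
    } else {
      tibble::as_tibble(out)
    }
  })
  res <- dplyr::bind_rows(rows)
  n_missing <- sum(is.na(res$urec_amoa))
  if (n_missing > 0) {
    warning(n_missing, " sample(s) without ", taxon,
            " amoA coverage reported as missing: ",
            paste(res$sample_id[is.na(res$urec_amoa)], collapse = ", "),
            call. = FALSE)
  }
  res
}

#' Region summaries of ureC:amoA ratios
#'
#' Median and quartiles of the per-sample ratios by region; missing ratios
#' are excluded.
#'
#' @param ratios Output of [sample_gene_ratios()].
#' @return A tibble with columns `region`, `n`, `median`, `q25`, `q75`.
#' @export
region_summary <- function(ratios) {
  if (!all(c("region", "urec_amoa") %in% names(ratios))) {
    stop("`ratios` must have columns region and urec_amoa", call. = FALSE)
  }
  keep <- !is.na(ratios$urec_amoa)
  dropped <- setdiff(unique(ratios$region), unique(ratios$region[keep]))
  if (length(dropped)) {
    warning("region(s) with no defined ratios omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  ratios[keep, , drop = FALSE] |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$urec_amoa),
                     q25 = stats::quantile(.data$urec_amoa, 0.25, names = FALSE),
                     q75 = stats::quantile(.data$urec_amoa, 0.75, names = FALSE),
                     .groups = "drop") |>
    dplyr::arrange(.data$region)
}

#' Linear fit of ureC:amoA ratios on substrate ratios
#'
#' Ordinary least squares of the gene ratio on the urea-N : ammonium
#' concentration ratio, on the linear (not log) scale.
#'
#' @param substrate_ratio Urea-N : ammonium concentration ratios.
#' @param urec_amoa Per-sample ureC:amoA gene coverage ratios.
#' @return A `regression_fit`.
#' @export
ratio_vs_substrate_fit <- function(substrate_ratio, urec_amoa) {
  if (length(substrate_ratio) != length(urec_amoa)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  ols_fit_xy(substrate_ratio, urec_amoa, method_label = "ols")
}

#' Linear fit of oxidation-rate ratios on ureC:amoA ratios
#'
#' Ordinary least squares of the urea-oxidation : ammonium-oxidation rate
#' ratio on the gene coverage ratio, on the linear scale.
#'
#' @param urec_amoa Per-sample ureC:amoA gene coverage ratios.
#' @param rate_ratio Urea-oxidation : ammonium-oxidation rate ratios.
#' @return A `regression_fit`.
#' @export
ratio_vs_rate_ratio_fit <- function(urec_amoa, rate_ratio) {
  if (length(urec_amoa) != length(rate_ratio)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  ols_fit_xy(urec_amoa, rate_ratio, method_label = "ols")
}
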