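# Isotope bookkeeping: labelled substrate fractions and the binomial
# N2O isotopologue model linking mass-45/46 accumulation to gross production.

#' Natural abundance of 15N
#'
#' Atom fraction of 15N in atmospheric N2, used as the default 15N content of
#' ambient (unamended) substrate pools.
#'
#' @return A length-one numeric, 0.003663.
#' @export
natural_abundance_15N <- function() 0.003663

#' Construct a substrate pool
#'
#' Describes an ammonium or urea nitrogen pool after tracer addition: the
#' ambient concentration, the added tracer concentration, and the 15N atom
#' fraction of each component. Urea concentrations must be given in nitrogen
#' units (2 x molar urea; see [urea_to_N()]).
#'
#' @param species `"ammonium"` or `"urea"`.
#' @param ambient_conc Ambient concentration, umol N L-1. Must be >= 0.
#' @param tracer_conc Added tracer concentration, umol N L-1. Must be >= 0.
#' @param ambient_atom_frac15 15N atom fraction of the ambient pool, in
#'   \[0, 1\]. Defaults to natural abundance.
#' @param tracer_atom_frac15 15N atom fraction of the tracer, in \[0, 1\].
#'   Defaults to 0.99, typical of commercial 15N salts.
#'
#' @return An object of class `substrate_pool`.
#' @seealso [label_fraction()], [tracer_conc_for_F()]
#' @export
#' @examples
#' pool <- substrate_pool("ammonium", ambient_conc = 0.9, tracer_conc = 0.1)
#' label_fraction(pool)
substrate_pool <- function(species = c("ammonium", "urea"),
                           ambient_conc,
                           tracer_conc,
                           ambient_atom_frac15 = natural_abundance_15N(),
                           tracer_atom_frac15 = 0.99) {
  species <- match.arg(species)
  for (nm in c("ambient_conc", "tracer_conc",
               "ambient_atom_frac15", "tracer_atom_frac15")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (ambient_conc < 0 || tracer_conc < 0) {
    stop("substrate pool concentrations must be >= 0", call. = FALSE)
  }
  if (ambient_atom_frac15 < 0 || ambient_atom_frac15 > 1 ||
      tracer_atom_frac15 < 0 || tracer_atom_frac15 > 1) {
    stop("atom fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(species = species,
         ambient_conc = ambient_conc,
         tracer_conc = tracer_conc,
         ambient_atom_frac15 = ambient_atom_frac15,
         tracer_atom_frac15 = tracer_atom_frac15),
    class = "substrate_pool"
  )
}

#' @export
print.substrate_pool <- function(x, ...) {
  cat(sprintf("<substrate_pool> %s: ambient %.4g + tracer %.4g umol N/L (F = %.4f)\n",
              x$species, x$ambient_conc, x$tracer_conc, label_fraction(x)))
  invisible(x)
}

#' Labelled fraction of a substrate pool
#'
#' The 15N atom fraction F of the combined ambient + tracer pool: the
#' concentration-weighted mean of the component atom fractions. F divides
#' measured labelled-product accumulation to give gross rates.
#'
#' @param pool A [substrate_pool()].
#' @return F, a fraction in \[0, 1\].
#' @export
label_fraction <- function(pool) {
  if (!inherits(pool, "substrate_pool")) {
    stop("`pool` must be a substrate_pool", call. = FALSE)
  }
  total <- pool$ambient_conc + pool$tracer_conc
  if (total <= 0) {
    stop("total substrate pool is zero; labelled fraction is undefined",
         call. = FALSE)
  }
  (pool$ambient_conc * pool$ambient_atom_frac15 +
     pool$tracer_conc * pool$tracer_atom_frac15) / total
}

#' Tracer concentration needed to reach a target labelled fraction
#'
#' Inverts [label_fraction()]: how much tracer (at `tracer_atom_frac15`) must
#' be added to an ambient pool to bring the pool's 15N atom fraction to
#' `target_F`. Used to emulate the field protocol of adding tracer at roughly
#' ten percent of the ambient pool.
#'
#' @param ambient_conc Ambient concentration, umol N L-1 (> 0).
#' @param target_F Desired labelled fraction; must lie strictly between
#'   `ambient_atom_frac15` and `tracer_atom_frac15`.
#' @inheritParams substrate_pool
#' @return Tracer concentration in umol N L-1.
#' @export
tracer_conc_for_F <- function(ambient_conc, target_F,
                              ambient_atom_frac15 = natural_abundance_15N(),
                              tracer_atom_frac15 = 0.99) {
  if (ambient_conc <= 0) stop("`ambient_conc` must be > 0", call. = FALSE)
  if (target_F <= ambient_atom_frac15 || target_F >= tracer_atom_frac15) {
    stop("`target_F` must lie between the ambient and tracer atom fractions",
         call. = FALSE)
  }
  ambient_conc * (target_F - ambient_atom_frac15) /
    (tracer_atom_frac15 - target_F)
}

#' Binomial N2O isotopologue distribution
#'
#' Under single-pool production, both N atoms of each product N2O molecule are
#' drawn independently from a substrate pool with 15N atom fraction F, so the
#' mass 44/45/46 fractions follow a binomial: p44 = (1-F)^2, p45 = 2F(1-F),
#' p46 = F^2.
#'
#' @param F Labelled fraction(s) in \[0, 1\]; vectorised.
#' @return A tibble with columns `p44`, `p45`, `p46`, one row per element of
#'   `F`; each row sums to 1.
#' @export
#' @examples
#' isotopologue_fractions(c(0, 0.1, 0.5))
isotopologue_fractions <- function(F) {
  if (!is.numeric(F) || any(!is.finite(F)) || any(F < 0) || any(F > 1)) {
    stop("`F` must be numeric in [0, 1]", call. = FALSE)
  }
  tibble::tibble(p44 = (1 - F)^2, p45 = 2 * F * (1 - F), p46 = F^2)
}

#' Gross N2O production rate from isotopologue accumulation slopes
#'
#' Inverts the binomial forward model: a gross production rate R from a pool
#' labelled at fraction F accumulates mass-45 N2O at R * 2F(1-F) and mass-46
#' at R * F^2, so the 15N-atom excess slope (slope45 + 2 * slope46) equals
#' 2F * R. Negative slopes (measurement noise) are accepted.
#'
#' @param slope45,slope46 Accumulation slopes of mass-45 and mass-46 N2O,
#'   nmol N2O L-1 d-1.
#' @param F Labelled fraction of the substrate pool, > 0.
#' @return Gross N2O production rate, nmol N2O L-1 d-1.
#' @export
#' @examples
#' excess_to_n2o_rate(slope45 = 0.18, slope46 = 0.01, F = 0.1) # 1.0
excess_to_n2o_rate <- function(slope45, slope46, F) {
  if (!is.numeric(F) || any(!is.finite(F)) || any(F <= 0) || any(F > 1)) {
    stop("`F` must lie in (0, 1]; rate inversion is undefined at F = 0",
         call. = FALSE)
  }
  if (any(!is.finite(slope45)) || any(!is.finite(slope46))) {
    stop("slopes must be finite", call. = FALSE)
  }
  (slope45 + 2 * slope46) / (2 * F)
}
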