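#' Floral trait names used throughout the package
#'
#' Canonical column order: three components of floral display size (stems per
#' plant, mean racemes per stem, mean open flowers per raceme) and three
#' components of flower colour from spectral reflectance (hue, chroma,
#' reflectivity).
#'
#' @return Character vector of the six trait column names.
#' @export
trait_names <- function() {
  c("stems_per_plant", "racemes_per_stem", "flowers_per_raceme",
    "hue", "chroma", "reflectivity")
}

#' Default bee species labels
#'
#' @return Character vector: bumble, honey, leafcutting.
#' @export
species_names <- function() c("bumble", "honey", "leafcutting")

#' Specify the trait distribution of a simulated plant population
#'
#' Each trait is marginally a truncated normal whose underlying location and
#' scale are solved numerically so that the *realised* (post-truncation)
#' distribution has the requested mean and SD. Traits are coupled through a
#' Gaussian copula with the given correlation matrix, so marginal moments are
#' exact in distribution regardless of correlation. Stems per plant are
#' rounded to the nearest integer and bounded below by 1.
#'
#' @param means Named numeric vector of target trait means (names must be
#'   `trait_names()`).
#' @param sds Named numeric vector of target trait SDs, all > 0.
#' @param lower Named numeric vector of lower bounds (use `-Inf` for none).
#' @param correlation Trait correlation matrix (6 x 6, symmetric positive
#'   semi-definite). Default identity: field trait inter-correlations are not
#'   published for this population, so uncorrelated is the stated default.
#' @param integer_traits Character vector of traits rounded to integers.
#' @return An object of class `trait_model`.
#' @examples
#' tm <- trait_model()           # defaults calibrated to the field population
#' plants <- generate_plants(tm, 100, seed = 1)
#' @export
trait_model <- function(means = NULL, sds = NULL, lower = NULL,
                        correlation = NULL,
                        integer_traits = "stems_per_plant") {
  tn <- trait_names()
  means <- means %||% c(stems_per_plant = 30.65, racemes_per_stem = 4.93,
                        flowers_per_raceme = 7.53, hue = -0.012,
                        chroma = 1.29, reflectivity = 3.76)
  sds <- sds %||% c(stems_per_plant = 16.4, racemes_per_stem = 3.41,
                    flowers_per_raceme = 2.44, hue = 0.476,
                    chroma = 0.76, reflectivity = 1.11)
  lower <- lower %||% c(stems_per_plant = 1, racemes_per_stem = 0,
                        flowers_per_raceme = 0, hue = -Inf,
                        chroma = 0, reflectivity = 0)
  correlation <- correlation %||% diag(length(tn))
  if (!all(tn %in% names(means)) || !all(tn %in% names(sds)) ||
      !all(tn %in% names(lower)))
    stop_config("means, sds and lower must be named for every trait: ",
                paste(tn, collapse = ", "))
  means <- means[tn]; sds <- sds[tn]; lower <- lower[tn]
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop_config("all trait sds must be finite and > 0")
  correlation <- as.matrix(correlation)
  dimnames(correlation) <- list(tn, tn)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)))
    stop_config("correlation matrix must be symmetric")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_config("correlation matrix must be positive semi-definite")
  if (any(abs(diag(correlation) - 1) > 1e-8))
    stop_config("correlation matrix must have unit diagonal")
  structure(list(means = means, sds = sds, lower = lower,
                 correlation = correlation,
                 integer_traits = intersect(integer_traits, tn)),
            class = "trait_model")
}

#' Specify trait-dependent visitation preferences of bee species
#'
#' Per-plant, per-species visit intensity is log-linear in the standardized
#' traits z (standardized with the generated sample's own mean/SD):
#' `log lambda_is = a_s + sum_j b_sj z_ij + sum_j q_sjj z_ij^2 +
#' sum_{j<k} c_sjk z_ij z_ik`, then all intensities are rescaled so the
#' expected total visit count over the whole population equals
#' `total_visits`. Intercepts therefore control only the relative species
#' mix; defaults reproduce the observed 52/45/3 percent split among bumble,
#' honey and leafcutting bees.
#'
#' @param species Character vector of species labels.
#' @param intercept Named numeric, per-species log baseline intensity.
#' @param linear,quadratic Named lists (by species) of named numeric vectors
#'   of coefficients on standardized traits; omitted entries are 0.
#' @param interaction Named list (by species) of named numeric vectors whose
#'   names are `"traitA:traitB"` pairs; omitted entries are 0.
#' @param total_visits Target expected total visit count over all plants and
#'   species (default 8727, the observed total).
#' @param overdispersion `Inf` (default) gives Poisson counts; a finite
#'   positive value is the negative-binomial size parameter.
#' @return An object of class `preference_model`.
#' @export
preference_model <- function(species = species_names(),
                             intercept = NULL,
                             linear = list(), quadratic = list(),
                             interaction = list(),
                             total_visits = 8727,
                             overdispersion = Inf) {
  intercept <- intercept %||%
    stats::setNames(log(c(0.523, 0.450, 0.027))[seq_along(species)], species)
  if (!all(species %in% names(intercept)))
    stop_config("intercept must be named for every species")
  assert_scalar_number(total_visits, "total_visits", lower = 1e-9)
  if (!(identical(overdispersion, Inf)))
    assert_scalar_number(overdispersion, "overdispersion", lower = 1e-12)
  tn <- trait_names()
  canon <- function(lst, kind) {
    out <- lapply(species, function(s) {
      v <- lst[[s]] %||% numeric(0)
      if (kind == "interaction") {
        ok <- vapply(strsplit(names(v) %||% character(0), ":", fixed = TRUE),
                     function(p) length(p) == 2 && all(p %in% tn), logical(1))
        if (length(v) && !all(ok))
          stop_config("interaction names must be 'traitA:traitB' pairs")
      } else if (length(v) && !all(names(v) %in% tn)) {
        stop_config(kind, " coefficient names must be traits")
      }
      v
    })
    stats::setNames(out, species)
  }
  structure(list(species = species, intercept = intercept[species],
                 linear = canon(linear, "linear"),
                 quadratic = canon(quadratic, "quadratic"),
                 interaction = canon(interaction, "interaction"),
                 total_visits = total_visits,
                 overdispersion = overdispersion),
            class = "preference_model")
}

#' Specify the visit-to-seed yield process
#'
#' A visited flower is tripped with a species-specific probability (tripping
#' is the mechanical release of anthers and stigma that a flower requires
#' before it can set seed) and each tripped flower yields `kappa` seeds in
#' expectation. With noise on, per-plant seed totals are negative-binomial
#' around the expectation.
#'
#' @param tripping_rates Named numeric in \[0, 1\] per species. Defaults
#'   0.55 (bumble), 0.25 (honey), 0.80 (leafcutting), the field rates for
#'   warm seed-production conditions.
#' @param kappa Expected seeds per tripped flower; a scalar or named
#'   per-species vector. The default 31.4 calibrates the simulated mean
#'   seed set to the observed 754.67 seeds/plant at the observed visit
#'   totals (it absorbs visitation outside the observation window).
#' @param dispersion Negative-binomial size parameter for seed noise;
#'   default 0.6 calibrates the seed-set SD to the observed 986.90.
#' @param noise Logical; `FALSE` makes seed set equal its expectation
#'   exactly (kept fractional -- observed per-plant seed totals are
#'   themselves fractional, being products of per-plant averages).
#' @return An object of class `yield_model`.
#' @export
yield_model <- function(tripping_rates = c(bumble = 0.55, honey = 0.25,
                                           leafcutting = 0.80),
                        kappa = 31.4, dispersion = 0.6, noise = TRUE) {
  if (is.null(names(tripping_rates)))
    stop_config("tripping_rates must be named by species")
  if (any(tripping_rates < 0 | tripping_rates > 1))
    stop_config("tripping rates must lie in [0, 1]")
  if (any(kappa < 0)) stop_config("kappa must be >= 0")
  assert_scalar_number(dispersion, "dispersion", lower = 1e-12)
  structure(list(tripping_rates = tripping_rates, kappa = kappa,
                 dispersion = dispersion, noise = isTRUE(noise)),
            class = "yield_model")
}
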