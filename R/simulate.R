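## Synthetic plant populations, trait-dependent bee visitation and
## tripping-mediated seed set with known ground truth.

## Moments of a lower-truncated normal with underlying (mu, sigma), bound L.
.tn_moments <- function(mu, sigma, L) {
  a <- (L - mu) / sigma
  lam <- exp(stats::dnorm(a, log = TRUE) -
               stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

## Solve for underlying (mu, sigma) so the truncated distribution has the
## target mean/SD. Naive truncation of N(mean, sd) would inflate the mean
## (e.g. racemes/stem from 4.93 to ~5.44), so the calibration is inverted.
.tn_match <- function(target_mean, target_sd, L) {
  if (!is.finite(L)) return(c(mu = target_mean, sigma = target_sd))
  obj <- function(p) {
    mo <- .tn_moments(p[1], exp(p[2]), L)
    (mo["mean"] - target_mean)^2 / target_sd^2 +
      (mo["sd"] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-8)
    stop_config("cannot match a truncated normal to mean ", target_mean,
                ", sd ", target_sd, " with lower bound ", L)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.tn_quantile <- function(p, mu, sigma, L) {
  if (!is.finite(L)) return(mu + sigma * stats::qnorm(p))
  pL <- stats::pnorm((L - mu) / sigma)
  pmax(mu + sigma * stats::qnorm(pL + p * (1 - pL)), L)
}

#' Generate a synthetic plant population
#'
#' Draws `n_plants` plants from the trait model via a Gaussian copula with
#' moment-matched truncated-normal marginals (see [trait_model()]).
#'
#' @param model A [trait_model()].
#' @param n_plants Number of plants (>= 2).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data frame with `plant_id` and the six trait columns.
#' @export
generate_plants <- function(model, n_plants, seed) {
  if (!inherits(model, "trait_model")) stop_config("model must be a trait_model")
  assert_scalar_number(n_plants, "n_plants", lower = 2)
  tn <- trait_names()
  pars <- lapply(tn, function(j)
    .tn_match(model$means[[j]], model$sds[[j]], model$lower[[j]]))
  names(pars) <- tn
  R <- model$correlation
  cl <- chol(R + diag(1e-10, nrow(R)))
  X <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_plants * length(tn)), n_plants) %*% cl
    U <- stats::pnorm(Z)
    vapply(seq_along(tn), function(k) {
      x <- .tn_quantile(U[, k], pars[[k]]["mu"], pars[[k]]["sigma"],
                        model$lower[[tn[k]]])
      if (tn[k] %in% model$integer_traits)
        x <- pmax(round(x), ceiling(model$lower[[tn[k]]]))
      x
    }, numeric(n_plants))
  })
  colnames(X) <- tn
  out <- data.frame(plant_id = seq_len(n_plants), X)
  rownames(out) <- NULL
  out
}

## Standardized trait matrix (sample mean 0, sample SD 1) for a plant table.
.z_matrix <- function(plants) {
  tn <- trait_names()
  X <- as.matrix(plants[, tn])
  scale(X, center = TRUE, scale = apply(X, 2, stats::sd))
}

#' Generate flower-visit counts for each plant x species
#'
#' Counts are Poisson (or negative-binomial when the preference model sets a
#' finite overdispersion) with log-linear intensity in the standardized
#' traits, rescaled so the expected grand total equals the model's
#' `total_visits` (see [preference_model()]).
#'
#' @param plants Plant table from [generate_plants()].
#' @param model A [preference_model()].
#' @param seed Integer seed.
#' @return Long data frame: `plant_id`, `species`, `flowers_visited`.
#' @export
generate_visits <- function(plants, model, seed) {
  if (!inherits(model, "preference_model"))
    stop_config("model must be a preference_model")
  if (nrow(plants) < 1) stop_validation("plants table is empty")
  Z <- .z_matrix(plants)
  lam <- vapply(model$species, function(s) {
    eta <- rep(model$intercept[[s]], nrow(Z))
    for (j in names(model$linear[[s]]))
      eta <- eta + model$linear[[s]][[j]] * Z[, j]
    for (j in names(model$quadratic[[s]]))
      eta <- eta + model$quadratic[[s]][[j]] * Z[, j]^2
    for (jk in names(model$interaction[[s]])) {
      p <- strsplit(jk, ":", fixed = TRUE)[[1]]
      eta <- eta + model$interaction[[s]][[jk]] * Z[, p[1]] * Z[, p[2]]
    }
    exp(eta)
  }, numeric(nrow(Z)))
  lam <- matrix(lam, nrow = nrow(Z))
  lam <- lam * (model$total_visits / sum(lam))
  counts <- with_seed(seed, {
    if (is.finite(model$overdispersion))
      stats::rnbinom(length(lam), mu = as.vector(lam),
                     size = model$overdispersion)
    else
      stats::rpois(length(lam), as.vector(lam))
  })
  data.frame(plant_id = rep(plants$plant_id, times = length(model$species)),
             species = rep(model$species, each = nrow(Z)),
             flowers_visited = as.integer(counts))
}

#' Generate seed set from visits through the tripping process
#'
#' Expected seed set of plant i is `sum_s visits_is * trip_s * kappa_s`.
#' With noise on, realised totals are negative-binomial around this
#' expectation; with noise off they equal it exactly (fractional, no
#' rounding). The returned truth object records each species' expected
#' tripped flowers and seed contribution per plant.
#'
#' @param plants Plant table.
#' @param visits Visit table aligned to `plants` (same plant ids).
#' @param model A [yield_model()].
#' @param seed Integer seed (unused when noise is off).
#' @return List with `seeds` (data frame `plant_id`, `total_seeds`) and
#'   `truth` (data frame `plant_id`, `species`, `expected_tripped`,
#'   `expected_seeds`).
#' @export
generate_seeds <- function(plants, visits, model, seed = 1L) {
  if (!inherits(model, "yield_model")) stop_config("model must be a yield_model")
  if (!all(visits$plant_id %in% plants$plant_id) ||
      !all(plants$plant_id %in% visits$plant_id))
    stop_validation("visits and plants tables are misaligned: plant ids differ")
  sp <- unique(visits$species)
  if (!all(sp %in% names(model$tripping_rates)))
    stop_config("tripping rate missing for species: ",
                paste(setdiff(sp, names(model$tripping_rates)), collapse = ", "))
  kap <- model$kappa
  if (length(kap) == 1L) kap <- stats::setNames(rep(kap, length(sp)), sp)
  if (!all(sp %in% names(kap)))
    stop_config("kappa missing for species: ",
                paste(setdiff(sp, names(kap)), collapse = ", "))
  truth <- data.frame(
    plant_id = visits$plant_id, species = visits$species,
    expected_tripped = visits$flowers_visited *
      model$tripping_rates[visits$species],
    row.names = NULL)
  truth$expected_seeds <- truth$expected_tripped * kap[truth$species]
  mu <- tapply(truth$expected_seeds, truth$plant_id, sum)
  mu <- as.numeric(mu[as.character(plants$plant_id)])
  total <- if (model$noise) {
    with_seed(seed, stats::rnbinom(length(mu), mu = mu,
                                   size = model$dispersion))
  } else mu
  list(seeds = data.frame(plant_id = plants$plant_id,
                          total_seeds = as.numeric(total)),
       truth = truth)
}

#' Simulate a complete study: plants, visits and seed set
#'
#' Convenience wrapper chaining [generate_plants()], [generate_visits()] and
#' [generate_seeds()]. Each stage receives its own seed stream derived from
#' the one master seed.
#'
#' @param n_plants Number of plants (default 153, the field sample size).
#' @param traits,preference,yield Model objects; defaults are the calibrated
#'   field-population models.
#' @param seed Master integer seed.
#' @return List: `plants` (trait table with `total_seeds` column), `visits`,
#'   `truth`, and the three model objects.
#' @examples
#' sim <- simulate_study(n_plants = 50, seed = 42)
#' head(sim$plants)
#' @export
simulate_study <- function(n_plants = 153, traits = trait_model(),
                           preference = preference_model(),
                           yield = yield_model(), seed) {
  plants <- generate_plants(traits, n_plants, stage_seed(seed, "plants"))
  visits <- generate_visits(plants, preference, stage_seed(seed, "visits"))
  gen <- generate_seeds(plants, visits, yield, stage_seed(seed, "seeds"))
  plants$total_seeds <- gen$seeds$total_seeds[
    match(plants$plant_id, gen$seeds$plant_id)]
  list(plants = plants, visits = visits, truth = gen$truth,
       models = list(traits = traits, preference = preference, yield = yield),
       seed = seed)
}
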