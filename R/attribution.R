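## Partition each plant's seed set among bee species and compute relative
## fitness and the opportunity for selection.

#' Convert flower-visit counts to tripped-flower counts
#'
#' Multiplies each species' visit count on each plant by that species'
#' tripping rate (the proportion of visited flowers whose anthers and
#' stigma are released, a prerequisite for seed set). Counts are real
#' valued: they are expectations, not integer realisations.
#'
#' @param visits Long visit table: `plant_id`, `species`, `flowers_visited`.
#' @param rates Named numeric vector of tripping rates in \[0, 1\], one per
#'   species present in `visits`.
#' @return The visit table with a `flowers_tripped` column.
#' @examples
#' v <- data.frame(plant_id = 1, species = c("bumble", "honey", "leafcutting"),
#'                 flowers_visited = c(10, 10, 5))
#' tripped_counts(v, c(bumble = 0.55, honey = 0.25, leafcutting = 0.80))
#' @export
tripped_counts <- function(visits, rates) {
  sp <- unique(visits$species)
  missing_sp <- setdiff(sp, names(rates))
  if (length(missing_sp))
    stop_config("no tripping rate for species: ",
                paste(missing_sp, collapse = ", "))
  if (any(rates < 0 | rates > 1))
    stop_config("tripping rates must lie in [0, 1]")
  if (any(visits$flowers_visited < 0))
    stop_validation("negative visit counts")
  visits$flowers_tripped <- visits$flowers_visited * rates[visits$species]
  visits
}

#' Per-plant species shares of a count column
#'
#' For each plant, divides each species' count by the plant total. Plants
#' whose counts are all zero (never observed being visited) get zero shares
#' and are flagged `unvisited`; they stay in the table so that downstream
#' within-species analyses retain the full plant sample.
#'
#' @param counts Long table: `plant_id`, `species`, and the count column.
#' @param column Name of the count column (default `"flowers_visited"`).
#' @return The table with columns `share` and `unvisited` added.
#' @export
species_proportions <- function(counts, column = "flowers_visited") {
  x <- counts[[column]]
  if (is.null(x)) stop_config("no column '", column, "' in counts")
  if (any(x < 0)) stop_validation("negative counts in '", column, "'")
  tot <- tapply(x, counts$plant_id, sum)
  tot_i <- as.numeric(tot[as.character(counts$plant_id)])
  counts$share <- ifelse(tot_i > 0, x / tot_i, 0)
  counts$unvisited <- tot_i == 0
  counts
}

#' Attribute each plant's seed set to species by their shares
#'
#' `attributed_is = share_is * seeds_i`. Attributed seeds are fractional by
#' design (a proportional expectation). For every visited plant the
#' attributed seeds sum over species to the plant total; unvisited plants
#' get 0 for every species while their actual seed set still counts in the
#' all-pollinator analysis.
#'
#' @param seeds Data frame `plant_id`, `total_seeds` (>= 0).
#' @param proportions Output of [species_proportions()].
#' @return `proportions` with an `attributed_seeds` column.
#' @export
attribute_seeds <- function(seeds, proportions) {
  if (any(seeds$total_seeds < 0)) stop_validation("negative seed counts")
  idx <- match(proportions$plant_id, seeds$plant_id)
  if (anyNA(idx))
    stop_validation("proportions contain plant ids absent from seeds table")
  proportions$attributed_seeds <- proportions$share * seeds$total_seeds[idx]
  proportions
}

#' Relativize fitness
#'
#' Divides absolute fitness by the group mean, so the returned vector has
#' mean exactly 1. Selection analyses use this relative fitness w.
#'
#' @param values Nonnegative absolute fitness (e.g. seeds attributed to one
#'   species across all plants).
#' @return Numeric vector `w` with `mean(w) == 1`.
#' @export
relative_fitness <- function(values) {
  if (any(values < 0)) stop_validation("absolute fitness must be >= 0")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop_validation("degenerate fitness: group mean is 0 (no seeds attributed)")
  values / m
}

#' Opportunity for selection
#'
#' The sample variance (n - 1 denominator) of relative fitness: an upper
#' bound on the strength of selection the fitness distribution allows.
#'
#' @param w Relative fitness from [relative_fitness()].
#' @return A single number, `var(w)`.
#' @export
opportunity_for_selection <- function(w) {
  if (length(w) < 2) stop_validation("need at least 2 plants")
  stats::var(w)
}

#' Build the full fitness table over species and attribution bases
#'
#' For each basis -- `visited` (shares of flowers visited) and `tripped`
#' (shares of flowers tripped) -- attributes each plant's seed set to each
#' species and relativizes within species over all plants (zeros included:
#' plants a species never visited contribute w = 0 rows rather than being
#' dropped, so sample size is identical across species). The `total` basis
#' carries each plant's full seed set (species label `all`), regardless of
#' visit coverage.
#'
#' @param plants Plant table with `plant_id` and `total_seeds`.
#' @param visits Long visit table.
#' @param rates Named tripping rates.
#' @param bases Subset of `c("visited", "tripped", "total")`.
#' @return Long data frame: `plant_id`, `basis`, `species`,
#'   `attributed_seeds`, `relative_fitness`.
#' @export
fitness_table <- function(plants, visits, rates = NULL,
                          bases = c("visited", "tripped", "total")) {
  bases <- match.arg(bases, several.ok = TRUE)
  if (!all(c("plant_id", "total_seeds") %in% names(plants)))
    stop_validation("plants must have plant_id and total_seeds")
  visits <- aggregate_visits(visits)
  ## complete the plant x species grid so every plant appears for every species
  sp <- sort(unique(visits$species))
  grid <- expand.grid(plant_id = plants$plant_id, species = sp,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$plant_id, grid$species),
               paste(visits$plant_id, visits$species))
  grid$flowers_visited <- ifelse(is.na(idx), 0, visits$flowers_visited[idx])
  seeds <- plants[, c("plant_id", "total_seeds")]
  out <- list()
  for (b in setdiff(bases, "total")) {
    cnt <- if (b == "tripped") {
      if (is.null(rates))
        stop_config("tripped basis requested but no tripping rates given")
      g <- tripped_counts(grid, rates); g$count <- g$flowers_tripped; g
    } else {
      g <- grid; g$count <- g$flowers_visited; g
    }
    pr <- species_proportions(cnt, "count")
    at <- attribute_seeds(seeds, pr)
    at <- at[order(at$species, at$plant_id), ]
    at$relative_fitness <- stats::ave(at$attributed_seeds, at$species,
                                      FUN = relative_fitness)
    out[[b]] <- data.frame(plant_id = at$plant_id, basis = b,
                           species = at$species,
                           attributed_seeds = at$attributed_seeds,
                           relative_fitness = at$relative_fitness)
  }
  if ("total" %in% bases) {
    out$total <- data.frame(plant_id = seeds$plant_id, basis = "total",
                            species = "all",
                            attributed_seeds = seeds$total_seeds,
                            relative_fitness = relative_fitness(seeds$total_seeds))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a visit table to one row per plant x species
#'
#' Flower visits are summed over observation bouts (and over racemes, if
#' records are raceme-level) so that proportions are defined on flowers.
#'
#' @param visits Long visit table, possibly with duplicate plant x species
#'   rows.
#' @return Aggregated table, one row per plant x species.
#' @export
aggregate_visits <- function(visits) {
  need <- c("plant_id", "species", "flowers_visited")
  if (!all(need %in% names(visits)))
    stop_validation("visit table must have columns ",
                    paste(need, collapse = ", "))
  if (any(visits$flowers_visited < 0))
    stop_validation("negative visit counts")
  agg <- stats::aggregate(flowers_visited ~ plant_id + species, visits, sum)
  agg[order(agg$plant_id, agg$species), , drop = FALSE]
}
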