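## Distributional selection differentials: total distributional change of a
## trait under fitness weighting (1-D transport distance between the
## empirical trait distribution and its fitness-weighted counterpart), split
## into a directional (mean-shift) and a non-directional (shape) component,
## with permutation inference.

#' Normalize fitness to post-selection probability weights
#'
#' @param w Nonnegative fitness values, not all zero.
#' @return Weights `w / sum(w)`, summing to 1.
#' @export
post_selection_weights <- function(w) {
  if (any(w < 0)) stop_validation("fitness must be >= 0")
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop_validation("degenerate fitness: all weights zero")
  w / s
}

#' Distributional selection differential and its decomposition
#'
#' DSD is the 1-D optimal-transport (earth mover's) distance between the
#' unweighted empirical distribution of the trait and its fitness-weighted
#' counterpart, computed as the area between the two step CDFs over the
#' merged sorted breakpoints. The directional component is the absolute
#' mean shift `dD = |sum(w z)/sum(w) - mean(z)|`; the non-directional
#' component `dN = DSD - dD` captures change in distribution shape
#' (variance, skew, ...) beyond the mean. Always `DSD >= dD`, hence
#' `dN >= 0`, and `DSD = dD + dN` by construction. With `z` standardized,
#' all three are in trait-SD units.
#'
#' @param z Trait values (standardized for SD units; the statistic itself
#'   only assumes numeric).
#' @param w Nonnegative fitness (relative fitness in the usual pipeline).
#' @return List of class `dsd` with elements `DSD`, `dD`, `dN`.
#' @examples
#' dsd(c(0, 1), c(0, 2))      # mass moves wholly to z = 1: pure mean shift
#' dsd(c(-1, 0, 1), c(0, 3, 0)) # symmetric contraction: pure shape change
#' @export
dsd <- function(z, w) {
  if (length(z) < 2) stop_validation("need at least 2 observations")
  if (length(w) != length(z)) stop_validation("z and w lengths differ")
  pw <- post_selection_weights(w)
  o <- order(z)
  zs <- z[o]
  F_pre <- cumsum(rep(1 / length(z), length(z)))
  F_post <- cumsum(pw[o])
  ## area between step CDFs over intervals [z_(k), z_(k+1))
  k <- seq_len(length(zs) - 1L)
  total <- sum(abs(F_pre[k] - F_post[k]) * diff(zs))
  dD <- abs(sum(pw * z) - mean(z))
  structure(list(DSD = total, dD = dD, dN = total - dD), class = "dsd")
}

#' Permutation test for the DSD decomposition
#'
#' Shuffles the fitness vector across plants `B` times and recomputes DSD,
#' dD and dN; one-sided p-values are `(1 + #{permuted >= observed}) /
#' (B + 1)`, so the smallest attainable p is `1/(B + 1)`.
#'
#' @inheritParams dsd
#' @param B Number of permutations (default 1999).
#' @param seed Integer seed.
#' @return List of class `dsd_test`: observed `DSD`, `dD`, `dN`, p-values
#'   `p_DSD`, `p_dD`, `p_dN`, and `B`.
#' @export
dsd_permutation_test <- function(z, w, B = 1999, seed = 1) {
  assert_scalar_number(B, "B", lower = 1)
  obs <- dsd(z, w)
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      d <- dsd(z, w[sample.int(length(w))])
      c(d$DSD, d$dD, d$dN)
    }, numeric(3))
  })
  pval <- function(stat, i) (1 + sum(perm[i, ] >= stat)) / (B + 1)
  structure(list(DSD = obs$DSD, dD = obs$dD, dN = obs$dN,
                 p_DSD = pval(obs$DSD, 1), p_dD = pval(obs$dD, 2),
                 p_dN = pval(obs$dN, 3), B = as.integer(B)),
            class = "dsd_test")
}

#' Distributional selection report over species, bases and traits
#'
#' For every species x attribution-basis block (zero-fitness plants
#' included, as in [selection_report()]) and every trait, computes the DSD
#' decomposition on the standardized trait with relativized fitness, plus
#' permutation p-values.
#'
#' @inheritParams selection_report
#' @param B Permutations per test (default 1999).
#' @param seed Integer seed (one stream per block, derived from it).
#' @return Tidy data frame: `species`, `basis`, `trait`, `DSD`, `p_DSD`,
#'   `dD`, `p_dD`, `dN`, `p_dN`, `B`, `seed`.
#' @export
dsd_report <- function(plants, visits, rates = NULL,
                       bases = c("visited", "tripped", "total"),
                       traits = trait_names(), B = 1999, seed = 1) {
  keep <- stats::complete.cases(plants[, c(traits, "total_seeds")])
  plants <- plants[keep, , drop = FALSE]
  ft <- fitness_table(plants, visits, rates, bases = bases)
  blocks <- unique(ft[, c("species", "basis")])
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    sp <- blocks$species[i]; b <- blocks$basis[i]
    fb <- ft[ft$species == sp & ft$basis == b, ]
    z <- standardize(plants[match(fb$plant_id, plants$plant_id), , drop = FALSE],
                     traits)
    w <- fb$relative_fitness
    rows <- lapply(traits, function(tr) {
      tst <- dsd_permutation_test(z$z[, tr], w, B = B,
                                  seed = stage_seed(seed, paste(sp, b, tr)))
      data.frame(species = sp, basis = b, trait = tr,
                 DSD = tst$DSD, p_DSD = tst$p_DSD, dD = tst$dD,
                 p_dD = tst$p_dD, dN = tst$dN, p_dN = tst$p_dN,
                 B = tst$B, seed = seed)
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
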